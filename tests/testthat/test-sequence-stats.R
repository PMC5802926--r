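# Fixture: superbursts with prescribed per-superburst motif compositions.
makeTypedFixture <- function(fractions, burstsPer = 100L) {
  nSB <- nrow(fractions)
  starts <- seq(0, by = 100, length.out = nSB)
  bursts <- list(); members <- list(); bid <- 0L
  motifs <- integer(0)
  for (i in seq_len(nSB)) {
    n1 <- round(fractions[i, 1] * burstsPer)
    mot <- c(rep(1L, n1), rep(2L, burstsPer - n1))
    ids <- bid + seq_len(burstsPer)
    bid <- bid + burstsPer
    bs <- starts[i] + seq_len(burstsPer) * 0.1
    bursts[[i]] <- data.frame(burst_id = ids, start_s = bs,
                              end_s = bs + 0.04, peak_s = bs,
                              n_spikes = 100L, class = "small")
    members[[i]] <- ids
    motifs <- c(motifs, mot)
  }
  bdf <- do.call(rbind, bursts)
  seq <- new("BurstSequence", bursts = bdf, metadata = list())
  sbs <- new("SuperburstSet",
             superbursts = data.frame(sb_id = seq_len(nSB),
                                      start_s = starts,
                                      end_s = starts + 99,
                                      n_bursts = burstsPer,
                                      length_class = "long",
                                      type = NA_integer_),
             members = members, metadata = list())
  list(seq = seq, sbs = sbs,
       motifs = data.frame(burst_id = bdf$burst_id, motif = motifs))
}

test_that("superbursts with contrasting motif content split into two types", {
  fx <- makeTypedFixture(rbind(c(0.97, 0.03), c(0.18, 0.82),
                               c(0.97, 0.03), c(0.18, 0.82)))
  ts <- typeSuperbursts(fx$sbs, fx$seq, fx$motifs)
  expect_equal(ts@table$type, c(ts@table$type[1], 3L - ts@table$type[1],
                                ts@table$type[1], 3L - ts@table$type[1]))
  expect_equal(sort(unname(ts@dominantMotif)), 1:2)
  # label-swapped motifs give the same partition with swapped names
  fx2 <- fx; fx2$motifs$motif <- 3L - fx2$motifs$motif
  ts2 <- typeSuperbursts(fx2$sbs, fx2$seq, fx2$motifs)
  expect_true(all((ts@table$type == ts@table$type[1]) ==
                  (ts2@table$type == ts2@table$type[1])))
})

test_that("degenerate typing inputs raise errors", {
  fx1 <- makeTypedFixture(rbind(c(0.9, 0.1)))
  expect_error(typeSuperbursts(fx1$sbs, fx1$seq, fx1$motifs), "at least 2")
  fxSame <- makeTypedFixture(rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.9, 0.1)))
  expect_error(typeSuperbursts(fxSame$sbs, fxSame$seq, fxSame$motifs),
               "identical")
})

test_that("motif fidelity counts matches to the type's dominant motif", {
  pure <- makeTypedFixture(rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1)))
  tsP <- typeSuperbursts(pure$sbs, pure$seq, pure$motifs)
  expect_equal(motifFidelity(tsP)$value, 1.0)
  mixed <- makeTypedFixture(rbind(c(0.9, 0.1), c(0.5, 0.5),
                                  c(0.9, 0.1), c(0.5, 0.5)))
  tsM <- typeSuperbursts(mixed$sbs, mixed$seq, mixed$motifs)
  # the half-mixed type contributes 0.5, the 90% type 0.9
  expect_equal(motifFidelity(tsM)$value, 0.7)
})

test_that("switch probabilities follow their definitions", {
  fx <- makeTypedFixture(rbind(c(0.97, 0.03), c(0.03, 0.97),
                               c(0.97, 0.03), c(0.03, 0.97)))
  ts <- typeSuperbursts(fx$sbs, fx$seq, fx$motifs)
  expect_equal(superburstSwitchProbability(ts)$value, 1.0)
  fx2 <- makeTypedFixture(rbind(c(0.97, 0.03), c(0.97, 0.03),
                                c(0.03, 0.97), c(0.03, 0.97)))
  ts2 <- typeSuperbursts(fx2$sbs, fx2$seq, fx2$motifs)
  expect_equal(superburstSwitchProbability(ts2)$value, 1 / 3)

  expect_equal(
    burstMotifSwitchProbability(c("A", "A", "A", "B", "B"))$value, 0.25)
  expect_equal(burstMotifSwitchProbability(rep(1L, 10))$value, 0)
  expect_error(burstMotifSwitchProbability(1L), "at least 2")
})

test_that("statistics are invariant to global motif relabelling", {
  fx <- makeTypedFixture(rbind(c(0.9, 0.1), c(0.2, 0.8),
                               c(0.85, 0.15), c(0.25, 0.75)))
  ts <- typeSuperbursts(fx$sbs, fx$seq, fx$motifs)
  fx2 <- fx; fx2$motifs$motif <- 3L - fx2$motifs$motif
  ts2 <- typeSuperbursts(fx2$sbs, fx2$seq, fx2$motifs)
  expect_equal(motifFidelity(ts)$value, motifFidelity(ts2)$value)
  expect_equal(superburstSwitchProbability(ts)$value,
               superburstSwitchProbability(ts2)$value)
  expect_equal(burstMotifSwitchProbability(ts)$value,
               burstMotifSwitchProbability(ts2)$value)
})

test_that("generator statistics match the two-level closed form", {
  cfg <- smallConfig(nSuperbursts = 30L,
                     smallBurstsPerSuperburst = c(60L, 60L),
                     interSuperburstGap = c(20, 30), seed = 31L)
  ds <- generateDataset(cfg)
  seq <- gtBurstSequence(ds$truth)
  sbs <- gtSuperburstSet(ds$truth)
  gt <- ds$truth@bursts
  motifs <- data.frame(burst_id = gt$burst_id[gt$class == "small"],
                       motif = gt$motif[gt$class == "small"])
  ts <- typeSuperbursts(sbs, seq, motifs)
  f <- cfg@params$motifFidelity
  nSB <- 30L; nB <- 60L
  fid <- motifFidelity(ts)
  seF <- sqrt(f * (1 - f) / fid$denominator)
  expect_lt(abs(fid$value - f), 3 * seF)

  sw <- superburstSwitchProbability(ts)
  expect_lt(abs(sw$value - 0.5), 3 * sqrt(0.25 / sw$denominator))

  bm <- burstMotifSwitchProbability(ts)
  pIn <- 2 * f * (1 - f)
  pAcross <- 0.5 * pIn + 0.5 * (f^2 + (1 - f)^2)
  nIn <- nSB * (nB - 1L); nAcross <- nSB - 1L
  expM <- (nIn * pIn + nAcross * pAcross) / (nIn + nAcross)
  seM <- sqrt(nIn * pIn * (1 - pIn) + nAcross * pAcross * (1 - pAcross)) /
    (nIn + nAcross)
  expect_lt(abs(bm$value - expM), 3 * seM)

  # numeric check of the dependence bound implied by the two-level process
  expect_lt(bm$value, 1 - f^2 + 3 * seM)
})
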