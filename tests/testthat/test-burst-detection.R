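test_that("the TSR bins and conserves spikes", {
  st <- SpikeTable(c(0L, 0L, 1L), c(0.001, 0.002, 0.007), duration = 0.01)
  tsr <- computeTSR(st, binWidth = 0.005)
  expect_equal(tsr@counts, c(2, 1))
  expect_error(computeTSR(SpikeTable(integer(0), numeric(0), duration = 1)),
               "empty")
  expect_error(computeTSR(st, binWidth = 0), "positive")
  set.seed(3)
  big <- SpikeTable(rep(0L, 1e4), runif(1e4, 0, 50), duration = 50)
  expect_equal(sum(computeTSR(big)@counts), 1e4)
})

test_that("a single planted burst is detected with an exact start", {
  set.seed(4)
  times <- sort(runif(200, 5, 5.05))
  st <- SpikeTable(rep(0L, 200), times, duration = 10)
  seq <- detectBursts(computeTSR(st), st)
  expect_equal(nBursts(seq), 1L)
  expect_equal(bursts(seq)$start_s, min(times))
  expect_equal(bursts(seq)$n_spikes, 200L)
  expect_gte(bursts(seq)$end_s, max(times))
})

test_that("a constant TSR yields no bursts with a warning", {
  st <- SpikeTable(rep(0L, 100), (0:99) * 0.005 + 0.0025, duration = 0.5)
  expect_warning(seq <- detectBursts(computeTSR(st), st), "constant TSR")
  expect_equal(nBursts(seq), 0L)
})

test_that("two planted bursts keep their peak separation", {
  set.seed(5)
  # peaked (bell-shaped) spike densities centred 150 ms apart
  t1 <- pmin(pmax(rnorm(200, 2.025, 0.008), 2.0), 2.0499)
  t2 <- pmin(pmax(rnorm(200, 2.175, 0.008), 2.15), 2.1999)
  st <- SpikeTable(rep(0L, 400), c(t1, t2), duration = 6)
  seq <- detectBursts(computeTSR(st), st)
  expect_equal(nBursts(seq), 2L)
  expect_equal(diff(bursts(seq)$peak_s), 0.15, tolerance = 0.005 + 1e-9)
})

test_that("burst detection matches a literal bin-scanning reference", {
  set.seed(6)
  for (trial in 1:100) {
    n <- sample(20:500, 1)
    # mixture of diffuse spikes and a few dense clumps
    nClump <- sample(0:3, 1)
    times <- runif(n, 0, 3)
    if (nClump > 0) {
      ctr <- runif(nClump, 0.2, 2.8)
      extra <- unlist(lapply(ctr, function(c0)
        runif(sample(30:120, 1), c0, c0 + 0.04)))
      times <- c(times, extra)
    }
    times <- sort(times)
    st <- SpikeTable(rep(0L, length(times)), times, duration = 3)
    got <- bursts(detectBursts(computeTSR(st), st))
    want <- naiveBurstScan(times, duration = 3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$end_s, want$end_s)
      expect_equal(got$peak_s, want$peak_s)
      expect_equal(got$n_spikes, want$n_spikes)
    }
  }
})

test_that("burst count is monotone in the threshold coefficient", {
  # deterministic unimodal bursts: exact per-bin counts, so raising the
  # threshold can only shrink or remove runs, never split them
  profile <- c(1, 3, 8, 15, 8, 3, 1)
  heights <- c(1, 2, 4, 8)   # scale factors of successive bursts
  times <- unlist(lapply(seq_along(heights), function(b) {
    off <- b * 0.5
    rep(off + (seq_along(profile) - 0.5) * 0.005,
        times = profile * heights[b])
  }))
  st <- SpikeTable(rep(0L, length(times)), sort(times), duration = 3)
  tsr <- computeTSR(st)
  counts <- sapply(c(0.05, 0.1, 0.2, 0.5, 1, 2, 4), function(cf)
    nBursts(suppressWarnings(detectBursts(tsr, st, coeff = cf))))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 4L)
})

test_that("planted bursts are recovered within one bin", {
  ds <- generateDataset(smallConfig(
    nSuperbursts = 1L, smallBurstsPerSuperburst = c(100L, 100L),
    backgroundRate = 0.1))
  st <- ds$spikes
  det <- bursts(detectBursts(computeTSR(st), st))
  gt <- ds$truth@bursts
  err <- sapply(gt$start_s, function(s) min(abs(det$start_s - s)))
  expect_gte(mean(err <= 0.005), 0.95)
})

test_that("K-means burst classification matches the exhaustive partition", {
  seq <- makeBurstSeq(starts = (1:5), ends = (1:5) + 0.05,
                      nSpikes = c(1500L, 2000L, 50L, 80L, 120L))
  cl <- classifyBursts(seq)
  expect_equal(bursts(cl)$class,
               c("initiation", "initiation", "small", "small", "small"))
  thr <- cl@metadata$class_threshold
  expect_true(thr > 120 && thr < 1500)

  # random count sets: agreement with the exhaustive 1-D WCSS optimum
  set.seed(8)
  for (trial in 1:50) {
    n <- sample(5:40, 1)
    counts <- c(sample(1000:3000, sample(1:4, 1), replace = TRUE),
                sample(10:500, n, replace = TRUE))
    seqR <- makeBurstSeq(starts = seq_along(counts),
                         ends = seq_along(counts) + 0.05,
                         nSpikes = as.integer(counts))
    got <- bursts(classifyBursts(seqR, seed = trial))$class == "initiation"
    expect_equal(got, best1d2split(counts))
  }
})

test_that("identical burst sizes degrade gracefully", {
  seq <- makeBurstSeq(starts = 1:3, ends = (1:3) + 0.05, nSpikes = 10L)
  expect_warning(cl <- classifyBursts(seq), "identical")
  expect_true(all(bursts(cl)$class == "small"))
})

test_that("interburst peak intervals convert to frequencies", {
  seq <- makeBurstSeq(starts = c(0.98, 1.08), ends = c(1.02, 1.12),
                      peaks = c(1.0, 1.1))
  r <- computeIBPI(seq, smallOnly = TRUE)
  expect_equal(r$ibpi_s, 0.1)
  expect_equal(r$if_hz, 10)

  pk <- seq(1, by = 0.0893, length.out = 50)
  seq2 <- makeBurstSeq(starts = pk - 0.01, ends = pk + 0.03, peaks = pk)
  expect_equal(computeIBPI(seq2)$median_if_hz, 1 / 0.0893, tolerance = 1e-9)

  single <- makeBurstSeq(1, 1.05)
  expect_length(computeIBPI(single)$ibpi_s, 0)
})

test_that("intervals never span superburst gaps", {
  ds <- generateDataset(smallConfig())
  seq <- gtBurstSequence(ds$truth)
  sbs <- gtSuperburstSet(ds$truth, minSmallLong = 5L)
  r <- computeIBPI(seq, superbursts = sbs)
  nSmall <- table(ds$truth@bursts$sb_id[ds$truth@bursts$class == "small"])
  expect_length(r$ibpi_s, sum(nSmall - 1L))
  expect_true(all(r$ibpi_s < 5))  # no 30-40 s gap intervals
})

test_that("intra-burst rates are computed per electrode", {
  lay <- standardLayout()
  st <- SpikeTable(rep(0L, 7), seq(1.001, 1.045, length.out = 7),
                   layout = lay, duration = 2)
  seq <- makeBurstSeq(1, 1.05)
  r <- intraBurstRate(seq, st)
  expect_equal(r$rate_hz[r$electrode == 0], 140)
  expect_equal(r$rate_hz[r$electrode == 1], 0)
  expect_false(r$active[r$electrode == 1])
  expect_error(intraBurstRate(makeBurstSeq(1, 1.05, class = "initiation"),
                              st), "no small bursts")
})

test_that("generator intra-burst rates are recovered by the estimator", {
  cfg <- smallConfig(nSuperbursts = 1L,
                     smallBurstsPerSuperburst = c(110L, 110L))
  ds <- generateDataset(cfg)
  seq <- gtBurstSequence(ds$truth)
  r <- intraBurstRate(seq, ds$spikes)
  small <- ds$truth@bursts[ds$truth@bursts$class == "small", ]
  nObs <- sum(small$n_spikes)
  se <- sqrt(nObs) / (sum(small$end_s - small$start_s) * 59)
  expect_lt(abs(mean(r$rate_hz) - cfg@params$intraBurstRate), 3 * se)
})
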