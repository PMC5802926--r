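test_that("the standard layout is a 59-site 200-um grid without corners", {
  lay <- standardLayout()
  expect_length(lay@ids, 59L)
  expect_false(anyDuplicated(lay@positions, MARGIN = 1) > 0)
  expect_equal(nearestNeighbourDistance(lay), 200)
  expect_equal(unname(apply(lay@positions, 2, function(p) diff(range(p)))),
               c(1400, 1400))
  # corners and the reference site are absent
  expect_false(any(lay@positions[, 1] == 0 & lay@positions[, 2] == 0))
  expect_error(new("ElectrodeLayout", ids = c(0L, 1L),
                   positions = rbind(c(0, 0), c(0, 0))),
               "unique")
})

test_that("generated burst and superburst counts follow the configuration", {
  ds <- generateDataset(smallConfig(nSuperbursts = 2L,
                                    smallBurstsPerSuperburst = c(10L, 10L)))
  gt <- ds$truth
  expect_equal(nrow(gt@superbursts), 2L)
  expect_equal(nrow(gt@bursts), 22L)  # 2 initiation + 20 small
  expect_equal(sum(gt@bursts$class == "initiation"), 2L)
  # bursts nested inside their superburst window, non-overlapping
  for (i in 1:2) {
    b <- gt@bursts[gt@bursts$sb_id == i, ]
    expect_true(all(b$start_s >= gt@superbursts$start_s[i]))
    expect_true(all(b$end_s <= gt@superbursts$end_s[i] + 1e-9))
    expect_true(all(diff(b$start_s) > 0))
    expect_true(all(b$start_s[-1] >= b$end_s[-nrow(b)]))
  }
  # with zero background, every spike lies in exactly one burst window and
  # window spike counts match the planted counts exactly
  sp <- spikes(ds$spikes)
  for (j in seq_len(nrow(gt@bursts)))
    expect_equal(sum(sp$time_s >= gt@bursts$start_s[j] &
                     sp$time_s < gt@bursts$end_s[j]),
                 gt@bursts$n_spikes[j])
  expect_equal(sum(gt@bursts$n_spikes), nrow(sp))
})

test_that("the generator is deterministic in (config, seed)", {
  a <- generateDataset(smallConfig(seed = 99L))
  b <- generateDataset(smallConfig(seed = 99L))
  expect_identical(spikes(a$spikes), spikes(b$spikes))
  expect_identical(a$truth@bursts, b$truth@bursts)
  c <- generateDataset(smallConfig(seed = 100L))
  expect_false(identical(spikes(a$spikes), spikes(c$spikes)))
})

test_that("a degenerate interburst-interval distribution gives exact gaps", {
  ds <- generateDataset(smallConfig(
    nSuperbursts = 1L, ibpiMean = 0.1, ibpiSd = 0,
    initiationBurstDuration = c(0.05, 0.05)))
  pk <- ds$truth@bursts$peak_s
  expect_equal(diff(pk), rep(0.1, length(pk) - 1), tolerance = 1e-12)
})

test_that("invalid generator configurations are rejected", {
  expect_error(smallConfig(smallBurstDuration = c(0.08, 0.09),
                           ibpiMean = 0.09), "overlap")
  expect_error(smallConfig(motifDirections = c(45, 45 + 360)), "non-zero")
  expect_error(smallConfig(motifFidelity = 1.2))
  expect_error(smallConfig(intraBurstRate = -1))
})

test_that("planted planar waves encode direction and speed exactly", {
  cfg <- smallConfig(nSuperbursts = 1L, latencyJitterSd = 0,
                     motifDirections = c(37, 290))
  ds <- generateDataset(cfg)
  lay <- arrayLayout(ds$spikes)
  gt <- ds$truth
  small <- which(gt@bursts$class == "small")
  for (j in small[1:3]) {
    lat <- gt@latencies[[j]]
    fit <- lm(lat ~ lay@positions[, 1] + lay@positions[, 2])
    g <- coef(fit)[2:3]
    ang <- (atan2(g[2], g[1]) * 180 / pi) %% 360
    expect_lt(circularAngleDifference(ang, gt@bursts$direction_deg[j]), 1)
    speed <- 1 / sqrt(sum(g^2)) / 1000      # (s/um)^-1 -> um/ms
    expect_equal(speed, cfg@params$waveSpeed, tolerance = 0.01)
  }
})

test_that("intra-burst rates are calibrated to the configured value", {
  cfg <- smallConfig(nSuperbursts = 1L,
                     smallBurstsPerSuperburst = c(120L, 120L))
  ds <- generateDataset(cfg)
  gt <- ds$truth@bursts
  small <- gt[gt$class == "small", ]
  totDur <- sum(small$end_s - small$start_s) * 59
  nObs <- sum(small$n_spikes)
  rate <- nObs / totDur
  se <- sqrt(nObs) / totDur
  expect_lt(abs(rate - cfg@params$intraBurstRate), 3 * se)
})

test_that("the type process yields the configured switch fraction", {
  set.seed(5)
  ty <- simulateTypes(1e4, 0.5)
  sw <- mean(diff(ty) != 0)
  expect_lt(abs(sw - 0.5), 3 * sqrt(0.25 / (1e4 - 1)))
  expect_equal(unique(simulateTypes(100, 0, seed = 2)), simulateTypes(1, 0, seed = 2))
  alt <- simulateTypes(50, 1, seed = 3)
  expect_true(all(diff(alt) != 0))
})

test_that("rendered raw signals place exact templates in Gaussian noise", {
  # all-zero case
  st0 <- SpikeTable(integer(0), numeric(0), duration = 0.1)
  r0 <- renderRawSignal(st0, noiseSd = 0, spikeAmplitude = 60,
                        samplingRate = 20000, duration = 0.1)
  expect_true(all(r0@channels == 0))
  # single template: extremum within 1 ms of the spike, exact magnitude
  st1 <- SpikeTable(0L, 0.5, duration = 1)
  r1 <- renderRawSignal(st1, noiseSd = 0, spikeAmplitude = 80,
                        samplingRate = 20000)
  x <- r1@channels[, 1]
  i <- which.max(abs(x))
  expect_equal(max(abs(x)), 80)
  expect_lt(abs((i - 1) / 20000 - 0.5), 0.001)
  # noise-only: sample sd close to requested
  rn <- renderRawSignal(st0, noiseSd = 5, spikeAmplitude = 60,
                        samplingRate = 20000, duration = 10, seed = 4)
  expect_equal(sd(rn@channels[, 1]), 5, tolerance = 0.02)
  # input validation
  expect_error(renderRawSignal(st1, duration = 0.2), "beyond")
  expect_error(renderRawSignal(st1, spikeAmplitude = 10), "20-200")
  expect_error(renderRawSignal(st1, samplingRate = 5000), "10 kHz")
})
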