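#' Construct a SpikeTable
#'
#' @param electrode integer electrode ids.
#' @param time_s spike times in seconds (0-based from recording start).
#' @param amplitude_uV signed peak amplitudes (uV); defaults to `NA`.
#' @param layout optional [ElectrodeLayout-class].
#' @param duration recording duration (s); defaults to the last spike time.
#' @param metadata list of provenance entries.
#' @return A [SpikeTable-class] sorted by time (ties by electrode).
#' @export
SpikeTable <- function(electrode, time_s, amplitude_uV = NA_real_,
                       layout = NULL, duration = NULL, metadata = list()) {
  df <- data.frame(electrode = as.integer(electrode),
                   time_s = as.numeric(time_s),
                   amplitude_uV = rep_len(as.numeric(amplitude_uV),
                                          length(time_s)))
  df <- df[order(df$time_s, df$electrode), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(duration))
    duration <- if (nrow(df)) max(df$time_s) else 0
  new("SpikeTable", spikes = df, layout = layout,
      duration = as.numeric(duration), metadata = metadata)
}

#' Configuration of the synthetic MEA generator
#'
#' Builds a validated [GeneratorConfig-class]. The defaults are the study
#' conditions the generator emulates: long superbursts containing 100-150
#' small planar-wave bursts of 30-50 ms at a ~11.2 Hz interburst-peak
#' frequency, initiation bursts of 50-100 ms with 1000-3000 spikes,
#' per-electrode intra-burst rates of 139 Hz, two motif directions 95 deg
#' apart, 91.5% within-superburst motif fidelity and equiprobable
#' (p = 0.5) type switching between consecutive superbursts.
#'
#' @param seed integer root seed; every random draw of
#'   [generateDataset()] derives from it.
#' @param nSuperbursts number of superbursts to generate.
#' @param pSwitch probability that a superburst's type differs from the
#'   previous one; 0.5 gives independent equiprobable types.
#' @param motifDirections two planar-wave propagation angles in degrees
#'   (counter-clockwise from +x), one per motif/type.
#' @param motifFidelity probability that a small burst carries its own
#'   superburst's motif (independently per burst).
#' @param smallBurstsPerSuperburst integer range (min, max) of small bursts
#'   per superburst.
#' @param ibpiMean,ibpiSd mean and sd (s) of the interburst peak interval;
#'   draws are truncated below so consecutive bursts cannot overlap.
#' @param smallBurstDuration range (s) of small-burst durations.
#' @param smallBurstSpikes optional integer range: exact total spikes per
#'   small burst. `NULL` (default) draws per-electrode counts from the
#'   `intraBurstRate` Poisson model instead.
#' @param initiationBurstDuration range (s) of initiation-burst durations.
#' @param initiationBurstSpikes integer range of total spikes per
#'   initiation burst. This is a population range: one recording-level mean
#'   is drawn from it and individual initiation bursts jitter around that
#'   mean (within-recording homogeneity, as in real recordings).
#' @param waveSpeed planar-wave propagation speed in um/ms.
#' @param latencyJitterSd sd (s) of the Gaussian first-spike latency jitter,
#'   truncated to the burst window.
#' @param intraBurstRate per-electrode spiking rate (Hz) inside small bursts.
#' @param backgroundRate per-electrode background rate (Hz) outside bursts.
#' @param interSuperburstGap range (s) of silent gaps between superbursts.
#' @param initiationPattern `"isotropic"` (default: initiation bursts carry
#'   no motif; latencies drawn uniformly) or `"wave"` (initiation bursts
#'   propagate along their superburst's own motif direction).
#' @return A [GeneratorConfig-class].
#' @seealso [generateDataset()]
#' @export
generatorConfig <- function(seed = 1L,
                            nSuperbursts = 10L,
                            pSwitch = 0.5,
                            motifDirections = c(29, 294),
                            motifFidelity = 0.915,
                            smallBurstsPerSuperburst = c(100L, 150L),
                            ibpiMean = 0.0893,
                            ibpiSd = 0.02,
                            smallBurstDuration = c(0.03, 0.05),
                            smallBurstSpikes = NULL,
                            initiationBurstDuration = c(0.05, 0.10),
                            initiationBurstSpikes = c(1000L, 3000L),
                            waveSpeed = 100,
                            latencyJitterSd = 0.002,
                            intraBurstRate = 139,
                            backgroundRate = 0.1,
                            interSuperburstGap = c(100, 200),
                            initiationPattern = c("isotropic", "wave")) {
  initiationPattern <- match.arg(initiationPattern)
  asRange <- function(x) if (length(x) == 1L) c(x, x) else sort(x[1:2])
  p <- list(seed = as.integer(seed),
            nSuperbursts = as.integer(nSuperbursts),
            pSwitch = pSwitch,
            motifDirections = motifDirections %% 360,
            motifFidelity = motifFidelity,
            smallBurstsPerSuperburst =
              as.integer(asRange(smallBurstsPerSuperburst)),
            ibpiMean = ibpiMean, ibpiSd = ibpiSd,
            smallBurstDuration = asRange(smallBurstDuration),
            smallBurstSpikes =
              if (is.null(smallBurstSpikes)) NULL
              else as.integer(asRange(smallBurstSpikes)),
            initiationBurstDuration = asRange(initiationBurstDuration),
            initiationBurstSpikes = as.integer(asRange(initiationBurstSpikes)),
            waveSpeed = waveSpeed,
            latencyJitterSd = latencyJitterSd,
            intraBurstRate = intraBurstRate,
            backgroundRate = backgroundRate,
            interSuperburstGap = asRange(interSuperburstGap),
            initiationPattern = initiationPattern)
  with(p, {
    stopifnot(nSuperbursts >= 1L,
              pSwitch >= 0, pSwitch <= 1,
              length(motifDirections) == 2L,
              motifFidelity >= 0, motifFidelity <= 1,
              all(smallBurstsPerSuperburst >= 1L),
              ibpiMean > 0, ibpiSd >= 0,
              all(smallBurstDuration > 0),
              all(initiationBurstDuration > 0),
              all(initiationBurstSpikes >= 59L),
              waveSpeed > 0, latencyJitterSd >= 0,
              intraBurstRate > 0, backgroundRate >= 0,
              all(interSuperburstGap > 0))
    if (circularAngleDifference(motifDirections[1], motifDirections[2]) == 0)
      stop("the two motif directions must differ by a non-zero circular angle")
    if (max(smallBurstDuration) + 0.005 >= ibpiMean)
      stop("small-burst durations overlap the interburst peak interval: ",
           "bursts would merge (need max(duration) + 5 ms < ibpiMean)")
    if (!is.null(smallBurstSpikes) && any(smallBurstSpikes < 59L))
      stop("smallBurstSpikes must allow one first spike per electrode")
  })
  new("GeneratorConfig", params = p)
}

#' Simulate a superburst type sequence
#'
#' Two-state type process used by the generator: the first type is drawn
#' equiprobably; each subsequent superburst switches type with probability
#' `pSwitch`. `pSwitch = 0.5` gives independent equiprobable types.
#'
#' @param n number of superbursts.
#' @param pSwitch switch probability in `[0, 1]`.
#' @param seed optional integer seed (set only when non-`NULL` so the
#'   generator can call this inside its own RNG stream).
#' @return Integer vector of types in `{1, 2}`.
#' @export
simulateTypes <- function(n, pSwitch = 0.5, seed = NULL) {
  stopifnot(n >= 1, pSwitch >= 0, pSwitch <= 1)
  if (!is.null(seed)) set.seed(seed)
  first <- sample(c(1L, 2L), 1L)
  if (n == 1L) return(first)
  switches <- stats::rbinom(n - 1L, 1L, pSwitch)
  1L + (cumsum(c(first - 1L, switches)) %% 2L)
}

## Draw an integer uniformly from an inclusive range.
.rint <- function(n, range) {
  if (range[1L] == range[2L]) rep.int(range[1L], n)
  else as.integer(range[1L] + floor(stats::runif(n) * (range[2L] - range[1L] + 1L)))
}

## m spike times in [lo + tau, hi) with pairwise gaps >= tau (uniform order
## statistics stretched by the dead time). m is capped at feasibility; the
## realized times are returned sorted.
.spacedTimes <- function(m, lo, hi, tau = 0.001) {
  if (m < 1L) return(numeric(0))
  mMax <- max(floor((hi - lo - tau) / tau), 0L)
  m <- min(m, mMax)
  if (m < 1L) return(numeric(0))
  slack <- (hi - lo - tau) - (m - 1L) * tau
  u <- sort(stats::runif(m, 0, slack))
  lo + tau + u + (seq_len(m) - 1L) * tau
}

## Realize one burst on all electrodes: planted first-spike latencies plus
## per-electrode extra spikes with a 1 ms dead time (the spike table's
## refractory contract). extraPerElectrode is a length-nEl count vector.
.realizeBurst <- function(lat, dur, extraPerElectrode) {
  nEl <- length(lat)
  eOut <- vector("list", nEl); tOut <- vector("list", nEl)
  for (e in seq_len(nEl)) {
    ts <- .spacedTimes(extraPerElectrode[e], lat[e], dur)
    eOut[[e]] <- rep.int(e, length(ts) + 1L)
    tOut[[e]] <- c(lat[e], ts)
  }
  list(electrode = unlist(eOut), time = unlist(tOut))
}

## Planar-wave first-spike latencies (s) over a layout, direction in degrees.
.waveLatencies <- function(layout, directionDeg, waveSpeed, jitterSd, dur) {
  theta <- directionDeg * pi / 180
  proj <- layout@positions %*% c(cos(theta), sin(theta))
  lat <- (proj - min(proj)) / (waveSpeed * 1000)   # um / (um/ms) -> ms -> s
  if (jitterSd > 0) lat <- lat + stats::rnorm(length(lat), 0, jitterSd)
  pmin(pmax(as.vector(lat), 0), dur * 0.98)
}

#' Generate a ground-truthed synthetic MEA dataset
#'
#' Simulates spike tables with the nested structure the analysis pipeline
#' assumes: superbursts of a planted type, each opened by a motif-neutral
#' initiation burst and followed by a train of small bursts realized as
#' planar waves (per-electrode first-spike latency = projection of the
#' electrode position onto the motif direction divided by the wave speed,
#' plus truncated Gaussian jitter, followed by Poisson spiking for the rest
#' of the burst window). Background spikes are placed only outside burst
#' windows, so every planted spike lies in exactly one burst window or is
#' background.
#'
#' All randomness derives from `config@params$seed`; identical configs give
#' byte-identical outputs.
#'
#' @param config a [GeneratorConfig-class].
#' @param layout an [ElectrodeLayout-class] (default [standardLayout()]).
#' @return A list with elements `spikes` (a [SpikeTable-class]) and
#'   `truth` (a [GroundTruth-class]).
#' @examples
#' ds <- generateDataset(generatorConfig(nSuperbursts = 2,
#'   smallBurstsPerSuperburst = c(10, 10), seed = 7))
#' nrow(ds$truth@bursts)   # 22: 2 initiation + 20 small
#' @export
generateDataset <- function(config, layout = standardLayout()) {
  stopifnot(is(config, "GeneratorConfig"), is(layout, "ElectrodeLayout"))
  p <- config@params
  nEl <- length(layout@ids)
  set.seed(p$seed)

  types <- simulateTypes(p$nSuperbursts, p$pSwitch)
  nSmall <- .rint(p$nSuperbursts, p$smallBurstsPerSuperburst)

  ## initiation-burst sizes are homogeneous within a recording: the
  ## configured range is a population range across cultures, so one
  ## recording-level mean is drawn from it and per-burst counts jitter
  ## around that mean (within the configured bounds)
  iRange <- p$initiationBurstSpikes
  iJit <- diff(iRange) / 8
  iMu <- stats::runif(1, iRange[1] + iJit, iRange[2] - iJit)
  iDraw <- function() .rint(1L, as.integer(round(c(iMu - iJit, iMu + iJit))))

  burstRows <- list()
  latList <- list()
  spkE <- list(); spkT <- list()
  sbRows <- data.frame(sb_id = seq_len(p$nSuperbursts), start_s = NA_real_,
                       end_s = NA_real_, type = types, n_small = nSmall)
  tcur <- 10
  bid <- 0L
  minIbpi <- max(p$smallBurstDuration) + 0.005

  for (i in seq_len(p$nSuperbursts)) {
    own <- types[i]
    other <- 3L - own
    keep <- stats::rbinom(nSmall[i], 1L, p$motifFidelity) == 1L
    motifs <- ifelse(keep, own, other)

    ## initiation burst
    dI <- stats::runif(1, p$initiationBurstDuration[1],
                       p$initiationBurstDuration[2])
    nI <- iDraw()
    if (p$initiationPattern == "wave") {
      latI <- .waveLatencies(layout, p$motifDirections[own], p$waveSpeed,
                             p$latencyJitterSd, dI)
      dirI <- p$motifDirections[own]
    } else {
      latI <- stats::runif(nEl, 0, dI * 0.5)
      dirI <- NA_real_
    }
    extraI <- tabulate(sample.int(nEl, nI - nEl, replace = TRUE), nEl)
    rb <- .realizeBurst(latI, dI, extraI)
    bid <- bid + 1L
    burstRows[[bid]] <- data.frame(burst_id = bid, sb_id = i,
      start_s = tcur, end_s = tcur + dI, peak_s = tcur,
      n_spikes = length(rb$electrode), class = "initiation",
      motif = NA_integer_, direction_deg = dirI)
    latList[[bid]] <- latI
    spkE[[bid]] <- layout@ids[rb$electrode]
    spkT[[bid]] <- tcur + rb$time
    sbRows$start_s[i] <- tcur

    ## small bursts
    bstart <- tcur
    prevEnd <- tcur + dI
    for (k in seq_len(nSmall[i])) {
      ib <- if (p$ibpiSd > 0)
        max(stats::rnorm(1, p$ibpiMean, p$ibpiSd), minIbpi)
      else p$ibpiMean
      ## never overlap the previous burst (the initiation burst may be
      ## longer than one interburst interval)
      bstart <- max(bstart + ib, prevEnd + 0.005)
      dS <- stats::runif(1, p$smallBurstDuration[1], p$smallBurstDuration[2])
      lat <- .waveLatencies(layout, p$motifDirections[motifs[k]],
                            p$waveSpeed, p$latencyJitterSd, dS)
      extra <- if (is.null(p$smallBurstSpikes)) {
        ## count model 1 + Poisson(rate*dur - 1): the first spike is part of
        ## the budget, keeping the spikes/duration estimator unbiased
        stats::rpois(nEl, max(p$intraBurstRate * dS - 1, 0))
      } else {
        nS <- .rint(1L, p$smallBurstSpikes)
        tabulate(sample.int(nEl, max(nS - nEl, 0L), replace = TRUE), nEl)
      }
      rb <- .realizeBurst(lat, dS, extra)
      bid <- bid + 1L
      burstRows[[bid]] <- data.frame(burst_id = bid, sb_id = i,
        start_s = bstart, end_s = bstart + dS, peak_s = bstart,
        n_spikes = length(rb$electrode), class = "small",
        motif = motifs[k],
        direction_deg = p$motifDirections[motifs[k]])
      latList[[bid]] <- lat
      spkE[[bid]] <- layout@ids[rb$electrode]
      spkT[[bid]] <- bstart + rb$time
      prevEnd <- bstart + dS
    }
    sbRows$end_s[i] <- burstRows[[bid]]$end_s
    tcur <- sbRows$end_s[i] +
      stats::runif(1, p$interSuperburstGap[1], p$interSuperburstGap[2])
  }

  gt <- do.call(rbind, burstRows)
  duration <- max(gt$end_s) + 10

  ## background spikes, rejected inside any burst window
  allE <- unlist(spkE); allT <- unlist(spkT)
  if (p$backgroundRate > 0) {
    nBg <- stats::rpois(1, p$backgroundRate * nEl * duration)
    if (nBg > 0) {
      bgT <- stats::runif(nBg, 0, duration)
      bgE <- sample.int(nEl, nBg, replace = TRUE)
      ## keep background clear of burst windows (with the 1 ms refractory
      ## margin) and impose the dead time within each electrode
      bnd <- as.vector(rbind(gt$start_s - 0.001, gt$end_s + 0.001))
      outside <- findInterval(bgT, bnd) %% 2L == 0L
      bgT <- bgT[outside]; bgE <- bgE[outside]
      o <- order(bgE, bgT)
      bgT <- bgT[o]; bgE <- bgE[o]
      if (length(bgT) > 1L) {
        ok <- c(TRUE, diff(bgT) >= 0.001 | diff(bgE) != 0L)
        bgT <- bgT[ok]; bgE <- bgE[ok]
      }
      allE <- c(allE, layout@ids[bgE]); allT <- c(allT, bgT)
    }
  }
  amp <- -stats::runif(length(allT), 20, 200)

  st <- SpikeTable(allE, allT, amp, layout = layout, duration = duration,
                   metadata = list(generator = p))
  truth <- new("GroundTruth", bursts = gt, superbursts = sbRows,
               latencies = latList, config = config)
  list(spikes = st, truth = truth)
}
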