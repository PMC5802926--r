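#' Total spiking rate (TSR) of a recording
#'
#' Counts spikes from all electrodes in consecutive half-open time bins
#' (`[0, bw)`, `[bw, 2bw)`, ...). The 5 ms default is the resolution at
#' which network bursts are defined.
#'
#' @param spikes a non-empty [SpikeTable-class].
#' @param binWidth bin width in seconds (default 0.005).
#' @return A [TSRSeries-class] whose counts sum to the spike count.
#' @export
computeTSR <- function(spikes, binWidth = 0.005) {
  stopifnot(is(spikes, "SpikeTable"))
  if (binWidth <= 0) stop("binWidth must be positive")
  df <- spikes@spikes
  if (!nrow(df)) stop("cannot compute the TSR of an empty spike table")
  nBins <- max(ceiling(spikes@duration / binWidth), 1L)
  idx <- pmin(floor(df$time_s / binWidth) + 1L, nBins)
  new("TSRSeries", binWidth = binWidth,
      counts = as.numeric(tabulate(idx, nBins)))
}

## Bin centre times of a TSRSeries.
.binCentres <- function(tsr) {
  (seq_along(tsr@counts) - 0.5) * tsr@binWidth
}

#' Detect network bursts from the TSR
#'
#' Maximal runs of bins with `TSR > T_burst` become network bursts, where
#' `T_burst = coeff * sd(TSR)` (coefficient 0.2 by default). Each burst's
#' start is adjusted to the first spike from any electrode at or after the
#' supra-threshold crossing; the end is the start of the first bin at which
#' the TSR falls back below threshold. The burst peak is the centre of the
#' (earliest) maximal TSR bin inside the burst.
#'
#' Runs separated by at least `minGapBins` sub-threshold bins are distinct
#' bursts; smaller gaps are merged.
#'
#' @param tsr a [TSRSeries-class] computed from `spikes`.
#' @param spikes the [SpikeTable-class] the TSR was computed from.
#' @param coeff burst threshold coefficient (default 0.2).
#' @param minGapBins minimum number of sub-threshold bins separating two
#'   bursts (default 1, i.e. no merging).
#' @return A [BurstSequence-class] with all bursts labelled `unclassified`;
#'   `metadata` records the threshold and `sd(TSR)`. A constant TSR
#'   (`sd = 0`) yields no bursts with a warning.
#' @export
detectBursts <- function(tsr, spikes, coeff = 0.2, minGapBins = 1L) {
  stopifnot(is(tsr, "TSRSeries"), is(spikes, "SpikeTable"), coeff > 0)
  counts <- tsr@counts
  bw <- tsr@binWidth
  sdTSR <- stats::sd(counts)
  emptySeq <- function(meta) new("BurstSequence",
    bursts = data.frame(burst_id = integer(0), start_s = numeric(0),
                        end_s = numeric(0), peak_s = numeric(0),
                        n_spikes = integer(0), class = character(0)),
    metadata = meta)
  if (is.na(sdTSR) || sdTSR == 0) {
    warning("constant TSR: burst threshold undefined, no bursts detected")
    return(emptySeq(list(threshold = NA_real_, sd_tsr = sdTSR,
                         coeff = coeff)))
  }
  thr <- coeff * sdTSR
  above <- counts > thr
  meta <- list(threshold = thr, sd_tsr = sdTSR, coeff = coeff,
               bin_width_s = bw)
  if (!any(above)) return(emptySeq(meta))

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (minGapBins > 1L && nrow(runs) > 1L) {
    gap <- runs$start[-1L] - runs$end[-nrow(runs)] - 1L
    keepBreak <- gap >= minGapBins
    grp <- cumsum(c(TRUE, keepBreak))
    runs <- data.frame(start = tapply(runs$start, grp, min),
                       end = tapply(runs$end, grp, max))
  }

  st <- spikes@spikes$time_s
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    crossT <- (runs$start[i] - 1L) * bw
    endT <- if (runs$end[i] < length(counts)) runs$end[i] * bw
            else length(counts) * bw
    ## first spike at or after the crossing
    k <- findInterval(crossT, st, left.open = TRUE) + 1L
    if (k > length(st) || st[k] >= endT) next  # supra-threshold bin w/o spikes
    startT <- st[k]
    nSpk <- findInterval(endT, st, left.open = TRUE) -
      findInterval(startT, st, left.open = TRUE)
    seg <- runs$start[i]:runs$end[i]
    pk <- seg[which.max(counts[seg])]
    peakT <- (pk - 0.5) * bw
    peakT <- min(max(peakT, startT), endT - 1e-9)
    out[[i]] <- data.frame(start_s = startT, end_s = endT, peak_s = peakT,
                           n_spikes = nSpk)
  }
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(emptySeq(meta))
  out <- data.frame(burst_id = seq_len(nrow(out)), out,
                    class = "unclassified")
  rownames(out) <- NULL
  new("BurstSequence", bursts = out, metadata = meta)
}

#' Interburst peak intervals and instantaneous frequencies
#'
#' IBPI_i is the interval between the TSR peak times of consecutive bursts;
#' its reciprocal is the instantaneous frequency (IF) of the pair. By
#' default only small bursts enter, and when superbursts are supplied the
#' intervals are computed within each superburst only (never across the
#' silent gaps), with initiation bursts excluded. Because IF distributions
#' are typically non-normal, the median IF is the recommended per-recording
#' summary and is returned alongside.
#'
#' @param seq a [BurstSequence-class].
#' @param superbursts optional [SuperburstSet-class]; when given, pairs are
#'   restricted to bursts of the same superburst.
#' @param smallOnly restrict to bursts labelled `small` (default TRUE; set
#'   FALSE for unclassified sequences).
#' @return A list with `ibpi_s`, `if_hz` (numeric vectors, empty when fewer
#'   than two eligible bursts) and `median_if_hz`.
#' @export
computeIBPI <- function(seq, superbursts = NULL, smallOnly = TRUE) {
  stopifnot(is(seq, "BurstSequence"))
  df <- seq@bursts
  if (smallOnly) df <- df[df$class == "small", , drop = FALSE]
  grp <- if (!is.null(superbursts)) {
    stopifnot(is(superbursts, "SuperburstSet"))
    m <- rep(NA_integer_, nrow(df))
    for (i in seq_along(superbursts@members))
      m[df$burst_id %in% superbursts@members[[i]]] <- i
    m
  } else rep(1L, nrow(df))
  keep <- !is.na(grp)
  df <- df[keep, , drop = FALSE]; grp <- grp[keep]
  ibpi <- unlist(lapply(split(df$peak_s, grp), function(p)
    if (length(p) >= 2L) diff(sort(p)) else numeric(0)), use.names = FALSE)
  if (!length(ibpi))
    return(list(ibpi_s = numeric(0), if_hz = numeric(0),
                median_if_hz = NA_real_))
  list(ibpi_s = ibpi, if_hz = 1 / ibpi,
       median_if_hz = stats::median(1 / ibpi))
}

#' Split bursts into initiation vs small bursts
#'
#' Two-means clustering (k = 2) on the spikes-per-burst counts. In one
#' dimension the K-means optimum is a contiguous split of the sorted
#' values, so it is computed exactly (prefix-sum scan over all split
#' points) rather than by Lloyd iterations. The cluster with the larger
#' mean becomes the initiation class; the boundary threshold reported is
#' the midpoint between the largest small-burst count and the smallest
#' initiation-burst count.
#'
#' @param seq a [BurstSequence-class] with at least 2 bursts.
#' @param seed kept for interface stability; the exact solution is
#'   deterministic.
#' @return The sequence with `class` set to `initiation`/`small` and
#'   `metadata$class_threshold` recorded. If all counts are identical the
#'   bursts are all labelled `small` with a warning.
#' @export
classifyBursts <- function(seq, seed = 1L) {
  stopifnot(is(seq, "BurstSequence"))
  df <- seq@bursts
  if (nrow(df) < 2L) stop("need at least 2 bursts to classify")
  n <- df$n_spikes
  if (length(unique(n)) < 2L) {
    warning("all burst spike counts identical: labelling all bursts small")
    df$class <- "small"
    meta <- seq@metadata
    meta$class_threshold <- NA_real_
    return(new("BurstSequence", bursts = df, metadata = meta))
  }
  xs <- sort(n)
  m <- length(xs)
  csum <- cumsum(xs); csq <- cumsum(xs^2)
  lo <- seq_len(m - 1L)
  wcssLow <- csq[lo] - csum[lo]^2 / lo
  hiN <- m - lo
  wcssHigh <- (csq[m] - csq[lo]) - (csum[m] - csum[lo])^2 / hiN
  cut <- which.min(wcssLow + wcssHigh)
  thr <- (xs[cut] + xs[cut + 1L]) / 2
  init <- n > thr
  df$class <- ifelse(init, "initiation", "small")
  meta <- seq@metadata
  meta$class_threshold <- thr
  new("BurstSequence", bursts = df, metadata = meta)
}

#' Per-electrode spiking rate inside small bursts
#'
#' For each electrode: spikes falling in small-burst windows divided by the
#' summed small-burst duration. Electrodes with no intra-burst spikes get a
#' rate of 0 and are flagged inactive (excluded from active-electrode
#' summaries).
#'
#' @param seq a classified [BurstSequence-class] containing small bursts.
#' @param spikes the matching [SpikeTable-class].
#' @return data.frame with columns `electrode`, `rate_hz`, `active`.
#' @export
intraBurstRate <- function(seq, spikes) {
  stopifnot(is(seq, "BurstSequence"), is(spikes, "SpikeTable"))
  small <- seq@bursts[seq@bursts$class == "small", , drop = FALSE]
  if (!nrow(small)) stop("no small bursts: classify bursts first")
  totDur <- sum(small$end_s - small$start_s)
  df <- spikes@spikes
  bnd <- as.vector(rbind(small$start_s, small$end_s))
  inside <- findInterval(df$time_s, bnd) %% 2L == 1L
  ids <- if (!is.null(spikes@layout)) spikes@layout@ids
         else sort(unique(df$electrode))
  cnt <- table(factor(df$electrode[inside], levels = ids))
  out <- data.frame(electrode = ids, rate_hz = as.numeric(cnt) / totDur)
  out$active <- out$rate_hz > 0
  out
}
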