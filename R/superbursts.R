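#' Detect superbursts by Gaussian-kernel correlation of the TSR
#'
#' The TSR is correlated with a wide Gaussian kernel (effective width =
#' full width at half maximum, 50 s by default; support truncated at
#' +/- 2 x FWHM; normalized to unit sum), evaluated on a regular time grid
#' (10 ms step). Maximal runs where the correlation exceeds
#' `coeff * sd(correlation)` are superbursts; member bursts are those whose
#' TSR peak lies inside the run.
#'
#' @param tsr a [TSRSeries-class].
#' @param seq optional [BurstSequence-class] used to assign member bursts.
#' @param width Gaussian effective width (FWHM) in seconds (default 50).
#' @param step evaluation step in seconds (default 0.01).
#' @param coeff threshold coefficient on the correlation sd (default 0.4).
#' @return A [SuperburstSet-class]; `length_class` is `unclassified` until
#'   [classifySuperburstLength()] is applied. A constant correlation yields
#'   none, with a warning.
#' @export
detectSuperbursts <- function(tsr, seq = NULL, width = 50, step = 0.01,
                              coeff = 0.4) {
  stopifnot(is(tsr, "TSRSeries"), width > 0, step > 0, coeff > 0)
  bw <- tsr@binWidth
  counts <- tsr@counts
  emptySet <- function(meta) new("SuperburstSet",
    superbursts = data.frame(sb_id = integer(0), start_s = numeric(0),
                             end_s = numeric(0), n_bursts = integer(0),
                             length_class = character(0),
                             type = integer(0)),
    members = list(), metadata = meta)

  sdK <- width / (2 * sqrt(2 * log(2)))          # FWHM -> Gaussian sd
  half <- ceiling(2 * width / bw)                 # support +/- 2 FWHM
  kt <- (-half:half) * bw
  kern <- exp(-kt^2 / (2 * sdK^2))
  kern <- kern / sum(kern)

  ## full cross-correlation c(t) = sum_tau TSR(tau) g(tau - t) at bin centres
  n <- length(counts)
  full <- stats::convolve(counts, kern, type = "open")  # length n + 2*half
  cc <- full[(half + 1L):(half + n)]

  stride <- max(round(step / bw), 1L)
  gridIdx <- seq(1L, n, by = stride)
  cg <- cc[gridIdx]
  gridT <- (gridIdx - 0.5) * bw
  meta <- list(width_s = width, step_s = step, coeff = coeff)
  sdC <- stats::sd(cg)
  if (is.na(sdC) || sdC == 0) {
    warning("constant TSR correlation: no superbursts detected")
    return(emptySet(meta))
  }
  thr <- coeff * sdC
  meta$threshold <- thr
  above <- cg > thr
  if (!any(above)) return(emptySet(meta))

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rs <- starts[r$values]; re <- ends[r$values]
  startT <- gridT[rs]
  endT <- ifelse(re < length(gridT), gridT[re + 1L],
                 gridT[length(gridT)] + step)

  members <- vector("list", length(rs))
  nb <- integer(length(rs))
  if (!is.null(seq)) {
    stopifnot(is(seq, "BurstSequence"))
    pk <- seq@bursts$peak_s
    for (i in seq_along(rs)) {
      inb <- which(pk >= startT[i] & pk < endT[i])
      members[[i]] <- seq@bursts$burst_id[inb]
      nb[i] <- length(inb)
    }
  }
  df <- data.frame(sb_id = seq_along(rs), start_s = startT, end_s = endT,
                   n_bursts = nb, length_class = "unclassified",
                   type = NA_integer_)
  new("SuperburstSet", superbursts = df, members = members, metadata = meta)
}

#' Classify superbursts as regular vs long
#'
#' A superburst is `long` when it contains at least `minSmallLong` member
#' small bursts, else `regular`. The default boundary (21) sits just above
#' the 3-20 small bursts typical of regular superbursts, separating them
#' from long superbursts with up to hundreds.
#'
#' @param sbs a [SuperburstSet-class] with member bursts assigned.
#' @param seq the classified [BurstSequence-class].
#' @param minSmallLong minimum member small bursts for the `long` class.
#' @return The [SuperburstSet-class] with `length_class` filled in.
#'   Superbursts with zero member bursts are dropped with a warning.
#' @export
classifySuperburstLength <- function(sbs, seq, minSmallLong = 21L) {
  stopifnot(is(sbs, "SuperburstSet"), is(seq, "BurstSequence"),
            minSmallLong >= 1L)
  df <- sbs@superbursts
  members <- sbs@members
  if (!nrow(df)) return(sbs)
  cls <- seq@bursts$class[match(unlist(members), seq@bursts$burst_id)]
  nSmall <- vapply(seq_along(members), function(i) {
    m <- match(members[[i]], seq@bursts$burst_id)
    sum(seq@bursts$class[m] == "small")
  }, integer(1))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning(sum(empty), " superburst(s) with no member bursts dropped")
    df <- df[!empty, , drop = FALSE]
    members <- members[!empty]
    nSmall <- nSmall[!empty]
    df$sb_id <- seq_len(nrow(df))
  }
  df$length_class <- ifelse(nSmall >= minSmallLong, "long", "regular")
  new("SuperburstSet", superbursts = df, members = members,
      metadata = c(sbs@metadata, list(min_small_long = minSmallLong)))
}
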