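#' First-spike activation patterns of bursts
#'
#' The activation pattern of a burst is the vector of per-electrode
#' first-spike latencies relative to the burst start; electrodes that stay
#' silent during the burst are missing (`NA`).
#'
#' `activationPatterns()` computes patterns for several bursts at once and
#' returns a matrix (bursts x electrodes, `NA` = missing) with attribute
#' `completeness` (per-burst fraction of electrodes with a spike).
#' `activationPattern()` is the single-burst form.
#'
#' @param seq a [BurstSequence-class].
#' @param spikes the matching [SpikeTable-class].
#' @param which integer vector of burst ids (default: all).
#' @param layout an [ElectrodeLayout-class] defining the electrode set and
#'   column order; defaults to the spike table's layout.
#' @return A numeric matrix of latencies in seconds with one column per
#'   layout electrode and rownames the burst ids.
#' @export
activationPatterns <- function(seq, spikes, which = NULL, layout = NULL) {
  stopifnot(is(seq, "BurstSequence"), is(spikes, "SpikeTable"))
  if (is.null(layout)) layout <- spikes@layout
  if (is.null(layout)) stop("an electrode layout is required")
  df <- seq@bursts
  if (!is.null(which)) df <- df[df$burst_id %in% which, , drop = FALSE]
  if (!nrow(df)) stop("no bursts selected")
  sp <- spikes@spikes
  nEl <- length(layout@ids)
  out <- matrix(NA_real_, nrow(df), nEl,
                dimnames = list(df$burst_id, layout@ids))
  st <- sp$time_s
  for (i in seq_len(nrow(df))) {
    a <- findInterval(df$start_s[i], st, left.open = TRUE) + 1L
    b <- findInterval(df$end_s[i], st, left.open = TRUE)
    if (a > b) next
    idx <- a:b
    first <- tapply(st[idx], factor(sp$electrode[idx], levels = layout@ids),
                    min)
    out[i, ] <- as.numeric(first) - df$start_s[i]
  }
  comp <- rowMeans(!is.na(out))
  if (any(rowSums(!is.na(out)) == 0))
    stop("burst without any spike in its window: check burst/spike pairing")
  attr(out, "completeness") <- comp
  out
}

#' @rdname activationPatterns
#' @param burstId a single burst id.
#' @return `activationPattern()`: a named numeric vector of latencies.
#' @export
activationPattern <- function(seq, spikes, burstId, layout = NULL) {
  m <- activationPatterns(seq, spikes, which = burstId, layout = layout)
  stats::setNames(m[1L, ], colnames(m))
}

## Grid neighbours (incl. self and diagonals) within radius pitches.
.neighbourList <- function(layout, neighbourRadius = 1) {
  pitch <- nearestNeighbourDistance(layout)
  rad <- neighbourRadius * pitch * sqrt(2) + 1e-6
  d <- as.matrix(stats::dist(layout@positions))
  lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= rad))
}

## Least-squares plane fit of z over (x, y); returns gradient c(dz/dx, dz/dy)
## or NULL when fewer than 3 points or collinear geometry.
.planeGradient <- function(x, y, z) {
  ok <- !is.na(z)
  if (sum(ok) < 3L) return(NULL)
  X <- cbind(1, x[ok], y[ok])
  if (qr(X)$rank < 3L) return(NULL)
  beta <- qr.coef(qr(X), z[ok])
  beta[2:3]
}

#' Activation-timing gradient vector field (dynamic pattern)
#'
#' For each electrode, fits a least-squares plane to the first-spike
#' latencies over the electrode and its grid neighbours within
#' `neighbourRadius` pitches (at least 3 non-missing, non-collinear points
#' required, else the vector is missing). The fitted spatial gradient
#' (units s/um) points from early to late activation, i.e. in the direction
#' of spike propagation. The major direction is the angle of the
#' arithmetic, magnitude-weighted mean of all defined vectors; an
#' unweighted unit-vector mean is available via `weighted = FALSE`.
#'
#' @param latencies named numeric vector of per-electrode latencies (s),
#'   `NA` = missing, in layout order (as produced by
#'   [activationPattern()]).
#' @param layout the [ElectrodeLayout-class].
#' @param neighbourRadius neighbourhood radius in units of the grid pitch
#'   (default 1, i.e. up to 8 lattice neighbours).
#' @param completenessFloor minimum fraction of non-missing electrodes
#'   (default 0.5); patterns below it are rejected.
#' @param minMeanLength floor on the mean vector length below which the
#'   major direction is undefined (`NA`), e.g. for constant latency fields.
#' @param weighted use the magnitude-weighted (arithmetic) vector mean
#'   (default) or the unit-vector mean.
#' @return A [DynamicPattern-class].
#' @export
dynamicPattern <- function(latencies, layout, neighbourRadius = 1,
                           completenessFloor = 0.5,
                           minMeanLength = 1e-12, weighted = TRUE,
                           neighbours = NULL) {
  stopifnot(is(layout, "ElectrodeLayout"))
  nEl <- length(layout@ids)
  stopifnot(length(latencies) == nEl)
  if (mean(!is.na(latencies)) < completenessFloor)
    stop("activation pattern below the completeness floor (",
         completenessFloor, ")")
  pos <- layout@positions
  if (is.null(neighbours))
    neighbours <- .neighbourList(layout, neighbourRadius)
  vec <- matrix(NA_real_, nEl, 2, dimnames = list(layout@ids, c("vx", "vy")))
  for (i in seq_len(nEl)) {
    nb <- neighbours[[i]]
    g <- .planeGradient(pos[nb, 1], pos[nb, 2], latencies[nb])
    if (!is.null(g)) vec[i, ] <- g
  }
  ok <- !is.na(vec[, 1])
  if (!any(ok))
    stop("no electrode had 3 usable neighbours: pattern rejected")
  vs <- vec[ok, , drop = FALSE]
  mv <- if (weighted) colMeans(vs) else {
    len <- sqrt(rowSums(vs^2))
    nz <- len > 0
    if (!any(nz)) c(0, 0) else colMeans(vs[nz, , drop = FALSE] / len[nz])
  }
  mvl <- sqrt(sum(mv^2))
  ang <- if (mvl < minMeanLength) NA_real_
         else .wrap360(atan2(mv[2], mv[1]) * 180 / pi)
  new("DynamicPattern", vectors = vec, majorDirection = unname(ang),
      meanVectorLength = mvl, layout = layout)
}

#' Mean dynamic pattern over several bursts
#'
#' Averages first-spike latencies electrode-wise over a set of activation
#' patterns (missing entries skipped; electrodes missing in every pattern
#' stay missing) and computes the dynamic pattern of the averaged field.
#'
#' @param patterns matrix of activation patterns (bursts x electrodes) as
#'   produced by [activationPatterns()].
#' @param layout the [ElectrodeLayout-class].
#' @param ... passed to [dynamicPattern()].
#' @return A [DynamicPattern-class].
#' @export
meanDynamicPattern <- function(patterns, layout, ...) {
  if (is.null(dim(patterns)) || !nrow(patterns))
    stop("need at least one activation pattern")
  meanLat <- colMeans(patterns, na.rm = TRUE)
  meanLat[!is.finite(meanLat)] <- NA_real_
  dynamicPattern(meanLat, layout, ...)
}

#' Major propagation directions of many bursts
#'
#' Convenience wrapper: computes the dynamic pattern of every row of a
#' pattern matrix and returns the major direction angles.
#'
#' @inheritParams meanDynamicPattern
#' @return Named numeric vector of angles in degrees (`NA` where the
#'   pattern was rejected or the direction undefined).
#' @export
majorDirections <- function(patterns, layout, neighbourRadius = 1, ...) {
  nb <- .neighbourList(layout, neighbourRadius)
  ang <- rep(NA_real_, nrow(patterns))
  names(ang) <- rownames(patterns)
  for (i in seq_len(nrow(patterns))) {
    dp <- tryCatch(
      dynamicPattern(patterns[i, ], layout, neighbours = nb, ...),
      error = function(e) NULL)
    if (!is.null(dp)) ang[i] <- dp@majorDirection
  }
  ang
}

#' Plot a dynamic pattern as an arrow field
#'
#' @param dp a [DynamicPattern-class].
#' @param scale arrow length scale relative to the grid pitch.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `dp`.
#' @export
plotDynamicPattern <- function(dp, scale = 0.8, ...) {
  stopifnot(is(dp, "DynamicPattern"))
  pos <- dp@layout@positions
  v <- dp@vectors
  ok <- stats::complete.cases(v)
  len <- sqrt(rowSums(v[ok, , drop = FALSE]^2))
  s <- scale * nearestNeighbourDistance(dp@layout) / max(len, 1e-300)
  graphics::plot(pos, asp = 1, pch = 16, cex = 0.5,
                 xlab = "x (um)", ylab = "y (um)", ...)
  graphics::arrows(pos[ok, 1], pos[ok, 2],
                   pos[ok, 1] + v[ok, 1] * s, pos[ok, 2] + v[ok, 2] * s,
                   length = 0.05, col = "steelblue")
  invisible(dp)
}
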