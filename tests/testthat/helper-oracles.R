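# Independent reference implementations (oracles) and fixture builders.
# These deliberately re-derive results with the most literal possible code,
# sharing nothing with the package internals they check.

# Literal bin-scanning network-burst detector: bin the spikes, threshold at
# coeff * sd, walk the bins one by one.
naiveBurstScan <- function(times, duration, binWidth = 0.005, coeff = 0.2) {
  nBins <- max(ceiling(duration / binWidth), 1)
  counts <- numeric(nBins)
  for (t in times) {
    i <- min(floor(t / binWidth) + 1, nBins)
    counts[i] <- counts[i] + 1
  }
  s <- sd(counts)
  if (is.na(s) || s == 0) return(NULL)
  thr <- coeff * s
  res <- list()
  i <- 1
  while (i <= nBins) {
    if (counts[i] > thr) {
      j <- i
      while (j < nBins && counts[j + 1] > thr) j <- j + 1
      crossT <- (i - 1) * binWidth
      endT <- if (j < nBins) j * binWidth else nBins * binWidth
      cand <- times[times >= crossT]
      if (length(cand) && min(cand) < endT) {
        startT <- min(cand)
        seg <- i:j
        pk <- seg[which.max(counts[seg])]
        peakT <- (pk - 0.5) * binWidth
        peakT <- min(max(peakT, startT), endT - 1e-9)
        res[[length(res) + 1]] <- data.frame(
          start_s = startT, end_s = endT, peak_s = peakT,
          n_spikes = sum(times >= startT & times < endT))
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(res)) NULL else do.call(rbind, res)
}

# Exhaustive optimal 1-D 2-partition by within-cluster sum of squares.
best1d2split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf; bestCut <- 1
  for (m in 1:(n - 1)) {
    a <- xs[1:m]; b <- xs[(m + 1):n]
    w <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (w < best) { best <- w; bestCut <- m }
  }
  # TRUE = member of the upper (large-count) cluster
  x >= (xs[bestCut] + xs[bestCut + 1]) / 2
}

# Brute-force Davies-Bouldin recomputation with explicit loops.
bruteDB <- function(features, labels) {
  features <- as.matrix(features)
  labs <- sort(unique(labels))
  k <- length(labs)
  cent <- list(); S <- numeric(k)
  for (i in seq_len(k)) {
    m <- features[labels == labs[i], , drop = FALSE]
    cent[[i]] <- colMeans(m)
    dsum <- 0
    for (r in seq_len(nrow(m)))
      dsum <- dsum + sqrt(sum((m[r, ] - cent[[i]])^2))
    S[i] <- dsum / nrow(m)
  }
  tot <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (S[i] + S[j]) / M)
    }
    tot <- tot + worst
  }
  tot / k
}

# Planar-wave latency field over a layout (seconds), by direct projection.
planarPattern <- function(layout, angleDeg, waveSpeed = 100, jitterSd = 0) {
  th <- angleDeg * pi / 180
  proj <- layout@positions %*% c(cos(th), sin(th))
  lat <- (proj - min(proj)) / (waveSpeed * 1000)
  if (jitterSd > 0) lat <- lat + rnorm(length(lat), 0, jitterSd)
  as.vector(pmax(lat, 0))
}

# Rotate a layout's coordinates about their centroid.
rotateLayout <- function(layout, thetaDeg) {
  th <- thetaDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p <- layout@positions
  ctr <- colMeans(p)
  q <- t(R %*% t(sweep(p, 2, ctr))) + rep(ctr, each = nrow(p))
  colnames(q) <- c("x", "y")
  new("ElectrodeLayout", ids = layout@ids, positions = q)
}

# Small, fast generator configuration for structural tests.
smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nSuperbursts = 2L, smallBurstsPerSuperburst = c(10L, 10L),
                   interSuperburstGap = c(30, 40), backgroundRate = 0,
                   seed = 1L)
  do.call(generatorConfig, utils::modifyList(defaults, args))
}

# BurstSequence / SuperburstSet built from a generator's ground truth,
# bypassing detection (for testing the downstream stages in isolation).
gtBurstSequence <- function(truth) {
  df <- truth@bursts[, c("burst_id", "start_s", "end_s", "peak_s",
                         "n_spikes", "class")]
  rownames(df) <- NULL
  new("BurstSequence", bursts = df, metadata = list(source = "ground-truth"))
}

gtSuperburstSet <- function(truth, minSmallLong = 21L) {
  sb <- truth@superbursts
  members <- lapply(sb$sb_id, function(i)
    truth@bursts$burst_id[truth@bursts$sb_id == i])
  df <- data.frame(sb_id = sb$sb_id, start_s = sb$start_s,
                   end_s = sb$end_s, n_bursts = lengths(members),
                   length_class = ifelse(sb$n_small >= minSmallLong,
                                         "long", "regular"),
                   type = NA_integer_)
  new("SuperburstSet", superbursts = df, members = members,
      metadata = list(source = "ground-truth"))
}

# Manual BurstSequence from burst windows (equal spike counts unless given).
makeBurstSeq <- function(starts, ends, peaks = starts, nSpikes = 10L,
                         class = "small") {
  n <- length(starts)
  new("BurstSequence",
      bursts = data.frame(burst_id = seq_len(n), start_s = starts,
                          end_s = ends, peak_s = peaks,
                          n_spikes = rep_len(nSpikes, n),
                          class = rep_len(class, n)),
      metadata = list())
}

# Best label-permutation agreement between two labelings with k = 2.
matchAccuracy2 <- function(labels, truthLabels) {
  a <- mean((labels == 1) == (truthLabels == truthLabels[1]))
  max(a, 1 - a)
}
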