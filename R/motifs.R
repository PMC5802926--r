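#' Principal-component features from activation patterns
#'
#' Prepares the feature matrix for motif clustering: missing first-spike
#' latencies are imputed with that burst's maximum observed latency (the
#' electrode activated last or never, preserving order information without
#' inventing early spikes); electrodes missing in more than `maxMissing` of
#' the bursts are dropped entirely; columns are mean-centred; scores of the
#' leading principal components are returned.
#'
#' @param patterns matrix of activation patterns (bursts x electrodes, `NA`
#'   = missing) from [activationPatterns()].
#' @param nPcs number of principal components (2 or 3 in practice).
#' @param maxMissing drop electrodes missing in more than this fraction of
#'   bursts (default 0.5).
#' @return Numeric score matrix (bursts x nPcs) with attribute
#'   `explainedVariance` (fraction per retained component).
#' @export
prepareFeatures <- function(patterns, nPcs = 3L, maxMissing = 0.5) {
  stopifnot(is.matrix(patterns), nPcs >= 1L)
  if (nrow(patterns) < nPcs + 1L)
    stop("need at least nPcs + 1 patterns")
  missFrac <- colMeans(is.na(patterns))
  keep <- missFrac <= maxMissing
  if (!any(keep)) stop("all electrodes dropped by the missingness filter")
  m <- patterns[, keep, drop = FALSE]
  rowMax <- apply(m, 1, max, na.rm = TRUE)
  ina <- which(is.na(m), arr.ind = TRUE)
  if (nrow(ina)) m[ina] <- rowMax[ina[, 1]]
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  nPcs <- min(nPcs, ncol(pc$x))
  scores <- pc$x[, seq_len(nPcs), drop = FALSE]
  attr(scores, "explainedVariance") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nPcs)]
  scores
}

## Gaussian-mixture labels with regularizing prior fallback. modelNames NULL
## lets BIC choose the covariance model (more stable for very small n, as in
## superburst typing); clusterPatterns() requests the full-covariance model.
.emCluster <- function(features, k, modelNames = NULL) {
  mn <- modelNames
  fit <- mclust::Mclust(features, G = k, modelNames = mn, verbose = FALSE)
  if (is.null(fit)) {
    message("degenerate Gaussian-mixture component at k = ", k,
            ": refitting with a regularizing prior")
    fit <- mclust::Mclust(features, G = k, modelNames = mn,
                          prior = mclust::priorControl(), verbose = FALSE)
  }
  if (is.null(fit)) stop("EM clustering failed at k = ", k)
  fit
}

#' Cluster burst features into motifs
#'
#' K-means (Lloyd's algorithm via [stats::kmeans()], 20 restarts, best
#' inertia kept) or EM Gaussian-mixture clustering (full covariance via
#' mclust, with a regularizing prior when a component degenerates).
#' Deterministic under a fixed seed.
#'
#' @param features numeric matrix (bursts x features), e.g. from
#'   [prepareFeatures()].
#' @param method `"kmeans"` or `"em"`.
#' @param k number of clusters (>= 2, and no more than the number of
#'   distinct rows).
#' @param seed integer seed.
#' @param nstart K-means restarts (default 20).
#' @return A [MotifModel-class] with labels in `1..k` and the
#'   Davies-Bouldin index of the fit.
#' @export
clusterPatterns <- function(features, method = c("kmeans", "em"), k,
                            seed = 1L, nstart = 20L) {
  method <- match.arg(method)
  features <- as.matrix(features)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  nDistinct <- nrow(unique(features))
  if (k > nDistinct)
    stop("k exceeds the number of distinct feature rows (", nDistinct, ")")
  set.seed(seed)
  if (method == "kmeans") {
    km <- stats::kmeans(features, centers = k, nstart = nstart,
                        iter.max = 100L)
    labels <- as.integer(km$cluster)
    centers <- km$centers
  } else {
    fit <- .emCluster(features, k,
                      modelNames = if (NCOL(features) > 1L) "VVV" else "V")
    labels <- as.integer(fit$classification)
    centers <- t(fit$parameters$mean)
  }
  db <- tryCatch(daviesBouldin(features, labels),
                 error = function(e) NA_real_)
  new("MotifModel", featureSpace = "pc", method = method, k = k,
      labels = labels, centers = as.matrix(centers), db = db,
      dbCurve = data.frame(k = integer(0), db = numeric(0)),
      kOpt = NA_integer_, motifAngles = NA_real_,
      metadata = list(seed = seed))
}

#' Davies-Bouldin cluster-validity index
#'
#' `DB = (1/k) * sum_i max_{j != i} (S_i + S_j) / M_ij` with `S_i` the mean
#' Euclidean distance of cluster `i`'s members to its centroid and `M_ij`
#' the distance between centroids. Lower is better; values below 1 indicate
#' compact clusters whose centres are far apart ("robust" clustering).
#'
#' @param features numeric matrix (points x dimensions).
#' @param labels cluster assignment (at least 2 non-empty clusters).
#' @return The DB index (non-negative scalar).
#' @examples
#' f <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' daviesBouldin(f, c(1, 1, 2, 2))  # 0.1
#' @export
daviesBouldin <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("need at least 2 non-empty clusters")
  cent <- matrix(0, k, ncol(features))
  S <- numeric(k)
  for (i in seq_len(k)) {
    m <- features[labels == i, , drop = FALSE]
    cent[i, ] <- colMeans(m)
    S[i] <- mean(sqrt(rowSums((m - rep(cent[i, ], each = nrow(m)))^2)))
  }
  M <- as.matrix(stats::dist(cent))
  if (any(M[upper.tri(M)] == 0))
    stop("coincident cluster centroids: DB index undefined")
  R <- outer(S, S, "+") / M
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Select the cluster number by the Davies-Bouldin curve
#'
#' Clusters the features at every `k` in `kRange` (skipping values that
#' exceed the number of distinct rows or fail to fit, recorded as `NA` in
#' the curve), computes the DB index of each fit, and returns the labelling
#' at the `k` minimizing DB (smallest `k` on ties).
#'
#' @inheritParams clusterPatterns
#' @param kRange candidate cluster numbers (default `2:30`).
#' @return A [MotifModel-class] whose `kOpt` and `dbCurve` are filled in and
#'   whose labels correspond to `kOpt`.
#' @export
selectK <- function(features, method = c("kmeans", "em"), kRange = 2:30,
                    seed = 1L) {
  method <- match.arg(method)
  features <- as.matrix(features)
  db <- rep(NA_real_, length(kRange))
  fits <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    fits[[i]] <- tryCatch(
      clusterPatterns(features, method, kRange[i], seed = seed),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) db[i] <- fits[[i]]@db
  }
  if (all(is.na(db))) stop("no cluster number could be fitted")
  best <- which.min(db)   # ignores NA; first (smallest k) on ties
  mm <- fits[[best]]
  mm@dbCurve <- data.frame(k = as.integer(kRange), db = db)
  mm@kOpt <- as.integer(kRange[best])
  mm
}

#' Cluster major propagation directions on the circle
#'
#' Angles are embedded as unit vectors `(cos, sin)` (removing the 0/360
#' seam), K-means clustered in the embedding, and summarized by per-motif
#' circular means; the DB index is computed in the embedding space.
#'
#' @param angles major-direction angles in degrees (`NA` dropped).
#' @param k number of direction motifs (default 2).
#' @param seed integer seed.
#' @param nstart K-means restarts.
#' @return A [MotifModel-class] in the `"angle"` feature space; `labels`
#'   refer to the non-`NA` angles in input order (see
#'   `metadata$angle_index` for their positions).
#' @export
clusterMajorDirections <- function(angles, k = 2L, seed = 1L,
                                   nstart = 20L) {
  idx <- which(!is.na(angles))
  a <- angles[idx]
  if (length(a) < k) stop("need at least k angles")
  th <- a * pi / 180
  emb <- cbind(cos = cos(th), sin = sin(th))
  if (nrow(unique(round(emb, 12))) < k)
    stop("degenerate input: fewer than k distinct directions")
  set.seed(seed)
  km <- stats::kmeans(emb, centers = k, nstart = nstart, iter.max = 100L)
  labels <- as.integer(km$cluster)
  motifAngles <- vapply(seq_len(k),
                        function(i) circularMean(a[labels == i]),
                        numeric(1))
  db <- daviesBouldin(emb, labels)
  new("MotifModel", featureSpace = "angle", method = "kmeans",
      k = as.integer(k), labels = labels, centers = km$centers, db = db,
      dbCurve = data.frame(k = integer(0), db = numeric(0)),
      kOpt = NA_integer_, motifAngles = motifAngles,
      metadata = list(seed = seed, angle_index = idx, angles = a))
}

#' DB curve over k for major-direction clustering
#'
#' Runs [clusterMajorDirections()] for every `k` in `kRange` and returns
#' the model at the DB-minimizing `k` with the curve attached.
#'
#' @inheritParams clusterMajorDirections
#' @param kRange candidate cluster numbers.
#' @return A [MotifModel-class] with `kOpt` and `dbCurve` filled in.
#' @export
selectKDirections <- function(angles, kRange = 2:30, seed = 1L) {
  db <- rep(NA_real_, length(kRange))
  fits <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    fits[[i]] <- tryCatch(
      clusterMajorDirections(angles, kRange[i], seed = seed),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) db[i] <- fits[[i]]@db
  }
  if (all(is.na(db))) stop("no cluster number could be fitted")
  best <- which.min(db)
  mm <- fits[[best]]
  mm@dbCurve <- data.frame(k = as.integer(kRange), db = db)
  mm@kOpt <- as.integer(kRange[best])
  mm
}
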