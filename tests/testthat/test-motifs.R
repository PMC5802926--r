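test_that("feature preparation respects rank, duplication and missingness", {
  lay <- standardLayout()
  # patterns on an exact 2-D latency subspace
  u <- planarPattern(lay, 10); w <- planarPattern(lay, 100)
  set.seed(15)
  coef <- matrix(runif(40, -1, 1), 20, 2)
  pats <- coef %*% rbind(u, w) + 0.01
  f <- prepareFeatures(pats, nPcs = 3)
  ev <- attr(f, "explainedVariance")
  expect_equal(sum(ev[1:2]), 1, tolerance = 1e-9)
  # duplicated patterns give identical scores
  pats2 <- rbind(pats, pats[3, ])
  f2 <- prepareFeatures(pats2, nPcs = 2)
  expect_equal(unname(f2[3, ]), unname(f2[21, ]), tolerance = 1e-12)
  # too few patterns
  expect_error(prepareFeatures(pats[1:3, ], nPcs = 3), "at least")
  # an all-missing electrode is dropped before the decomposition
  pats3 <- pats; pats3[, 5] <- NA
  f3 <- prepareFeatures(pats3, nPcs = 2)
  expect_equal(dim(f3), c(20L, 2L))
  expect_true(all(is.finite(f3)))
})

test_that("planted two-motif patterns separate along the leading PC", {
  ds <- generateDataset(smallConfig(nSuperbursts = 2L,
                                    smallBurstsPerSuperburst = c(40L, 40L)))
  seq <- gtBurstSequence(ds$truth)
  gt <- ds$truth@bursts
  small <- gt[gt$class == "small", ]
  ap <- activationPatterns(seq, ds$spikes, which = small$burst_id,
                           layout = arrayLayout(ds$spikes))
  f <- prepareFeatures(ap, nPcs = 2)
  mm <- clusterPatterns(f, "kmeans", k = 2, seed = 1)
  expect_gte(matchAccuracy2(mm@labels, small$motif), 0.99)
})

test_that("both clustering engines recover well-separated blobs", {
  set.seed(16)
  ctr <- matrix(rnorm(18, sd = 30), 6, 3)
  truth <- rep(1:6, each = 40)
  feats <- ctr[truth, ] + matrix(rnorm(240 * 3), 240, 3)
  for (method in c("kmeans", "em")) {
    mm <- clusterPatterns(feats, method, k = 6, seed = 2)
    conf <- table(mm@labels, truth)
    expect_gte(sum(apply(conf, 2, max)) / length(truth), 0.99)
  }
  # two point masses, k = 2: perfect split either labelling
  pm <- rbind(matrix(0, 50, 2), matrix(5, 50, 2))
  mm2 <- clusterPatterns(pm, "kmeans", k = 2)
  expect_length(unique(mm2@labels[1:50]), 1L)
  expect_length(unique(mm2@labels[51:100]), 1L)
  expect_false(mm2@labels[1] == mm2@labels[51])
  expect_error(clusterPatterns(pm, "kmeans", k = 3), "distinct")
})

test_that("the Davies-Bouldin index matches its closed form", {
  f <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  expect_identical(daviesBouldin(f, c(1, 1, 2, 2)), 0.1)
  # two singleton clusters
  expect_equal(daviesBouldin(rbind(c(0, 0), c(3, 4)), 1:2), 0)
  # shrinking within-cluster spread strictly decreases DB
  set.seed(17)
  base <- rbind(matrix(rnorm(60), 30, 2),
                matrix(rnorm(60, mean = 6), 30, 2))
  labs <- rep(1:2, each = 30)
  shrink <- function(x, s) {
    for (l in 1:2) {
      idx <- labs == l
      ctr <- colMeans(x[idx, ])
      x[idx, ] <- sweep(x[idx, ], 2, ctr) * s + rep(ctr, each = sum(idx))
    }
    x
  }
  expect_lt(daviesBouldin(shrink(base, 0.5), labs),
            daviesBouldin(base, labs))
  expect_error(daviesBouldin(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)),
                             c(1, 2, 1, 2)), "coincident")
  expect_error(daviesBouldin(base, rep(1, 60)), "at least 2")
})

test_that("the DB implementation agrees with brute force on random data", {
  set.seed(18)
  for (trial in 1:10) {
    n <- sample(20:100, 1); k <- sample(2:5, 1)
    f <- matrix(rnorm(n * 3), n, 3)
    labs <- sample(k, n, replace = TRUE)
    labs[1:k] <- 1:k   # ensure non-empty clusters
    expect_equal(daviesBouldin(f, labs), bruteDB(f, labs),
                 tolerance = 1e-12)
  }
})

test_that("DB is invariant to label permutation", {
  set.seed(19)
  f <- matrix(rnorm(120), 60, 2)
  labs <- rep(1:3, each = 20)
  perm <- c(3L, 1L, 2L)[labs]
  expect_equal(daviesBouldin(f, labs), daviesBouldin(f, perm))
})

test_that("the DB curve selects the planted cluster number", {
  set.seed(20)
  three <- rbind(matrix(rnorm(80, 0), 40, 2),
                 matrix(rnorm(80, 15), 40, 2),
                 cbind(rnorm(40, 0), rnorm(40, 15)))
  m3 <- selectK(three, "kmeans", kRange = 2:10)
  expect_equal(m3@kOpt, 3L)
  two <- rbind(matrix(rnorm(80, 0), 40, 2), matrix(rnorm(80, 12), 40, 2))
  m2 <- selectK(two, "kmeans", kRange = 2:10)
  expect_equal(m2@kOpt, 2L)
  expect_lt(m2@db, 1)
  # a single isotropic blob scores worse at k = 2 than planted two-motif data
  iso <- matrix(rnorm(160), 80, 2)
  dbIso <- clusterPatterns(iso, "kmeans", k = 2)@db
  expect_gt(dbIso, m2@db)
})

test_that("direction motifs cluster on the circle", {
  set.seed(22)
  a <- c(rnorm(60, 30, 5), rnorm(60, 300, 5)) %% 360
  mm <- clusterMajorDirections(a, k = 2)
  got <- sort(mm@motifAngles)
  expect_lt(circularAngleDifference(got[1], 30), 2)
  expect_lt(circularAngleDifference(got[2], 300), 2)
  # antipodal clouds separate with a very small DB
  b <- c(rnorm(50, 0, 3), rnorm(50, 180, 3)) %% 360
  mb <- clusterMajorDirections(b, k = 2)
  expect_lt(mb@db, 0.3)
  # a cloud spanning the 0/360 seam stays together
  wrap <- c(runif(40, 350, 360), runif(40, 0, 10), rnorm(40, 180, 5)) %% 360
  mw <- clusterMajorDirections(wrap, k = 2)
  expect_length(unique(mw@labels[1:80]), 1L)
  expect_error(clusterMajorDirections(rep(45, 10), k = 2), "degenerate")
})

test_that("circular angle arithmetic handles wrap-around", {
  expect_equal(circularAngleDifference(29, 302), 87)
  expect_equal(circularAngleDifference(0, 0), 0)
  expect_equal(circularAngleDifference(10, 350), 20)
  expect_equal(circularAngleDifference(c(0, 90), c(359, 271)),
               c(1, 179))
  expect_equal(circularMean(c(350, 10)), 0)
  expect_equal(circularMean(c(90, 90)), 90)
  expect_true(is.na(circularMean(c(0, 180))))
})
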