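# Brute-force O(n^2) pair-counting oracle for the ROC area.
azOracle <- function(proj, y) {
  pos <- proj[y == 1]; neg <- proj[y == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

test_that("sliding windows average within windows on the expected grid", {
  set.seed(1)
  ep <- toyEpochs(array(rnorm(5 * 3 * 50), c(5, 3, 50)), srate = 250)
  # one-sample window and step: identity over samples
  sw <- slidingWindows(ep, window_ms = 4, step_ms = 4)
  expect_equal(dim(sw$features)[3], 50)
  expect_equal(sw$features, epochData(ep))
  # 800 ms epoch at 1000 Hz, 106 ms window, 10 ms step -> 70 windows
  ep2 <- toyEpochs(array(0, c(2, 1, 800)), srate = 1000, t0 = 0)
  expect_equal(dim(slidingWindows(ep2, 106, 10)$features)[3], 70)
  # constant epochs give constant features
  ep3 <- toyEpochs(array(3.5, c(2, 2, 60)))
  expect_true(all(slidingWindows(ep3, 106, 10)$features == 3.5))
  expect_error(slidingWindows(toyEpochs(array(0, c(1, 1, 5))), 500, 10), "longer")
})

test_that("Az equals the pair-counting oracle, including ties", {
  expect_equal(azScore(1:10, rep(c(0, 1), each = 5)), 1)   # perfectly ranked
  expect_equal(azScore(10:1, rep(c(0, 1), each = 5)), 0)   # anti-ranked
  proj <- c(1, 2, 2, 3, 4, 4, 5, 6); y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  expect_equal(azScore(proj, y), azOracle(proj, y))
  set.seed(2)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.5); if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    proj <- sample(round(rnorm(n), 1))        # coarse values force ties
    expect_equal(azScore(proj, y), azOracle(proj, y))
  }
  expect_error(azScore(1:4, c(1, 1, 1, 1)), "two classes")
})

test_that("the spatial filter separates a separable toy and is chance on shuffled labels", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- c(0, 0, 1, 1)                           # class = first channel
  m <- trainSpatialFilter(X, y)
  expect_s4_class(m, "SpatialFilterModel")
  expect_equal(azScore(projectTrials(m, X), y), 1)
  expect_error(trainSpatialFilter(X, c(1, 1, 1, 1)), "two classes")
  set.seed(3)
  Xr <- matrix(rnorm(2e4), 1e4, 2)
  yr <- sample(rep(0:1, 5e3))
  mr <- trainSpatialFilter(Xr, yr)
  expect_lt(abs(azScore(projectTrials(mr, Xr), yr) - 0.5), 0.02)
})

test_that("within-condition decoding is seeded and near chance for shuffled labels", {
  set.seed(4)
  n <- 220
  ep <- toyEpochs(array(rnorm(n * 4 * 100), c(n, 4, 100)))
  y <- rep(c("high", "low"), n / 2)            # independent of the features
  cfg <- decodingConfig(step_ms = 20, n_repeats = 2, k_folds = 10)
  m1 <- tgmWithin(ep, y, cfg, seed = 11)
  m2 <- tgmWithin(ep, y, cfg, seed = 11)
  expect_identical(azMatrix(m1), azMatrix(m2))
  # a single dataset scatters around chance with SD ~0.02 in the grand mean
  expect_lt(abs(mean(azMatrix(m1)) - 0.5), 0.06)
  expect_true(all(azMatrix(m1) >= 0 & azMatrix(m1) <= 1))
})

test_that("cross-validation never leaks held-out trials into the fold classifier", {
  set.seed(4)
  n <- 40
  F1 <- array(rnorm(n * 3 * 40), c(n, 3, 40))
  F2 <- F1
  F2[7, , ] <- F2[7, , ] + 100                 # perturb one trial
  y <- rep(0:1, n / 2)
  folds <- withr::with_seed(5, seekEEG:::stratifiedFolds(y, 10))
  held <- folds[7]
  tr_i <- folds != held                        # trial 7 held out here
  sw <- function(F) apply(F[tr_i, , 10:20], c(1, 2), mean)
  m1 <- trainSpatialFilter(sw(F1), y[tr_i])
  m2 <- trainSpatialFilter(sw(F2), y[tr_i])
  expect_identical(filterWeights(m1), filterWeights(m2))
  expect_identical(filterBias(m1), filterBias(m2))
})

test_that("class counts below k reduce the fold count with a warning", {
  set.seed(5)
  ep <- toyEpochs(array(rnorm(12 * 3 * 40), c(12, 3, 40)))
  y <- c(rep("high", 4), rep("low", 8))
  expect_warning(tgmWithin(ep, y, decodingConfig(step_ms = 60, n_repeats = 1), seed = 1),
                 "reducing k_folds")
})

test_that("across-condition decoding requires shared signal and refuses trial overlap", {
  set.seed(6)
  n <- 120
  sig <- rep(c(1, -1), n / 2)
  mk <- function(coupled, idx) {
    d <- array(rnorm(n * 4 * 100), c(n, 4, 100))
    if (coupled) d[, 2, 30:70] <- d[, 2, 30:70] + 1.5 * sig
    e <- toyEpochs(d)
    EpochSet(epochData(e), epochTimes(e), "response", channelNames(e),
             samplingRate(e), idx)
  }
  y <- ifelse(sig > 0, "high", "low")
  cfg <- decodingConfig(step_ms = 20, n_balance_iters = 10)
  tr_ep <- mk(TRUE, 1:n); te_ep <- mk(TRUE, n + 1:n)
  m <- tgmAcross(tr_ep, y, te_ep, y, cfg, seed = 7)
  az <- azMatrix(m)
  # windows fully inside the injected 30:70-sample signal span
  w <- which(trainTimes(m) > 69 & trainTimes(m) < 123)
  expect_gt(mean(az[w, w]), 0.8)
  # no shared signal: chance transfer
  te0 <- mk(FALSE, n + 1:n)
  az0 <- azMatrix(tgmAcross(tr_ep, y, te0, y, cfg, seed = 8))
  expect_lt(abs(mean(az0) - 0.5), 0.03)
  expect_error(tgmAcross(tr_ep, y, tr_ep, y, cfg, seed = 9), "share")
})

test_that("null matrices sit at chance and are reproducible", {
  set.seed(7)
  n <- 200
  ep <- toyEpochs(array(rnorm(n * 3 * 40), c(n, 3, 40)))
  y <- rep(c("high", "low"), n / 2)
  cfg <- decodingConfig(step_ms = 60, n_null_iters = 8)
  nm <- nullMatrices(ep, y, cfg, seed = 12)
  expect_lt(abs(mean(azMatrix(nm)) - 0.5), 0.03)
  expect_identical(azMatrix(nullMatrices(ep, y, cfg, seed = 12)), azMatrix(nm))
})

test_that("2-D cluster inference finds an elevated block and nothing under the null", {
  set.seed(8)
  S <- 8; A <- 20; B <- 20
  true <- array(rnorm(S * A * B, 0.5, 0.02), c(S, A, B))
  null <- array(rnorm(S * A * B, 0.5, 0.02), c(S, A, B))
  cs0 <- clusterPermutation2D(true, true, seed = 1)
  expect_equal(nrow(clusterTable(cs0)), 0)
  block_r <- 6:15; block_c <- 6:15
  true[, block_r, block_c] <- true[, block_r, block_c] + 0.2
  cs <- clusterPermutation2D(true, null, element_p = 0.01, seed = 2)
  sig <- significantClusters(cs)
  expect_equal(nrow(sig), 1)
  block_idx <- as.vector(outer(block_r, (block_c - 1) * A, "+"))
  expect_true(all(block_idx %in% clusterMembers(cs)[[sig$id]]))
  expect_equal(cs@connectivity, "2d-8neighbor")
})

test_that("cluster inference is invariant to affine rescaling of both matrices", {
  set.seed(9)
  S <- 8
  true <- array(rnorm(S * 15 * 15, 0.55, 0.05), c(S, 15, 15))
  null <- array(rnorm(S * 15 * 15, 0.50, 0.05), c(S, 15, 15))
  cs1 <- clusterPermutation2D(true, null, seed = 3)
  cs2 <- clusterPermutation2D(0.25 + 0.5 * true, 0.25 + 0.5 * null, seed = 3)
  expect_equal(clusterTable(cs1), clusterTable(cs2), tolerance = 1e-9)
  expect_equal(clusterMembers(cs1), clusterMembers(cs2))
})

test_that("residualization leaves residuals exactly orthogonal to the factors", {
  d <- makeDesign(n_blocks = 1, seed = 10)
  tr <- simulateObserver(d, seed = 11)
  ep <- simulateEEG(tr, smallEEGParams(n = 4, beta_difficulty_pe = 3), seed = 12)
  res <- residualizeEpochs(ep$response, tr)
  X <- model.matrix(~ mean_level * var_level, tr)
  E <- matrix(epochData(res), nTrials(res), )
  expect_lt(max(abs(crossprod(X, E))), 1e-8)
  # constant factors are rejected
  tr0 <- tr; tr0$flat <- 1
  expect_error(residualizeEpochs(ep$response, tr0, c("mean_level", "flat")),
               "rank deficient")
})

test_that("peak-cluster comparison behaves in degenerate and powered cases", {
  set.seed(13)
  S <- 15; A <- 12; B <- 12
  mat <- array(rnorm(S * A * B, 0.5, 0.05), c(S, A, B))
  ref <- c(5, 6, 17, 18)
  # same matrix, same pixels: no difference
  r0 <- comparePeakClusters(mat, mat, ref, cmp_members = ref)
  expect_equal(r0$t, 0); expect_equal(r0$p_value, 1)
  # matched mode selects as many pixels as the reference cluster
  r1 <- comparePeakClusters(mat, mat, ref, shape = "matched")
  expect_length(r1$cmp_members, length(ref))
  # 1-pixel square equals the direct per-pixel paired t
  post <- array(rnorm(S * A * B, 0.5, 0.05), c(S, A, B))
  post[, 3, 4] <- post[, 3, 4] + 0.3
  r2 <- comparePeakClusters(mat, post, (4 - 1) * A + 3, shape = 1)
  direct <- t.test(post[, 3, 4] - mat[, 3, 4])
  expect_equal(r2$t, unname(direct$statistic))
  expect_equal(r2$p_value, direct$p.value)
  # powered construction: post 0.7 vs pre 0.5 (SD 0.05, 15 subjects)
  pre <- array(rnorm(S * A * B, 0.5, 0.05), c(S, A, B))
  post2 <- array(rnorm(S * A * B, 0.5, 0.05), c(S, A, B))
  post2[, 5:9, 5:9] <- post2[, 5:9, 5:9] + 0.2
  r3 <- comparePeakClusters(pre, post2, ref, shape = 5)
  expect_gt(r3$t, 4)
  expect_lt(r3$p_value, 0.001)
  # clipping at the matrix edge warns
  expect_warning(comparePeakClusters(mat, post2, ref, cmp_members = NULL,
                                     cmp_cluster = 1L, shape = 5), "clipped")
})

test_that("closestCluster returns the largest uncorrected supra-threshold set", {
  set.seed(14)
  S <- 8
  true <- array(rnorm(S * 10 * 10, 0.5, 0.02), c(S, 10, 10))
  null <- array(rnorm(S * 10 * 10, 0.5, 0.02), c(S, 10, 10))
  true[, 2:4, 2:4] <- true[, 2:4, 2:4] + 0.3
  cc <- closestCluster(true, null, 0.01)
  blk <- as.vector(outer(2:4, (2:4 - 1) * 10, "+"))
  expect_true(all(blk %in% cc$members))
  # no signal at a strict threshold: falls back to the peak pixel
  expect_message(cc0 <- closestCluster(null, null + array(rnorm(length(null), 0, 1e-6), dim(null)), 1e-12),
                 "peak")
  expect_length(cc0$members, 1)
})
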