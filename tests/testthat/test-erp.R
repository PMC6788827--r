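test_that("condition ERPs are per-condition trial means", {
  set.seed(1)
  ep <- toyEpochs(array(rnorm(6 * 2 * 40), c(6, 2, 40)), channels = c("CPz", "Pz"))
  labs <- c("high", "low", "low", "high", "low", "high")
  erp <- conditionERP(ep, labs, "CPz")
  expect_equal(erp["high", ], colMeans(epochData(ep)[labs == "high", 1, ]),
               ignore_attr = TRUE)
  # a single-trial condition equals that trial
  erp1 <- conditionERP(ep[1:3], c("a", "b", "b"), "CPz")
  expect_equal(erp1["a", ], epochData(ep)[1, 1, ], ignore_attr = TRUE)
  # swapping labels swaps waveforms
  swapped <- conditionERP(ep, ifelse(labs == "high", "low", "high"), "CPz")
  expect_equal(swapped["low", ], erp["high", ], ignore_attr = TRUE)
  expect_error(conditionERP(ep, labs, "Oz"), "not found")
})

test_that("noise-free confidence ERP difference matches the Pe coupling", {
  d <- makeDesign(n_blocks = 2, seed = 2)
  tr <- simulateObserver(d, seed = 3)
  # post-decisional coupling only, and no baseline components, so the
  # response-locked difference is pure Pe coupling
  p <- smallEEGParams(noise_sd = 0, alpha0 = 0, alpha1_p3 = 0)
  ep <- simulateEEG(tr, p, seed = 4)
  labs <- medianSplit(tr$confidence_z)
  erp <- conditionERP(ep$response, labs, "CPz")
  tz <- tr; tz$confidence_abs <- tz$confidence_pre
  z <- zscoreConfidence(tz)$confidence_z
  tR <- epochTimes(ep$response)
  kern <- exp(-(tR - p$pe_latency_ms)^2 / (2 * p$pe_width_ms^2))
  kern[tR < p$pe_support_ms[1] | tR > p$pe_support_ms[2]] <- 0
  hi <- labs$label == "high"
  expected <- p$alpha1_pe * (mean(z[hi]) - mean(z[!hi])) *
    p$pe_topography[["CPz"]] * kern
  expect_equal(erp["low", ] - erp["high", ], expected,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("identical conditions yield an empty cluster set", {
  set.seed(5)
  w <- matrix(rnorm(8 * 60), 8, 60)
  cs <- clusterPermutation1D(w, w, element_p = 0.05, n_perm = 200, seed = 1)
  expect_equal(nrow(clusterTable(cs)), 0)
  expect_s4_class(cs, "ClusterSet")
})

test_that("an injected 400-600 ms difference is recovered as one significant cluster", {
  set.seed(6)
  times <- seq(0, 796, by = 4)                  # 250 Hz
  S <- 8
  base <- matrix(rnorm(S * length(times), sd = 0.3), S, length(times))
  eff <- ifelse(times >= 400 & times <= 600, 2, 0)
  cond_a <- base + matrix(eff, S, length(times), byrow = TRUE)
  cond_b <- matrix(rnorm(S * length(times), sd = 0.3), S, length(times))
  cs <- clusterPermutation1D(cond_a, cond_b, element_p = 0.05, seed = 2)
  sig <- significantClusters(cs)
  expect_equal(nrow(sig), 1)
  ext <- range(times[clusterMembers(cs)[[sig$id]]])
  expect_lt(abs(ext[1] - 400), 30)
  expect_lt(abs(ext[2] - 600), 30)
  expect_equal(sig$sign, 1)
  # p values respect the resolution of the enumerated null
  expect_gte(sig$p_value, 1 / (cs@nPermutations + 1))
})

test_that("element-level t values equal the paired t.test oracle", {
  set.seed(7)
  a <- matrix(rnorm(6 * 10), 6, 10)
  b <- matrix(rnorm(6 * 10), 6, 10)
  cs <- clusterPermutation1D(a, b, seed = 3)
  oracle <- vapply(1:10, function(j) unname(t.test(a[, j], b[, j], paired = TRUE)$statistic),
                   numeric(1))
  expect_equal(as.numeric(cs@tmap), oracle, tolerance = 1e-12)
})

test_that("cluster permutation requires enough subjects and warns on few permutations", {
  a <- matrix(rnorm(3 * 10), 3, 10)
  expect_error(clusterPermutation1D(a, a * 0), "6 subjects")
  a8 <- matrix(rnorm(16 * 10), 16, 10)         # 2^16 > 4096 -> Monte-Carlo
  expect_warning(clusterPermutation1D(a8, a8 * 0, n_perm = 50, seed = 1), "unstable")
})

test_that("time-resolved regression t values are scale invariant and match the coupling", {
  d <- makeDesign(n_blocks = 2, seed = 8)
  tr <- simulateObserver(d, seed = 9)
  # Pe coupling only: no P3 and no baseline amplitude, so nothing can
  # leak into the pre-response window through RT variability
  p <- smallEEGParams(noise_sd = 2, alpha0 = 0, alpha1_p3 = 0)
  ep <- simulateEEG(tr, p, seed = 10)
  tv <- timewiseRegression(ep$response, tr, "CPz",
                           c("mean_level", "var_level", "mean_level:var_level",
                             "confidence_z"))
  expect_equal(nrow(tv), 4)
  expect_true(all(is.finite(tv)))
  # doubling amplitudes leaves t values unchanged
  ep2 <- EpochSet(epochData(ep$response) * 2, epochTimes(ep$response), "response",
                  channelNames(ep$response), samplingRate(ep$response),
                  trialIndex(ep$response))
  tv2 <- timewiseRegression(ep2, tr, "CPz",
                            c("mean_level", "var_level", "mean_level:var_level",
                              "confidence_z"))
  expect_equal(tv2, tv, tolerance = 1e-9)
  # the confidence coupling dominates in the Pe window
  tR <- epochTimes(ep$response)
  pe_win <- tR >= 400 & tR <= 560            # around the Pe kernel peak
  expect_lt(mean(tv["confidence_z", pe_win]), -2.5)
  pre_win <- tR <= 100                       # before the Pe support
  expect_lt(mean(abs(tv["confidence_z", pre_win])), 1.2)
  expect_error(timewiseRegression(ep$response, transform(tr, dup = confidence_z),
                                  "CPz", c("confidence_z", "dup")), "collinear")
})

test_that("residualizing the predictor out of the EEG removes its regression effect", {
  d <- makeDesign(n_blocks = 2, seed = 11)
  tr <- simulateObserver(d, seed = 12)
  p <- smallEEGParams(noise_sd = 4, alpha1_p3 = 0)
  ep <- simulateEEG(tr, p, seed = 13)
  res <- residualizeEpochs(ep$response, tr, "confidence_z")
  tv <- timewiseRegression(res, tr, "CPz", "confidence_z")
  expect_lt(max(abs(tv)), 1e-6)                # exact orthogonality
})
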