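test_that("baseline correction zeroes the baseline window and is idempotent", {
  set.seed(1)
  ep <- toyEpochs(array(rnorm(20 * 3 * 100, mean = 5), c(20, 3, 100)))
  bc <- baselineCorrect(ep, c(-100, 0))
  idx <- epochTimes(bc) >= -100 & epochTimes(bc) <= 0
  bmeans <- apply(epochData(bc)[, , idx], c(1, 2), mean)
  expect_lt(max(abs(bmeans)), 1e-10)
  expect_equal(baselineWindow(bc), c(-100, 0))
  expect_equal(epochData(baselineCorrect(bc, c(-100, 0))), epochData(bc))
  # constant-offset epochs become exactly zero
  const <- toyEpochs(array(7, c(2, 2, 50)))
  expect_true(all(epochData(baselineCorrect(const, c(-100, 0))) == 0))
  expect_error(baselineCorrect(ep, c(-500, 0)), "outside")
})

test_that("realignment shifts samples by per-trial offsets", {
  set.seed(2)
  ep <- toyEpochs(array(rnorm(4 * 2 * 200), c(4, 2, 200)))   # -100..696 ms
  # zero offsets: identity on the overlapping window
  r0 <- realignEpochs(ep, rep(0, 4), c(-100, 400), "response")
  idx <- epochTimes(ep) %in% epochTimes(r0)
  expect_equal(epochData(r0), epochData(ep)[, , idx])
  # a 300 ms offset puts the old 300 ms sample at new time 0
  r3 <- realignEpochs(ep, rep(300, 4), c(-100, 300), "response")
  j_new <- which(epochTimes(r3) == 0)
  j_old <- which(epochTimes(ep) == 300)
  expect_equal(epochData(r3)[, , j_new], epochData(ep)[, , j_old])
  # realign then inverse realign recovers the original on the common support
  back <- realignEpochs(r3, rep(-300, 4), c(200, 600), "stimulus")
  idx_b <- match(epochTimes(back), epochTimes(ep))
  expect_equal(epochData(back), epochData(ep)[, , idx_b])
  expect_error(realignEpochs(ep, c(0, NA, 0, 0), c(-100, 300), "response"), "finite")
})

test_that("realigning simulator output reproduces its native response-locked epochs", {
  d <- makeDesign(n_blocks = 1, seed = 1)
  tr <- simulateObserver(d, seed = 2)
  p <- smallEEGParams()
  # a stimulus window long enough that no trial is dropped on realignment
  ep <- simulateEEG(tr, p, seed = 3,
                    windows = list(stimulus = c(-200, 2300), response = c(-100, 700),
                                   choice = c(-700, 100)))
  dt <- 1000 / p$srate_hz
  rt <- round(tr$rt_ms / dt) * dt
  realigned <- realignEpochs(ep$stimulus, rt, c(-100, 700), "response")
  expect_equal(nTrials(realigned), nTrials(ep$response))
  expect_equal(epochTimes(realigned), epochTimes(ep$response))
  expect_equal(epochData(realigned), epochData(ep$response))
})

test_that("trials whose realigned window exceeds the epoch are dropped and logged", {
  set.seed(3)
  ep <- toyEpochs(array(rnorm(5 * 2 * 100), c(5, 2, 100)))   # -100..296 ms
  expect_message(r <- realignEpochs(ep, c(0, 0, 400, 0, 800), c(-100, 200), "response"),
                 "dropping 2")
  expect_equal(trialIndex(r), c(1L, 2L, 4L))
})

test_that("extreme-value rejection removes exactly the supra-threshold trials", {
  set.seed(4)
  d <- array(rnorm(10 * 2 * 50, sd = 10), c(10, 2, 50))      # bounded well below 200
  spiked <- c(2, 5, 9)
  for (i in spiked) d[i, 1, 25] <- 300
  out <- rejectExtreme(toyEpochs(d), 200)
  expect_equal(nTrials(out$epochs), 7)
  expect_equal(which(!out$mask$keep), spiked)
  expect_true(all(out$mask$reason[spiked] == "extreme_value"))
  # a 250 uV peak is rejected at the 200 uV bound
  d2 <- array(0, c(2, 1, 10)); d2[1, 1, 3] <- 250
  expect_equal(sum(rejectExtreme(toyEpochs(d2))$mask$keep), 1)
  # nothing rejected when bounded by 50 uV
  d3 <- array(runif(5 * 2 * 20, -50, 50), c(5, 2, 20))
  expect_true(all(rejectExtreme(toyEpochs(d3))$mask$keep))
  d2[2, 1, 5] <- -260
  expect_error(rejectExtreme(toyEpochs(d2), 10), "all trials")
})

test_that("the rejection mask is a pure function of amplitudes", {
  set.seed(5)
  d <- array(rnorm(12 * 2 * 30, sd = 60), c(12, 2, 30))
  m1 <- rejectExtreme(toyEpochs(d), 160)$mask$keep
  perm <- sample(12)
  m2 <- rejectExtreme(toyEpochs(d[perm, , , drop = FALSE]), 160)$mask$keep
  expect_identical(m2, m1[perm])
})

test_that("confidence z-scores are standardized per participant and block", {
  tt <- data.frame(participant = 1, block = 1, confidence_abs = c(10, 30))
  z <- zscoreConfidence(tt)$confidence_z
  expect_equal(z, c(-sqrt(0.5), sqrt(0.5)))    # sample-sd convention
  d <- makeDesign(n_blocks = 3, seed = 6)
  tr <- simulateObserver(d, seed = 7)
  for (b in unique(tr$block)) {
    zb <- tr$confidence_z[tr$block == b]
    expect_lt(abs(mean(zb)), 1e-10)
    expect_lt(abs(sd(zb) - 1), 1e-10)
  }
  # degenerate block: all zero, flagged
  tt2 <- data.frame(participant = 1, block = c(1, 1, 2, 2),
                    confidence_abs = c(20, 20, 10, 30))
  out <- zscoreConfidence(tt2)
  expect_equal(out$confidence_z[1:2], c(0, 0))
  expect_equal(attr(out, "degenerate_blocks"), "1.1")
})

test_that("median split balances classes, alternating ties", {
  s <- medianSplit(c(1, 2, 3, 4))
  expect_equal(s$label, c("low", "low", "high", "high"))
  expect_equal(s$split_value, 2.5)
  s2 <- medianSplit(c(1, 2, 2, 3))
  expect_equal(s2$split_value, 2)
  expect_equal(sum(s2$label == "high"), 2)     # the two ties split one per class
  expect_equal(sum(s2$label == "low"), 2)
  expect_error(medianSplit(rep(3, 5)), "distinct")
  # property: imbalance never exceeds the tie count
  set.seed(8)
  for (i in 1:25) {
    v <- sample(1:6, 30, replace = TRUE)
    sp <- medianSplit(v)
    imb <- abs(sum(sp$label == "high") - sum(sp$label == "low"))
    expect_lte(imb, sum(v == sp$split_value))
  }
})
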