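test_that("noiseless BOLD peaks at the HRF lag with amplitude-scaled response", {
  sched <- data.frame(onset = 20, duration = 9, run = 1, run_trial = 1,
                      correct = TRUE, censored = FALSE)
  b <- simulateBold(sched, matrix(c(1, 2), 1, 2), noise_sd = 0,
                    fd_spike_p = 0, seed = 1)
  Y <- b$runs[["1"]]$Y
  tpk <- b$runs[["1"]]$frame_times[which.max(Y[, 1])]
  # response peaks a hemodynamic lag (~4-8 s) after stimulus onset
  expect_gt(tpk, 20 + 3)
  expect_lt(tpk, 20 + 12)
  # amplitude scales linearly with the pattern value
  expect_equal(max(Y[, 2] - 100), 2 * max(Y[, 1] - 100), tolerance = 1e-9)
})

test_that("motion censoring follows the framewise-displacement trace", {
  sched <- fxSchedule()[fxSchedule()$run == 1, ]
  amp <- matrix(0, nrow(sched), 3)
  b0 <- simulateBold(sched, amp, fd_spike_p = 0, seed = 4)
  expect_false(any(b0$schedule$censored))
  # censored fraction matches the binomial closed form: a trial covering
  # F frames is censored with probability 1 - (1-p)^F
  p <- 0.05
  frac <- vapply(1:60, function(seed) {
    b <- simulateBold(sched, amp, fd_spike_p = p, seed = seed)
    mean(b$schedule$censored)
  }, numeric(1))
  ft <- b0$runs[["1"]]$frame_times
  F_k <- vapply(seq_len(nrow(sched)), function(k)
    sum(ft >= sched$onset[k] & ft < sched$onset[k] + sched$duration[k]),
    numeric(1))
  expected <- mean(1 - (1 - p)^F_k)
  expect_lt(abs(mean(frac) - expected), 0.015)
})

test_that("LS-S recovers planted amplitudes for isolated trials", {
  sched <- data.frame(onset = 30, duration = 9, run = 1, run_trial = 1,
                      correct = TRUE, censored = FALSE)
  amp <- matrix(c(2.5, -1, 0.5), 1, 3)
  b <- simulateBold(sched, amp, noise_sd = 0, fd_spike_p = 0, seed = 1,
                    pad_s = 40)
  est <- fitLSS(b$runs[["1"]]$Y, sched, statistic = "beta")
  expect_equal(as.numeric(est), as.numeric(amp), tolerance = 1e-6)
})

test_that("LS-S equals full-model OLS for widely separated trials", {
  sched <- data.frame(onset = c(30, 150), duration = 9, run = 1,
                      run_trial = 1:2, correct = TRUE, censored = FALSE)
  amp <- matrix(c(2, -1, 1, 3), 2, 2)
  b <- simulateBold(sched, amp, noise_sd = 0, fd_spike_p = 0, seed = 1,
                    pad_s = 60)
  Y <- b$runs[["1"]]$Y
  lss <- fitLSS(Y, sched, statistic = "beta")
  # oracle: one model with both trial regressors, closed-form OLS
  X <- overlapMPS:::.convolveTrials(sched$onset, sched$duration, nrow(Y),
                                    2.59)
  nuis <- overlapMPS:::.nuisanceBlock(nrow(Y), 2.59, NULL, integer(0), 100)
  Xf <- cbind(X, nuis)
  bf <- solve(crossprod(Xf), crossprod(Xf, Y))[1:2, ]
  expect_equal(unclass(lss)[, , drop = TRUE], bf, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("degenerate and rank-deficient inputs fail loudly", {
  sched <- data.frame(onset = 20, duration = 9, run = 1, run_trial = 1,
                      correct = TRUE, censored = FALSE)
  Y <- matrix(0, 40, 2)  # all-zero series
  expect_warning(est <- fitLSS(Y, sched), "NaN")
  expect_true(all(is.nan(est)))
  # duplicated motion column -> collinear design named in the error
  b <- simulateBold(sched, matrix(1, 1, 2), noise_sd = 0.1, seed = 2)
  nf <- nrow(b$runs[["1"]]$Y)
  mot <- cbind(rnorm(nf), rnorm(nf)); mot <- cbind(mot, mot[, 1])
  expect_error(fitLSS(b$runs[["1"]]$Y, sched, motion = mot),
               "rank deficient.*motion")
})

test_that("run GLM produces one map per run, consistent with LS-S means", {
  env <- fxEnv()
  sched <- fxSchedule()
  # low-noise subject with a common pattern per run
  codes <- makeStoreCodes(env, effectSpec(sigma_noise = 0), seed = 6)
  map <- neuronToVoxelMap(200, 30, seed = 6)
  amp <- patterns(simulateTrialPatterns(sched, codes, map, env, seed = 6))
  two_runs <- sched$run %in% 1:2
  b <- simulateBold(sched[two_runs, ], amp[two_runs, ], noise_sd = 0.3,
                    fd_spike_p = 0, seed = 6)
  rp <- estimateRunPatterns(b)
  expect_equal(nrow(patterns(rp)), 2)
  tp <- estimateTrialPatterns(b)
  # run map aligns with the mean of its single-trial maps on low-noise data
  for (r in 1:2) {
    runmean <- colMeans(patterns(tp)[trialData(tp)$run == r &
                                       trialData(tp)$correct, ])
    cosim <- sum(runmean * patterns(rp)[r, ]) /
      sqrt(sum(runmean^2) * sum(patterns(rp)[r, ]^2))
    expect_gt(cosim, 0.95)
  }
  # a run with no remembered trials is rejected
  s2 <- sched[sched$run == 1, ]; s2$correct <- FALSE
  expect_error(fitRunGLM(b$runs[["1"]]$Y, s2), "no remembered trials")
})

test_that("t-maps are invariant to joint rescaling of signal and noise", {
  sched <- data.frame(onset = c(20, 60), duration = 9, run = 1,
                      run_trial = 1:2, correct = TRUE, censored = FALSE)
  b <- simulateBold(sched, matrix(c(1, 2, 0.5, 1), 2, 2), noise_sd = 0.5,
                    fd_spike_p = 0, seed = 3, baseline = 0)
  Y <- b$runs[["1"]]$Y
  t1 <- fitLSS(Y, sched)
  t2 <- fitLSS(Y * 7, sched)
  expect_equal(unclass(t1), unclass(t2), tolerance = 1e-9)
})
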