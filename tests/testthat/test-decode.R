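test_that("uniformity trimming leaves uniform sets alone and matches exhaustive search", {
  # already uniform: nothing removed
  tr <- data.frame(dist_index = rep(1:6, each = 10))
  out <- enforceUniformDistance(tr, seed = 1)
  expect_length(out$removed, 0)
  expect_gt(out$p.value, 0.05)

  # one bin doubled on a 6-bin toy set: removals equal the brute-force
  # minimum found by exhaustively trimming the doubled bin
  tr2 <- data.frame(dist_index = c(rep(1, 20), rep(2:6, each = 10)))
  out2 <- enforceUniformDistance(tr2, seed = 1)
  ks_after_removing <- function(k) {
    counts <- c(20 - k, rep(10, 5))
    overlapMPS:::.ksUniformDiscrete(counts)$p.value
  }
  kmin <- min(which(vapply(0:19, ks_after_removing, numeric(1)) > 0.05)) - 1
  expect_equal(length(out2$removed), kmin)
  expect_gt(out2$p.value, 0.05)
  expect_true(all(tr2$dist_index[out2$removed] == 1))

  # degenerate: everything in one bin of a wider reference bin set
  tr3 <- data.frame(dist_index = rep(2, 30))
  expect_error(enforceUniformDistance(tr3, bins = 1:6, seed = 1),
               "unattainable|exhausted")
})

test_that("trimming is seed-deterministic", {
  tr <- data.frame(dist_index = c(rep(1, 25), rep(2:6, each = 8)),
                   id = seq_len(65))
  a <- enforceUniformDistance(tr, seed = 9)
  b <- enforceUniformDistance(tr, seed = 9)
  expect_identical(a, b)
})

test_that("a noiseless shared distance code is decoded perfectly across cities", {
  env <- fxEnv()
  sched <- fxSchedule()
  sp <- sched[sched$task == "spatial", ]
  D <- round(spatialDistanceIndex(sp$store_top, sp$store_bl, sp$store_br,
                                  env), 9)
  set.seed(3)
  w <- rnorm(30)
  ps <- PatternSet(outer(D, w), sp, voxelTSNR = rep(40, 30))
  res <- svrLeaveOneCityOut(ps, env, enforce_uniform = FALSE, seed = 1)
  expect_equal(res$folds$rho, rep(1, 3), tolerance = 1e-12)
  expect_equal(res$chance, 0)
})

test_that("schema decoding recovers the planted code only where it is planted", {
  env <- fxEnv()
  zs <- t(vapply(1:20, function(seed) {
    eff <- effectSpec(beta_schema = 0.5, sigma_noise = 1)
    codes <- makeStoreCodes(env, eff, seed = seed)
    map <- neuronToVoxelMap(seed = seed)
    withschema <- simulateTrialPatterns(fxSchedule(), codes, map, env,
                                        seed = seed, schema = TRUE)
    without <- simulateTrialPatterns(fxSchedule(), codes, map, env,
                                     seed = seed + 1000, schema = FALSE)
    c(svrLeaveOneCityOut(withschema, env, seed = seed)$overall,
      svrLeaveOneCityOut(without, env, seed = seed)$overall)
  }, numeric(2)))
  expect_lt(t.test(zs[, 1])$p.value, 1e-4)   # schema ROI decodes
  expect_gt(mean(zs[, 1]), 0.2)
  expect_gt(t.test(zs[, 2])$p.value, 0.01)   # control ROI at chance 0
  expect_lt(abs(mean(zs[, 2])), 0.1)
})

test_that("interval classification generalizes only for city-general codes", {
  env <- fxEnv()
  acc <- t(vapply(1:10, function(seed) {
    shared <- fxSubject(seed + 700, effectSpec(kappa_interval = 1.5,
                                               interval_shared = TRUE),
                        interval = TRUE)
    local_ <- fxSubject(seed + 800, effectSpec(kappa_interval = 1.5,
                                               interval_shared = FALSE),
                        interval = TRUE)
    c(svmIntervalLeaveOneCityOut(shared$retrieval, env, seed = seed)$overall,
      svmIntervalLeaveOneCityOut(local_$retrieval, env, seed = seed)$overall)
  }, numeric(2)))
  expect_gt(mean(acc[, 1]), 0.6)    # shared code generalizes across cities
  expect_lt(abs(mean(acc[, 2]) - 1 / 3), 0.08)  # within-city code: chance
  # noiseless shared code: perfect classification
  sub <- fxSubject(901, effectSpec(kappa_interval = 1, sigma_noise = 0),
                   interval = TRUE)
  expect_equal(svmIntervalLeaveOneCityOut(sub$retrieval, env,
                                          seed = 1)$overall, 1)
})

test_that("city classifier enumerates all 64 held-out combinations", {
  env <- fxEnv()
  rp <- simulateRunPatterns(env, effectSpec(gamma_city = 5,
                                            sigma_noise = 0.1), seed = 2)
  res <- svmCity(rp)
  expect_equal(unique(res$folds$n_folds), 64)
  expect_equal(res$overall, 1)          # well-separated city codes
  expect_equal(res$chance, 1 / 3)
  # missing run map is rejected
  td <- trialData(rp)
  expect_error(svmCity(PatternSet(patterns(rp)[-1, ], td[-1, ])),
               "4 run maps per city")
})

test_that("city accuracy rises monotonically with the planted city signal", {
  env <- fxEnv()
  grid <- c(0, 0.2, 0.5, 1)
  acc <- vapply(grid, function(g) {
    mean(vapply(1:10, function(seed)
      svmCity(simulateRunPatterns(env, effectSpec(gamma_city = g),
                                  seed = seed))$overall, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= -0.02))   # nondecreasing up to noise
  expect_gt(acc[4], acc[1] + 0.3)
})

test_that("balancing and decoding are deterministic given a seed", {
  env <- fxEnv()
  sub <- fxSubject(77, effectSpec(kappa_interval = 0.5), interval = TRUE)
  r1 <- svmIntervalLeaveOneCityOut(sub$retrieval, env, seed = 4)
  r2 <- svmIntervalLeaveOneCityOut(sub$retrieval, env, seed = 4)
  expect_identical(r1$folds, r2$folds)
  s1 <- svrLeaveOneCityOut(sub$retrieval, env, seed = 4)
  s2 <- svrLeaveOneCityOut(sub$retrieval, env, seed = 4)
  expect_identical(s1$folds, s2$folds)
})
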