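test_that("Fisher z matches atanh and clamps perfect correlations", {
  expect_equal(fisherZ(0.5), atanh(0.5))
  expect_equal(fisherZ(0.5), 0.5493061, tolerance = 1e-6)
  expect_equal(fisherZ(c(-0.2, 0, 0.9)), atanh(c(-0.2, 0, 0.9)))
  expect_true(is.finite(fisherZ(1)) && is.finite(fisherZ(-1)))
})

test_that("templates average localizer repetitions per studied store", {
  loc <- fxLocalizer()
  # identical repetition patterns -> template equals them
  base <- matrix(0, nrow(loc), 12)
  for (s in c(2, 4, 6, 7, 8, 9)) {
    base[loc$store_old == s, ] <- matrix(rep(s + (1:12) / 10, sum(loc$store_old == s)),
                                         ncol = 12, byrow = TRUE)
  }
  lp <- PatternSet(base, loc, voxelTSNR = rep(40, 12))
  tmpl <- buildStoreTemplates(lp)
  expect_equal(dim(tmpl$templates), c(6, 12))
  expect_equal(unname(tmpl$n_reps), rep(6L, 6))
  expect_equal(tmpl$templates["4", ], 4 + (1:12) / 10)
  # unusable repetitions are excluded, zero repetitions rejected
  loc2 <- loc; loc2$correct[loc2$store_old == 9] <- FALSE
  expect_error(buildStoreTemplates(PatternSet(base, loc2,
                                              voxelTSNR = rep(40, 12))),
               "store 9")
})

test_that("averaging repetitions denoises the planted code", {
  env <- fxEnv()
  gains <- vapply(1:40, function(seed) {
    sub <- fxSubject(seed, effectSpec(sigma_noise = 2))
    tmpl <- buildStoreTemplates(sub$localizer)
    truth <- as.numeric(sub$codes$identity[["4"]] %*% sub$map$weights)
    td <- trialData(sub$localizer)
    singles <- patterns(sub$localizer)[td$store_old == 4, ]
    cor(tmpl$templates["4", ], truth) -
      mean(apply(singles, 1, cor, y = truth))
  }, numeric(1))
  expect_gt(mean(gains), 0)
  expect_lt(t.test(gains)$p.value, 1e-4)
})

test_that("holistic condition pair counts match a brute-force enumeration", {
  env <- fxEnv()
  sub <- fxSubject(13, effectSpec())
  res <- holisticPS(buildStoreTemplates(sub$localizer), sub$retrieval, env)
  td <- trialData(sub$retrieval)
  use <- td$correct & !td$censored
  # oracle: literal nested loops over (store, trial)
  counts <- c(unique_within = 0, shared_within = 0, unique_between = 0)
  for (s in c(2, 4, 6, 7, 8, 9)) {
    own <- which(vapply(env@cities, function(x) s %in% x, logical(1)))
    uniq <- length(own) == 1L
    for (i in which(use)) {
      present <- s %in% c(td$store_top[i], td$store_bl[i], td$store_br[i])
      if (td$city[i] %in% own && !present) {
        nm <- if (uniq) "unique_within" else "shared_within"
        counts[nm] <- counts[nm] + 1
      } else if (uniq && !td$city[i] %in% own) {
        counts["unique_between"] <- counts["unique_between"] + 1
      }
    }
  }
  expect_equal(res$n_pairs[match(names(counts), res$condition)],
               unname(counts), ignore_attr = TRUE)
})

test_that("templates orthogonal to all trial patterns give z = 0", {
  env <- fxEnv()
  sched <- fxSchedule()
  nv <- 40
  set.seed(8)
  # trials live on voxels 1-20, templates on 21-40, each half mean-centered,
  # so every template-trial Pearson numerator is exactly zero
  pat <- cbind(t(scale(matrix(rnorm(nrow(sched) * 20), 20), scale = FALSE)),
               matrix(0, nrow(sched), 20))
  loc <- fxLocalizer()
  tm <- cbind(matrix(0, nrow(loc), 20),
              t(scale(matrix(rnorm(nrow(loc) * 20), 20), scale = FALSE)))
  res <- holisticPS(buildStoreTemplates(PatternSet(tm, loc)),
                    PatternSet(pat, sched), env)
  expect_equal(res$z, rep(0, 3), tolerance = 1e-10)
})

test_that("planted reinstatement yields holistic, differentiated similarity", {
  env <- fxEnv()
  wins <- t(vapply(1:25, function(seed) {
    sub <- fxSubject(seed, effectSpec(eta_holistic = 0.5, rho_shared = 0))
    res <- holisticPS(buildStoreTemplates(sub$localizer), sub$retrieval, env)
    z <- setNames(res$z, res$condition)
    c(z["unique_within"] - z["unique_between"],
      z["unique_within"] - z["shared_within"])
  }, numeric(2)))
  expect_gt(mean(wins[, 1] > 0), 0.9)
  expect_gt(mean(wins[, 2] > 0), 0.9)
  # and a null subject shows no such ordering bias
  null_d <- vapply(1:25, function(seed) {
    sub <- fxSubject(100 + seed, effectSpec(eta_holistic = 0))
    res <- holisticPS(buildStoreTemplates(sub$localizer), sub$retrieval, env)
    z <- setNames(res$z, res$condition)
    unname(z["unique_within"] - z["unique_between"])
  }, numeric(1))
  expect_gt(t.test(null_d)$p.value, 0.01)
})

test_that("balanced-pair control preserves the holistic contrast", {
  env <- fxEnv()
  sub <- fxSubject(31, effectSpec(eta_holistic = 0.8))
  tmpl <- buildStoreTemplates(sub$localizer)
  full <- holisticPS(tmpl, sub$retrieval, env)
  bal <- holisticPS(tmpl, sub$retrieval, env, balance_pairs = TRUE, seed = 2)
  expect_true(all(bal$n_pairs == min(full$n_pairs)))
  zf <- setNames(full$z, full$condition); zb <- setNames(bal$z, bal$condition)
  expect_gt(zb["unique_within"], zb["unique_between"])
  # seeded subsampling is deterministic
  bal2 <- holisticPS(tmpl, sub$retrieval, env, balance_pairs = TRUE, seed = 2)
  expect_identical(bal, bal2)
})

test_that("pooled and per-task analyses agree up to sampling error", {
  env <- fxEnv()
  sub <- fxSubject(17, effectSpec(eta_holistic = 0.6))
  tmpl <- buildStoreTemplates(sub$localizer)
  td <- trialData(sub$retrieval)
  zs <- lapply(c("spatial", "temporal"), function(tk) {
    keep <- which(td$task == tk)
    ps <- PatternSet(patterns(sub$retrieval)[keep, ], td[keep, ],
                     voxelTSNR = voxelTSNR(sub$retrieval))
    res <- holisticPS(tmpl, ps, env)
    setNames(res$z, res$condition)
  })
  for (z in zs) expect_gt(z["unique_within"], z["unique_between"])
})
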