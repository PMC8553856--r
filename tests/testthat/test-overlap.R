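test_that("between-city pair rules match a brute-force enumerator on toy metadata", {
  env <- fxEnv()
  # 20-trial toy metadata spanning all sharing classes and cities
  td <- data.frame(
    run = rep(1:4, each = 5),
    city = rep(c(1, 2, 3, 1), each = 5),
    task = rep(c("spatial", "spatial", "temporal", "temporal"), each = 5),
    store_top = c(1, 4, 2, 1, 3,   1, 7, 2, 1, 3,   0, 0, 0, 0, 0,
                  0, 0, 0, 0, 0),
    store_bl  = c(4, 2, 1, 3, 5,   7, 2, 1, 3, 5,   1, 3, 8, 1, 7,
                  1, 3, 4, 1, 2),
    store_br  = c(5, 3, 6, 5, 4,   5, 3, 6, 5, 7,   3, 5, 9, 5, 8,
                  3, 5, 6, 5, 6),
    correct = TRUE, censored = FALSE
  )
  td$correct[2] <- FALSE; td$censored[13] <- TRUE
  set.seed(2)
  ps <- PatternSet(matrix(rnorm(20 * 15), 20, 15), td)
  res <- betweenCityPS(ps, env)

  # oracle: literal nested loops over trial pairs, straight off the rules
  sets <- lapply(seq_len(20), function(i)
    sort(setdiff(c(td$store_top[i], td$store_bl[i], td$store_br[i]), 0)))
  level <- vapply(seq_len(20), function(i)
    classifySharing(c(td$store_top[i], td$store_bl[i], td$store_br[i]),
                    env)$level, character(1))
  counts <- c(unique = 0, two_shared = 0, three_shared = 0)
  for (i in 1:19) for (j in (i + 1):20) {
    if (!td$correct[i] || !td$correct[j] || td$censored[i] || td$censored[j])
      next
    if (td$city[i] == td$city[j]) next
    if (level[i] != level[j]) next
    if (level[i] == "unique") {
      if (length(intersect(sets[[i]], sets[[j]])) == 0)
        counts["unique"] <- counts["unique"] + 1
    } else if (identical(sets[[i]], sets[[j]])) {
      counts[level[i]] <- counts[level[i]] + 1
    }
  }
  expect_equal(setNames(res$n_pairs, res$condition), counts)
  # between-city pairs are necessarily cross-run (one city per run)
  expect_true(all(td$run[td$city == 1] != td$run[td$city == 2]))
})

test_that("repulsion score trivia: sign follows the construction", {
  expect_equal(repulsionScore(0.2, 0.2), 0)
  expect_lt(repulsionScore(0.2, 0.1), 0)
  expect_gt(repulsionScore(0.1, 0.3), 0)
})

test_that("three-shared similarity explodes when shared codes are identical and noiseless", {
  env <- fxEnv()
  sub <- fxSubject(41, effectSpec(rho_shared = 1, sigma_noise = 0))
  res <- betweenCityPS(sub$retrieval, env, condition = "three_shared")
  expect_gt(res$z, 2)
})

test_that("planted rho recovers separation vs repulsion regimes", {
  env <- fxEnv()
  score <- function(seed, rho) {
    sub <- fxSubject(seed, effectSpec(rho_shared = rho))
    res <- betweenCityPS(sub$retrieval, env,
                         condition = c("unique", "three_shared"))
    z <- setNames(res$z, res$condition)
    repulsionScore(z["unique"], z["three_shared"])
  }
  rep_scores <- vapply(1:25, score, numeric(1), rho = -0.3)
  sep_scores <- vapply(26:50, score, numeric(1), rho = 0)
  expect_gt(mean(rep_scores < 0), 0.9)        # repulsion: sign recovered
  expect_gt(t.test(sep_scores)$p.value, 0.01) # separation: no systematic sign
  expect_lt(t.test(rep_scores, sep_scores)$p.value, 1e-3)
})

test_that("two-shared similarity interpolates between unique and three-shared", {
  env <- fxEnv()
  diffs <- t(vapply(1:20, function(seed) {
    sub <- fxSubject(seed + 300, effectSpec(rho_shared = c(0, -0.4)))
    res <- betweenCityPS(sub$retrieval, env)
    z <- setNames(res$z, res$condition)
    c(z["two_shared"] - z["three_shared"], z["unique"] - z["three_shared"])
  }, numeric(2)))
  expect_lt(t.test(diffs[, 1])$p.value, 0.05)
  expect_gt(mean(diffs[, 1]), 0)  # two_shared above three_shared
  expect_gt(mean(diffs[, 2]), 0)  # unique above three_shared
})

test_that("equal-pair-count control preserves the repulsion sign", {
  env <- fxEnv()
  signs <- vapply(1:15, function(seed) {
    sub <- fxSubject(seed + 500, effectSpec(rho_shared = -0.4))
    res <- betweenCityPS(sub$retrieval, env,
                         condition = c("unique", "three_shared"),
                         balance_pairs = TRUE, seed = seed)
    expect_equal(res$n_pairs[1], res$n_pairs[2])
    z <- setNames(res$z, res$condition)
    unname(z["three_shared"] - z["unique"])
  }, numeric(1))
  expect_gt(mean(signs < 0), 0.8)
})

test_that("empty conditions and per-task restriction behave as specified", {
  env <- fxEnv()
  td <- data.frame(run = 1:2, city = c(1, 2), task = "spatial",
                   store_top = c(1, 1), store_bl = c(2, 2),
                   store_br = c(6, 6), correct = TRUE, censored = FALSE)
  ps <- PatternSet(matrix(rnorm(2 * 10), 2, 10), td)
  expect_error(betweenCityPS(ps, env, condition = "three_shared"),
               "no qualifying pairs")
  sub <- fxSubject(61, effectSpec())
  pooled <- betweenCityPS(sub$retrieval, env, condition = "unique")
  sp <- betweenCityPS(sub$retrieval, env, condition = "unique",
                      task = "spatial")
  expect_lt(sp$n_pairs, pooled$n_pairs)
})
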