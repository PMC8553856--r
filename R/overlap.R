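# Between-city pair rules.  Trials are labeled by the sharing class of
# their triad (attributable to 1, 2 or 3 cities).  Qualifying pairs are
# always from different cities (hence different runs, since each run tests
# one city):
#   unique:       both triads unique-class, store sets disjoint (the shared
#                 center store of temporal triads is ignored in the
#                 disjointness check, as it belongs to every city);
#   two_shared:   identical store sets attributable to exactly two cities;
#   three_shared: identical store sets attributable to all three cities.
.trialSharing <- function(td, env) {
  vapply(seq_len(nrow(td)), function(i) {
    classifySharing(c(td$store_top[i], td$store_bl[i], td$store_br[i]),
                    env)$level
  }, character(1))
}

.storeSets <- function(td, env) {
  lapply(seq_len(nrow(td)), function(i) {
    sort(setdiff(c(td$store_top[i], td$store_bl[i], td$store_br[i]),
                 env@center_id))
  })
}

# Enumerate qualifying trial-pair indices for one condition.
.betweenCityPairs <- function(td, env, condition, idx) {
  sharing <- .trialSharing(td[idx, , drop = FALSE], env)
  sets <- .storeSets(td[idx, , drop = FALSE], env)
  cand <- which(sharing == condition)
  out <- list()
  if (length(cand) >= 2L) {
    for (a in seq_along(cand)[-length(cand)]) {
      for (b in (a + 1L):length(cand)) {
        i <- cand[a]; j <- cand[b]
        if (td$city[idx[i]] == td$city[idx[j]]) next
        if (condition == "unique") {
          if (length(intersect(sets[[i]], sets[[j]]))) next
        } else {
          if (!identical(sets[[i]], sets[[j]])) next
        }
        out[[length(out) + 1L]] <- c(idx[i], idx[j])
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(0), 0, 2)
}

#' Between-city pattern similarity by sharing class
#'
#' Computes the mean Fisher-z Pearson similarity between correctly
#' retrieved, uncensored trials of different cities within one sharing
#' condition, under the pair rules above.  Pattern-separated shared codes
#' predict three_shared similarity comparable to the unique baseline;
#' repulsed codes predict it below the baseline.
#'
#' @param retrieval a retrieval \linkS4class{PatternSet}.
#' @param env the \linkS4class{CityEnvironment}.
#' @param condition \code{"unique"}, \code{"two_shared"} or
#'   \code{"three_shared"} (default: all three).
#' @param mask optional \code{TSNRMask} or voxel index vector.
#' @param task restrict trials to one task (\code{"spatial"} or
#'   \code{"temporal"}); the default \code{NULL} pools both tasks, so
#'   within-task and cross-task pairs are included.
#' @param balance_pairs subsample all conditions to the minimum condition
#'   pair count (seeded), the equal-pair-count control.
#' @param seed seed for the balancing subsample.
#' @param detail also return the per-pair Fisher z values (attribute
#'   \code{"pair_z"}, a named list by condition), for pair-level tests.
#' @param disjoint_pairs greedily thin each condition's pair set (seeded
#'   random order) so no trial contributes to more than one pair, reducing
#'   the dependence among pair-level values for within-subject tests.
#' @return data.frame: condition, z, n_pairs.
#' @export
betweenCityPS <- function(retrieval, env,
                          condition = c("unique", "two_shared",
                                        "three_shared"),
                          mask = NULL, task = NULL, balance_pairs = FALSE,
                          seed = 1, detail = FALSE, disjoint_pairs = FALSE) {
  condition <- match.arg(condition, several.ok = TRUE)
  td <- trialData(retrieval)
  pat <- patterns(retrieval)
  keep <- .maskIndices(mask, ncol(pat))
  use <- usableTrials(retrieval)
  if (!is.null(task)) use <- use & td$task == task
  idx <- which(use)
  if (!length(idx)) stop("no usable trials")
  C <- suppressWarnings(stats::cor(t(pat[, keep, drop = FALSE])))
  pairsets <- lapply(condition, function(cond) {
    pr <- .betweenCityPairs(td, env, cond, idx)
    if (!nrow(pr)) stop("no qualifying pairs for condition '", cond, "'")
    pr
  })
  names(pairsets) <- condition
  if (disjoint_pairs) {
    pairsets <- .withSeed(.substream(seed, "disjoint-pairs"), {
      lapply(pairsets, function(pr) {
        pr <- pr[sample.int(nrow(pr)), , drop = FALSE]
        used <- logical(max(pr))
        keep <- logical(nrow(pr))
        for (k in seq_len(nrow(pr))) {
          if (!used[pr[k, 1]] && !used[pr[k, 2]]) {
            used[pr[k, ]] <- TRUE
            keep[k] <- TRUE
          }
        }
        pr[keep, , drop = FALSE]
      })
    })
  }
  if (balance_pairs) {
    nmin <- min(vapply(pairsets, nrow, integer(1)))
    pairsets <- .withSeed(.substream(seed, "balance-between"), {
      lapply(pairsets, function(pr)
        pr[sample.int(nrow(pr), nmin), , drop = FALSE])
    })
  }
  zlists <- lapply(pairsets, function(pr) {
    r <- C[pr]
    fisherZ(r[!is.na(r)])
  })
  res <- do.call(rbind, lapply(condition, function(cond) {
    data.frame(condition = cond, z = mean(zlists[[cond]]),
               n_pairs = length(zlists[[cond]]))
  }))
  if (detail) attr(res, "pair_z") <- zlists
  res
}

#' Repulsion difference score
#'
#' Relative difference in between-city similarity for three-shared vs
#' unique trials: \code{three_shared_z - unique_z}.  Negative values
#' indicate repulsion (shared content made \emph{less} similar across
#' cities than unrelated content); values near zero indicate pattern
#' separation.
#'
#' @param unique_z,three_shared_z Fisher-z between-city similarities from
#'   the same region and tSNR aggregation.
#' @return numeric difference score.
#' @export
repulsionScore <- function(unique_z, three_shared_z) {
  three_shared_z - unique_z
}
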