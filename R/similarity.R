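#' Build per-store pattern templates from localizer trials
#'
#' Averages the single-trial localizer patterns of each studied store across
#' its repetitions (six by default: three per run, two runs), giving an
#' environment-independent probe of that store's memory trace.
#'
#' @param localizer a \linkS4class{PatternSet} from the localizer task whose
#'   trialData has a \code{store_old} column.
#' @param stores studied store ids to build templates for.
#' @return list of class \code{"StoreTemplates"}: \code{templates} (stores x
#'   voxels matrix, rownames = store ids), \code{n_reps} per store.
#' @export
buildStoreTemplates <- function(localizer,
                                stores = c(2L, 4L, 6L, 7L, 8L, 9L)) {
  td <- trialData(localizer)
  if (!"store_old" %in% names(td)) {
    stop("localizer trialData must have a 'store_old' column")
  }
  pat <- patterns(localizer)
  use <- usableTrials(localizer)
  tmpl <- matrix(NA_real_, length(stores), ncol(pat),
                 dimnames = list(as.character(stores), NULL))
  n_reps <- integer(length(stores))
  for (k in seq_along(stores)) {
    idx <- which(use & td$store_old == stores[k])
    if (!length(idx)) stop("store ", stores[k], " has no usable repetitions")
    tmpl[k, ] <- colMeans(pat[idx, , drop = FALSE])
    n_reps[k] <- length(idx)
  }
  structure(list(templates = tmpl,
                 n_reps = stats::setNames(n_reps, as.character(stores))),
            class = "StoreTemplates")
}

# Pearson correlations between one template and many trial patterns on the
# kept voxels; zero-variance patterns yield NA and are dropped by callers.
.templateTrialCor <- function(tmpl_vec, pat, rows, keep) {
  if (!length(rows)) return(numeric(0))
  suppressWarnings(
    as.numeric(stats::cor(tmpl_vec[keep],
                          t(pat[rows, keep, drop = FALSE])))
  )
}

# Enumerate the (template store, trial) pairs of one holistic condition.
.holisticPairs <- function(td, env, use) {
  stores <- c(2L, 4L, 6L, 7L, 8L, 9L)
  trio <- cbind(td$store_top, td$store_bl, td$store_br)
  out <- list(unique_within = list(), shared_within = list(),
              unique_between = list())
  for (s in stores) {
    sh <- classifySharing(s, env)
    own <- match(sh$attributable_cities, names(env@cities))
    contains_s <- trio[, 1] == s | trio[, 2] == s | trio[, 3] == s
    if (sh$level == "unique") {
      out$unique_within[[as.character(s)]] <-
        which(use & td$city %in% own & !contains_s)
      out$unique_between[[as.character(s)]] <-
        which(use & !td$city %in% own)
    } else {
      out$shared_within[[as.character(s)]] <-
        which(use & td$city %in% own & !contains_s)
    }
  }
  out
}

#' Template-based holistic-reinstatement pattern similarity
#'
#' Correlates each store template with the correctly retrieved, uncensored
#' trial patterns under the three holistic-retrieval conditions:
#' \describe{
#'   \item{unique_within}{template of a store unique to one city vs trials
#'     of that city that do not present the store — reinstatement of an
#'     unpresented unique landmark.}
#'   \item{unique_between}{the same template vs trials of the other cities.}
#'   \item{shared_within}{template of a store shared between cities vs
#'     trials of its sharing cities that do not present it.}
#' }
#' Each Pearson r is Fisher-z transformed; the condition value is the mean z
#' over all template-trial pairs.  Holistic, differentiated retrieval
#' predicts unique_within above both other conditions.
#'
#' @param templates a \code{StoreTemplates} from [buildStoreTemplates()].
#' @param retrieval a retrieval \linkS4class{PatternSet}.
#' @param env the \linkS4class{CityEnvironment}.
#' @param mask optional \code{TSNRMask} or voxel index vector.
#' @param balance_pairs subsample every condition to the smallest condition
#'   pair count (seeded), the equal-pair-count control.
#' @param seed seed for the balancing subsample.
#' @return data.frame: condition, z (mean Fisher z), n_pairs, n_dropped
#'   (zero-variance pairs excluded).
#' @export
holisticPS <- function(templates, retrieval, env, mask = NULL,
                       balance_pairs = FALSE, seed = 1) {
  td <- trialData(retrieval)
  pat <- patterns(retrieval)
  keep <- .maskIndices(mask, ncol(pat))
  use <- usableTrials(retrieval)
  pairs <- .holisticPairs(td, env, use)
  rvals <- lapply(pairs, function(bystore) {
    unlist(lapply(names(bystore), function(s) {
      .templateTrialCor(templates$templates[s, ], pat, bystore[[s]], keep)
    }))
  })
  if (balance_pairs) {
    nmin <- min(vapply(rvals, length, integer(1)))
    rvals <- .withSeed(.substream(seed, "balance-holistic"), {
      lapply(rvals, function(r) r[sample.int(length(r), nmin)])
    })
  }
  res <- lapply(names(rvals), function(cond) {
    r <- rvals[[cond]]
    dropped <- sum(is.na(r))
    r <- r[!is.na(r)]
    if (!length(r)) stop("condition '", cond, "' has no usable pairs")
    data.frame(condition = cond, z = mean(fisherZ(r)), n_pairs = length(r),
               n_dropped = dropped)
  })
  do.call(rbind, res)
}
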