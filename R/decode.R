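# Kolmogorov-Smirnov test of a binned sample against the discrete uniform
# over a fixed bin set: D is the largest gap between the empirical CDF and
# the uniform CDF at the bin atoms (both step sides), with the asymptotic
# Kolmogorov p-value.
.ksUniformDiscrete <- function(counts) {
  n <- sum(counts)
  K <- length(counts)
  if (n == 0L) stop("no trials to test")
  emp <- cumsum(counts) / n
  unif <- seq_len(K) / K
  D <- max(abs(emp - unif), abs(c(0, emp[-K]) - unif))
  x <- sqrt(n) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  list(statistic = D, p.value = min(max(p, 0), 1))
}

#' Trim trials to a uniform distance distribution
#'
#' The spatial-distance decoder requires the distance-index distribution to
#' be uniform over its bins; over-represented short distances otherwise
#' bias the regression.  Trials are removed one at a time from the fullest
#' bin (ties broken toward the shortest distance; seeded random choice of
#' trial within the bin) until a Kolmogorov-Smirnov test against the
#' discrete uniform over \code{bins} exceeds \code{alpha}.  Performed per
#' subject.
#'
#' @param trials data.frame of spatial trials with a \code{dist_index}
#'   column (correct, uncensored trials only).
#' @param bins reference bin values; defaults to the distinct distances
#'   observed in \code{trials}.
#' @param alpha uniformity criterion (KS p-value must exceed it).
#' @param seed integer seed for within-bin removal choices.
#' @return list: \code{trials} (trimmed data.frame), \code{removed}
#'   (original row positions removed), \code{p.value}, \code{statistic},
#'   \code{counts} (final per-bin counts).
#' @export
enforceUniformDistance <- function(trials, bins = NULL, alpha = 0.05,
                                   seed = 1) {
  if (!"dist_index" %in% names(trials)) {
    stop("trials must carry a dist_index column")
  }
  d <- round(trials$dist_index, 9)
  if (is.null(bins)) bins <- sort(unique(d))
  bins <- sort(round(bins, 9))
  if (!all(d %in% bins)) stop("trials contain distances outside 'bins'")
  alive <- rep(TRUE, nrow(trials))
  .withSeed(.substream(seed, "uniform-trim"), {
    repeat {
      counts <- vapply(bins, function(b) sum(alive & d == b), integer(1))
      ks <- .ksUniformDiscrete(counts)
      if (ks$p.value > alpha) break
      if (any(counts == 0L)) {
        stop("uniformity unattainable: reference bin(s) at distance ",
             paste(bins[counts == 0L], collapse = ", "),
             " contain no trials and removal cannot populate them")
      }
      modal <- bins[counts == max(counts)][1]  # fullest bin, shortest first
      inbin <- which(alive & d == modal)
      if (length(inbin) <= 1L) {
        stop("bin at distance ", modal, " exhausted before uniformity ",
             "(KS p = ", signif(ks$p.value, 3), ", counts: ",
             paste(counts, collapse = ","), ")")
      }
      alive[inbin[sample.int(length(inbin), 1)]] <- FALSE
    }
    counts <- vapply(bins, function(b) sum(alive & d == b), integer(1))
    ks <- .ksUniformDiscrete(counts)
    list(trials = trials[alive, , drop = FALSE], removed = which(!alive),
         p.value = ks$p.value, statistic = ks$statistic,
         counts = stats::setNames(counts, bins))
  })
}

#' Leave-one-city-out support-vector regression of spatial distance
#'
#' Tests for a distance code that generalizes across environments: a linear
#' SVR is trained on the spatial trials of two cities to predict the
#' distance index, and evaluated on the held-out city; accuracy is the
#' Spearman rank correlation between actual and predicted indices, Fisher-z
#' transformed, averaged over the three folds.  Chance level is 0.
#'
#' @param patternSet a retrieval \linkS4class{PatternSet}.
#' @param env the \linkS4class{CityEnvironment}.
#' @param mask optional voxel mask.
#' @param enforce_uniform apply [enforceUniformDistance()] first.
#' @param cost,epsilon linear-SVR hyperparameters.
#' @param scale standardize features before training (off by default).
#' @param seed seed (uniformity trimming).
#' @param alpha uniformity criterion passed through.
#' @return list of class \code{"DecodeResult"}: \code{scheme}, \code{folds}
#'   (data.frame city/rho/z/n_test), \code{overall} (mean z), \code{chance}.
#' @export
svrLeaveOneCityOut <- function(patternSet, env, mask = NULL,
                               enforce_uniform = TRUE, cost = 1,
                               epsilon = 0.1, scale = FALSE, seed = 1,
                               alpha = 0.05) {
  td <- trialData(patternSet)
  pat <- patterns(patternSet)
  keep <- .maskIndices(mask, ncol(pat))
  use <- usableTrials(patternSet) & td$task == "spatial"
  td <- td[use, , drop = FALSE]
  pat <- pat[use, keep, drop = FALSE]
  # 9-decimal rounding makes geometrically equal distances exact ties
  td$dist_index <- round(spatialDistanceIndex(td$store_top, td$store_bl,
                                              td$store_br, env), 9)
  if (enforce_uniform) {
    td$.row <- seq_len(nrow(td))
    trim <- enforceUniformDistance(td, seed = seed, alpha = alpha)
    pat <- pat[trim$trials$.row, , drop = FALSE]
    td <- trim$trials
  }
  folds <- lapply(sort(unique(td$city)), function(cty) {
    test <- td$city == cty
    if (sum(test) < 3L) stop("held-out city ", cty, " has fewer than 3 trials")
    fit <- e1071::svm(pat[!test, , drop = FALSE], td$dist_index[!test],
                      type = "eps-regression", kernel = "linear",
                      cost = cost, epsilon = epsilon, scale = scale)
    pred <- stats::predict(fit, pat[test, , drop = FALSE])
    rho <- suppressWarnings(
      stats::cor(td$dist_index[test], pred, method = "spearman"))
    data.frame(city = cty, rho = rho, z = fisherZ(rho), n_test = sum(test))
  })
  folds <- do.call(rbind, folds)
  structure(list(scheme = "svr_distance", folds = folds,
                 overall = mean(folds$z), chance = 0),
            class = "DecodeResult")
}

# Balance class counts by seeded subsampling to the smallest class.
.balanceClasses <- function(labels, idx) {
  tab <- table(labels[idx])
  if (any(tab == 0)) stop("a class is empty: ", paste(names(tab)[tab == 0],
                                                      collapse = ", "))
  nmin <- min(tab)
  unlist(lapply(names(tab), function(l) {
    cand <- idx[labels[idx] == l]
    cand[sample.int(length(cand), nmin)]
  }), use.names = FALSE)
}

#' Leave-one-city-out SVM classification of temporal interval
#'
#' Three-class (16/24/32 s) linear SVM trained on the temporal trials of
#' two cities and tested on the third, with class counts balanced by seeded
#' subsampling in both training and test sets.  Chance level is 1/3.
#'
#' @inheritParams svrLeaveOneCityOut
#' @param cost SVM penalty parameter.
#' @return \code{DecodeResult} with per-fold proportion correct.
#' @export
svmIntervalLeaveOneCityOut <- function(patternSet, env, mask = NULL,
                                       cost = 1, seed = 1) {
  td <- trialData(patternSet)
  pat <- patterns(patternSet)
  keep <- .maskIndices(mask, ncol(pat))
  use <- usableTrials(patternSet) & td$task == "temporal"
  td <- td[use, , drop = FALSE]
  pat <- pat[use, keep, drop = FALSE]
  lab <- factor(temporalIntervalIndex(td$store_top, td$store_bl,
                                      td$store_br, env))
  .withSeed(.substream(seed, "svm-interval"), {
    folds <- lapply(sort(unique(td$city)), function(cty) {
      tr <- .balanceClasses(lab, which(td$city != cty))
      te <- .balanceClasses(lab, which(td$city == cty))
      fit <- e1071::svm(pat[tr, , drop = FALSE], droplevels(lab[tr]),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, pat[te, , drop = FALSE])
      data.frame(city = cty,
                 accuracy = mean(as.character(pred) == as.character(lab[te])),
                 n_test = length(te))
    })
    folds <- do.call(rbind, folds)
    structure(list(scheme = "svm_interval", folds = folds,
                   overall = mean(folds$accuracy), chance = 1 / 3),
              class = "DecodeResult")
  })
}

#' City classification from run-level patterns
#'
#' Linear SVM (penalty parameter 1) classifying the three cities from the
#' 12 run-level t-maps (4 per city) under leave-three-runs-out
#' cross-validation: every combination of one held-out run per city (4^3 =
#' 64 folds) is trained on the remaining 9 runs, and each held-out run is
#' assigned the class with the highest probability estimate.  Accuracy is
#' reported per city and overall against the 33.33\% chance level.
#'
#' @param runPatterns a \linkS4class{PatternSet} of run-level maps with
#'   trialData columns \code{run} and \code{city} (4 runs per city).
#' @param mask optional voxel mask.
#' @param cost SVM penalty parameter.
#' @return \code{DecodeResult}: per-city accuracy over the 64 folds,
#'   \code{overall} mean accuracy, \code{chance} = 1/3.
#' @export
svmCity <- function(runPatterns, mask = NULL, cost = 1) {
  td <- trialData(runPatterns)
  pat <- patterns(runPatterns)
  keep <- .maskIndices(mask, ncol(pat))
  pat <- pat[, keep, drop = FALSE]
  cities <- sort(unique(td$city))
  runsByCity <- lapply(cities, function(cty) which(td$city == cty))
  if (any(lengths(runsByCity) != 4L)) {
    stop("expected 4 run maps per city; got ",
         paste(lengths(runsByCity), collapse = ","))
  }
  combos <- expand.grid(runsByCity)
  lab <- factor(td$city)
  correct <- matrix(NA, nrow(combos), length(cities))
  for (f in seq_len(nrow(combos))) {
    test <- as.integer(combos[f, ])
    train <- setdiff(seq_len(nrow(pat)), test)
    fit <- e1071::svm(pat[train, , drop = FALSE], lab[train],
                      kernel = "linear", cost = cost, scale = FALSE,
                      probability = TRUE)
    pred <- stats::predict(fit, pat[test, , drop = FALSE],
                           probability = TRUE)
    pr <- attr(pred, "probabilities")
    cls <- if (!is.null(pr)) colnames(pr)[max.col(pr)] else
      as.character(pred)
    correct[f, ] <- cls == as.character(lab[test])
  }
  folds <- data.frame(city = cities, accuracy = colMeans(correct),
                      n_folds = nrow(combos))
  structure(list(scheme = "svm_city", folds = folds,
                 overall = mean(correct), chance = 1 / 3),
            class = "DecodeResult")
}

#' @export
print.DecodeResult <- function(x, ...) {
  cat("DecodeResult [", x$scheme, "]  overall = ", round(x$overall, 4),
      "  (chance ", round(x$chance, 4), ")\n", sep = "")
  print(x$folds, row.names = FALSE)
  invisible(x)
}
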