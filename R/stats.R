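#' Spearman partial correlation
#'
#' Rank-based partial correlation of \code{x} and \code{y} given one or
#' more control variables: all variables are rank-transformed, \code{x} and
#' \code{y} are residualized on the (ranked) controls by least squares, and
#' the residuals are correlated.  Invariant to monotone transforms of any
#' input and symmetric in \code{x}, \code{y}.
#'
#' @param x,y numeric vectors (length >= 4).
#' @param control numeric vector or matrix of control variables.
#' @return partial Spearman rho.
#' @export
partialSpearman <- function(x, y, control) {
  control <- as.matrix(control)
  n <- length(x)
  stopifnot(length(y) == n, nrow(control) == n)
  if (n < 4) stop("need at least 4 observations")
  vars <- cbind(x, y, control)
  if (any(apply(vars, 2, stats::sd) == 0)) stop("constant input vector")
  rx <- rank(x); ry <- rank(y)
  rc <- apply(control, 2, rank)
  Z <- cbind(1, rc)
  ex <- stats::lm.fit(Z, rx)$residuals
  ey <- stats::lm.fit(Z, ry)$residuals
  stats::cor(ex, ey)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up FDR adjustment of a vector of p-values with rejection decisions
#' at level \code{q}.
#'
#' @param pvalues numeric p-values (finite).
#' @param q FDR level.
#' @return data.frame: p, p_adjusted, rejected.
#' @export
fdrCorrect <- function(pvalues, q = 0.05) {
  stopifnot(all(is.finite(pvalues)))
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adjusted = adj, rejected = adj <= q)
}

#' Cohen's d for paired contrasts
#'
#' Mean of the paired differences divided by the SD of the differences.
#'
#' @param x,y paired measurements, or \code{y = NULL} to treat \code{x} as
#'   the differences (one-sample d against zero).
#' @return numeric effect size.
#' @export
cohensD <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  mean(d) / stats::sd(d)
}

#' Regional modulation of pattern similarity (one subject)
#'
#' For each similarity condition, computes the Fisher-z Spearman partial
#' correlation between a region's activation and the per-pair pattern
#' similarity of a target ROI, controlling for the target ROI's own
#' activation level on the same analysis units (template-trial or
#' trial-trial pairs).  The modulation contrast is
#' \code{z(unique_within) - z(unique_between)}.
#'
#' @param region_activation numeric vector, the modulating region's mean
#'   activation per analysis unit.
#' @param ps numeric vector, the target ROI's Fisher-z similarity per unit.
#' @param roi_activation numeric vector, the target ROI's activation per
#'   unit (the control variable).
#' @param condition character vector labeling each unit's condition.
#' @return list of class \code{"ModulationResult"}: \code{conditions}
#'   data.frame (condition, partial_rho, z, n), \code{contrast}.
#' @export
modulationMap <- function(region_activation, ps, roi_activation, condition) {
  n <- length(ps)
  if (length(region_activation) != n || length(roi_activation) != n ||
      length(condition) != n) {
    stop("misaligned unit counts across inputs")
  }
  conds <- unique(condition)
  rows <- lapply(conds, function(cc) {
    i <- condition == cc
    rho <- partialSpearman(region_activation[i], ps[i], roi_activation[i])
    data.frame(condition = cc, partial_rho = rho, z = fisherZ(rho),
               n = sum(i))
  })
  rows <- do.call(rbind, rows)
  contrast <- if (all(c("unique_within", "unique_between") %in% conds)) {
    rows$z[rows$condition == "unique_within"] -
      rows$z[rows$condition == "unique_between"]
  } else NA_real_
  structure(list(conditions = rows, contrast = contrast),
            class = "ModulationResult")
}

#' Group test over per-subject modulation results
#'
#' One-sample t-test of each condition's Fisher-z partial correlation
#' against zero across subjects, with BH-FDR correction over conditions,
#' plus the paired contrast test.
#'
#' @param results list of \code{ModulationResult} (one per subject).
#' @param q FDR level.
#' @return data.frame: condition, mean_z, t, df, p, p_adjusted, rejected,
#'   cohens_d.
#' @export
modulationGroupTest <- function(results, q = 0.05) {
  zmat <- sapply(results, function(r)
    stats::setNames(r$conditions$z, r$conditions$condition))
  out <- lapply(rownames(zmat), function(cc) {
    z <- zmat[cc, ]
    tt <- stats::t.test(z)
    data.frame(condition = cc, mean_z = mean(z),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohens_d = cohensD(z))
  })
  out <- do.call(rbind, out)
  fdr <- fdrCorrect(out$p, q)
  out$p_adjusted <- fdr$p_adjusted
  out$rejected <- fdr$rejected
  out
}
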