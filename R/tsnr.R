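#' Per-voxel temporal signal-to-noise ratio
#'
#' tSNR of a voxel is the mean of its time series divided by its standard
#' deviation (sample SD, n - 1).  Zero-variance voxels have undefined tSNR
#' and are returned as \code{NA} with a warning; downstream percentile
#' masks exclude them.
#'
#' @param Y frames x voxels time-series matrix (at least 2 frames).
#' @return numeric vector of per-voxel tSNR.
#' @examples
#' computeTSNR(cbind(c(90, 100, 110)))  # mean 100 / sd 10 = 10
#' @export
computeTSNR <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 time points per voxel")
  m <- colMeans(Y)
  s <- apply(Y, 2, stats::sd)
  out <- ifelse(s > 0, m / s, NA_real_)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " zero-variance voxel(s) excluded (tSNR undefined)")
  }
  out
}

#' Percentile-threshold a tSNR distribution into a voxel mask
#'
#' Removes voxels whose tSNR falls strictly below the \code{level}-th
#' percentile of the region's tSNR distribution (linear-interpolation
#' percentile; ties with the cutoff are kept).  The eight standard levels
#' 10..80 produce nested kept sets, and analyses are typically averaged
#' across all eight (see [tsnrMaskSet()]).
#'
#' @param tsnr_values numeric vector of per-voxel tSNR (\code{NA} = excluded).
#' @param level percentile level, one of 10, 20, ..., 80.
#' @return list of class \code{"TSNRMask"}: \code{level}, \code{cutoff},
#'   \code{kept_voxels} (integer indices).
#' @examples
#' thresholdByPercentile(1:10, 10)$kept_voxels  # drops the tSNR-1 voxel
#' @export
thresholdByPercentile <- function(tsnr_values, level) {
  if (!level %in% seq(10, 80, by = 10)) {
    stop("level must be one of 10, 20, ..., 80")
  }
  ok <- which(!is.na(tsnr_values))
  if (!length(ok)) stop("empty ROI: no voxels with defined tSNR")
  cutoff <- stats::quantile(tsnr_values[ok], level / 100, names = FALSE)
  kept <- ok[tsnr_values[ok] >= cutoff]
  structure(list(level = level, cutoff = cutoff, kept_voxels = kept),
            class = "TSNRMask")
}

#' @rdname thresholdByPercentile
#' @param levels percentile levels for the mask set.
#' @export
tsnrMaskSet <- function(tsnr_values, levels = seq(10, 80, by = 10)) {
  stats::setNames(lapply(levels, function(l)
    thresholdByPercentile(tsnr_values, l)), paste0("p", levels))
}

# Resolve a mask argument (NULL, TSNRMask, or integer indices) to voxel
# indices into a PatternSet.
.maskIndices <- function(mask, n_voxels) {
  if (is.null(mask)) return(seq_len(n_voxels))
  if (inherits(mask, "TSNRMask")) return(mask$kept_voxels)
  as.integer(mask)
}

#' Average a tSNR-gated similarity analysis across the eight levels
#'
#' Runs an analysis function once per tSNR percentile mask (derived from the
#' PatternSet's own per-voxel tSNR) and averages the resulting Fisher-z
#' values across levels, the aggregation used for all ROI-based similarity
#' summaries.
#'
#' @param fun analysis function taking \code{(patternSet, ..., mask = )} and
#'   returning a data.frame with columns \code{condition} and \code{z}.
#' @param patternSet a \linkS4class{PatternSet} with defined voxel tSNR.
#' @param ... further arguments to \code{fun}.
#' @param levels percentile levels to average over.
#' @return data.frame with per-condition z averaged across levels.
#' @export
averageAcrossTSNR <- function(fun, patternSet, ..., levels = seq(10, 80, 10)) {
  masks <- tsnrMaskSet(voxelTSNR(patternSet), levels)
  per <- lapply(masks, function(m) {
    res <- fun(patternSet, ..., mask = m)
    res$tsnr_level <- m$level
    res
  })
  all <- do.call(rbind, per)
  agg <- stats::aggregate(z ~ condition, data = all, FUN = mean)
  agg$n_levels <- length(levels)
  agg
}
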