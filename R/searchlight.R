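#' Same-location vs different-location between-city similarity
#'
#' Tests for a shared spatial-layout (schema) code: between-city trial
#' pairs whose triads occupy the same three coordinate slots are compared
#' with pairs at different slots.  Because different-location pairs also
#' differ in more store identities, the different-location set is matched
#' to the same-location set on the number of differing stores: pairs are
#' stratified by that count, and only strata present in the same-location
#' set contribute, weighted by the same-location stratum sizes.  Strata
#' with no matched different-location pair are dropped with a message.
#'
#' @param patternSet a retrieval \linkS4class{PatternSet}.
#' @param env the \linkS4class{CityEnvironment}.
#' @param mask optional voxel mask.
#' @return list: \code{conditions} data.frame (condition, z, n_pairs),
#'   \code{contrast} (same minus different, stratum-weighted),
#'   \code{strata} per-stratum detail.
#' @export
sameLocationMPS <- function(patternSet, env, mask = NULL) {
  td <- trialData(patternSet)
  pat <- patterns(patternSet)
  keep <- .maskIndices(mask, ncol(pat))
  use <- which(usableTrials(patternSet))
  td <- td[use, , drop = FALSE]
  C <- suppressWarnings(stats::cor(t(pat[use, keep, drop = FALSE])))
  slotOf <- function(ids) sort(env@stores$slot[match(ids, env@stores$id)])
  trios <- lapply(seq_len(nrow(td)), function(i)
    c(td$store_top[i], td$store_bl[i], td$store_br[i]))
  slots <- lapply(trios, slotOf)
  n <- nrow(td)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (td$city[i] == td$city[j]) next
      same <- identical(slots[[i]], slots[[j]])
      ndiff <- 3L - length(intersect(trios[[i]], trios[[j]]))
      rows[[length(rows) + 1L]] <- data.frame(
        same = same, ndiff = ndiff, r = C[i, j])
    }
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[!is.na(pairs$r), ]
  strata <- sort(unique(pairs$ndiff[pairs$same]))
  detail <- list()
  for (k in strata) {
    s_r <- pairs$r[pairs$same & pairs$ndiff == k]
    d_r <- pairs$r[!pairs$same & pairs$ndiff == k]
    if (!length(d_r)) {
      message("no different-location pairs with ", k,
              " differing stores; stratum dropped")
      next
    }
    detail[[as.character(k)]] <- data.frame(
      ndiff = k, n_same = length(s_r), n_diff = length(d_r),
      z_same = mean(fisherZ(s_r)), z_diff = mean(fisherZ(d_r)))
  }
  if (!length(detail)) stop("no matched same/different-location strata")
  detail <- do.call(rbind, detail)
  w <- detail$n_same / sum(detail$n_same)
  z_same <- sum(w * detail$z_same)
  z_diff <- sum(w * detail$z_diff)
  list(
    conditions = data.frame(
      condition = c("same_location", "different_location"),
      z = c(z_same, z_diff),
      n_pairs = c(sum(detail$n_same), sum(detail$n_diff))),
    contrast = z_same - z_diff,
    strata = detail
  )
}

#' Cubic searchlight engine
#'
#' Recomputes a multivariate statistic within a sliding cubic neighborhood
#' (default edge 7, i.e. 343 voxels) centered on every in-mask voxel of a
#' volume.  Cubes are clipped at the volume boundary and intersected with
#' the mask; centers whose cube retains fewer than \code{min_frac} of
#' \code{edge^3} voxels get \code{NA}.
#'
#' @param volumes 4-D numeric array (x, y, z, trial) of single-trial maps.
#' @param mask 3-D logical array of analysis voxels (default: all).
#' @param statistic function taking a trials x voxels matrix (the cube's
#'   patterns) and returning one number; build trial metadata into its
#'   closure.
#' @param edge cube edge in voxels (odd).
#' @param min_frac minimum fraction of \code{edge^3} voxels a clipped cube
#'   must retain.
#' @return 3-D array of statistic values (NA outside mask / below floor).
#' @export
runSearchlight <- function(volumes, statistic, mask = NULL, edge = 7,
                           min_frac = 0.5) {
  stopifnot(length(dim(volumes)) == 4L, edge %% 2 == 1)
  dims <- dim(volumes)[1:3]
  n_trials <- dim(volumes)[4]
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), dims))
  half <- (edge - 1) / 2
  floor_n <- min_frac * edge^3
  flat <- matrix(volumes, prod(dims), n_trials)  # voxels x trials
  out <- array(NA_real_, dims)
  maskIdx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(maskIdx))) {
    cx <- maskIdx[v, 1]; cy <- maskIdx[v, 2]; cz <- maskIdx[v, 3]
    xs <- max(1, cx - half):min(dims[1], cx + half)
    ys <- max(1, cy - half):min(dims[2], cy + half)
    zs <- max(1, cz - half):min(dims[3], cz + half)
    cube <- as.vector(outer(outer(xs, (ys - 1) * dims[1], "+"),
                            (zs - 1) * dims[1] * dims[2], "+"))
    cube <- cube[mask[cube]]
    if (length(cube) < floor_n) next
    out[cx, cy, cz] <- statistic(t(flat[cube, , drop = FALSE]))
  }
  out
}
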