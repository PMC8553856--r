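#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' CityEnvironment: layout of partially overlapping store environments
#'
#' Encodes the store layout shared by three virtual cities: six peripheral
#' stores per city arranged on a circle around a common center store, with
#' some stores shared between cities and some unique to one city.  Every
#' peripheral store occupies a fixed coordinate slot, the same slot in every
#' city it appears in, so the physical layout is identical across cities and
#' only store identities differ.
#'
#' @slot stores data.frame with one row per store: \code{id} (integer, 0 is
#'   the center), \code{slot} (coordinate slot 0 for center, 1..6 on the
#'   circle), \code{angle} (radians), \code{radius}, \code{x}, \code{y},
#'   \code{duration_s} (encoded travel duration from the center, 8 or 16 s;
#'   \code{NA} for the center itself).
#' @slot cities named list of integer vectors, the six peripheral store ids
#'   of each city.
#' @slot center_id integer id of the shared center store.
#'
#' @seealso [buildEnvironment()]
#' @export
setClass("CityEnvironment",
  representation(
    stores = "data.frame",
    cities = "list",
    center_id = "integer"
  )
)

setValidity("CityEnvironment", function(object) {
  msg <- character()
  st <- object@stores
  need <- c("id", "slot", "angle", "radius", "x", "y", "duration_s")
  if (!all(need %in% names(st))) {
    return(paste("stores must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(st$id)) msg <- c(msg, "duplicate store ids")
  ctr <- st[st$id == object@center_id, ]
  if (nrow(ctr) != 1L) msg <- c(msg, "center store missing")
  else if (ctr$radius != 0) msg <- c(msg, "center store must have radius 0")
  periph <- st[st$id != object@center_id, ]
  if (length(unique(periph$radius)) > 1L) {
    msg <- c(msg, "peripheral stores must share one radius")
  }
  if (!all(periph$duration_s %in% c(8, 16))) {
    msg <- c(msg, "peripheral durations must be 8 or 16 s")
  }
  for (nm in names(object@cities)) {
    cty <- object@cities[[nm]]
    if (length(cty) != 6L) msg <- c(msg, paste0(nm, ": city must have 6 peripheral stores"))
    if (anyDuplicated(cty)) msg <- c(msg, paste0(nm, ": duplicate store ids in city"))
    if (!all(cty %in% periph$id)) msg <- c(msg, paste0(nm, ": unknown store id"))
    # one store per coordinate slot within a city
    sl <- st$slot[match(cty, st$id)]
    if (anyDuplicated(sl)) msg <- c(msg, paste0(nm, ": two stores on the same slot"))
  }
  if (length(msg)) msg else TRUE
})

#' PatternSet: single-trial activation patterns for one region
#'
#' A trials-by-voxels container of single-trial t-statistic patterns for one
#' ROI or searchlight neighborhood, stored as a
#' \linkS4class{SummarizedExperiment} with voxels as rows and trials as
#' columns.  Trial metadata (city, task, triad stores, correctness,
#' censoring, onsets) lives in \code{colData}; per-voxel temporal
#' signal-to-noise ratio lives in \code{rowData$tsnr}.
#'
#' Use [PatternSet()] to construct one, and [patterns()], [trialData()],
#' [voxelTSNR()], [roiName()] to access the pieces.
#'
#' @export
setClass("PatternSet", contains = "SummarizedExperiment")

setValidity("PatternSet", function(object) {
  msg <- character()
  if (!"tstat" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'tstat' is required")
  } else if (any(!is.finite(assay(object, "tstat")))) {
    msg <- c(msg, "non-finite values in patterns")
  }
  if (!"tsnr" %in% names(rowData(object))) {
    msg <- c(msg, "rowData$tsnr (per-voxel tSNR) is required")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PatternSet
#'
#' @param patterns numeric matrix, trials x voxels, of single-trial
#'   t-statistic values.
#' @param trialData data.frame of trial metadata, one row per trial (the
#'   schedule rows produced by [generateRetrievalSchedule()] or
#'   [generateLocalizerSchedule()]).
#' @param voxelTSNR numeric vector of per-voxel temporal SNR, length
#'   \code{ncol(patterns)}.
#' @param roiName character label for the region.
#' @return A \linkS4class{PatternSet}.
#' @examples
#' env <- buildEnvironment()
#' sched <- generateRetrievalSchedule(env, seed = 1)
#' ps <- PatternSet(matrix(rnorm(nrow(sched) * 20), nrow(sched), 20),
#'                  sched, voxelTSNR = rep(40, 20), roiName = "CA1")
#' ps
#' @export
PatternSet <- function(patterns, trialData, voxelTSNR = NULL,
                       roiName = "ROI") {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) != nrow(trialData)) {
    stop("patterns rows (", nrow(patterns), ") must match trialData rows (",
         nrow(trialData), ")")
  }
  if (is.null(voxelTSNR)) voxelTSNR <- rep(NA_real_, ncol(patterns))
  if (length(voxelTSNR) != ncol(patterns)) {
    stop("voxelTSNR must have one value per voxel")
  }
  se <- SummarizedExperiment(
    assays = list(tstat = t(patterns)),
    colData = DataFrame(trialData),
    rowData = DataFrame(tsnr = as.numeric(voxelTSNR)),
    metadata = list(roi = as.character(roiName))
  )
  new("PatternSet", se)
}

setMethod("show", "PatternSet", function(object) {
  cat("PatternSet '", roiName(object), "': ",
      ncol(object), " trials x ", nrow(object), " voxels\n", sep = "")
  td <- trialData(object)
  if ("city" %in% names(td)) {
    cat("  cities:", paste(sort(unique(td$city)), collapse = ", "))
    if ("task" %in% names(td)) {
      cat("; tasks:", paste(sort(unique(td$task)), collapse = ", "))
    }
    cat("\n")
  }
  if ("correct" %in% names(td)) {
    cat("  usable trials (correct & uncensored):", sum(usableTrials(object)),
        "\n")
  }
})

setMethod("show", "CityEnvironment", function(object) {
  cat("CityEnvironment:", length(object@cities), "cities,",
      nrow(object@stores) - 1L, "peripheral stores + center\n")
  for (nm in names(object@cities)) {
    cat("  ", nm, ": {", paste(sort(object@cities[[nm]]), collapse = ", "),
        "}\n", sep = "")
  }
})
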