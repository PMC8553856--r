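#' Accessors for PatternSet objects
#'
#' \code{patterns} returns the trials-by-voxels matrix, \code{trialData} the
#' trial metadata as a base data.frame, \code{voxelTSNR} the per-voxel
#' temporal SNR, \code{roiName} the region label, and \code{usableTrials} a
#' logical vector marking trials that are both correct and uncensored (the
#' trials every similarity and decoding analysis operates on).
#'
#' @param x a \linkS4class{PatternSet}.
#' @return See individual descriptions above.
#' @name PatternSet-accessors
#' @aliases patterns trialData voxelTSNR roiName usableTrials
NULL

#' @rdname PatternSet-accessors
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))

#' @rdname PatternSet-accessors
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' @rdname PatternSet-accessors
#' @export
setGeneric("voxelTSNR", function(x) standardGeneric("voxelTSNR"))

#' @rdname PatternSet-accessors
#' @export
setGeneric("roiName", function(x) standardGeneric("roiName"))

#' @rdname PatternSet-accessors
#' @export
setGeneric("usableTrials", function(x) standardGeneric("usableTrials"))

#' @rdname PatternSet-accessors
setMethod("patterns", "PatternSet", function(x) t(assay(x, "tstat")))

#' @rdname PatternSet-accessors
setMethod("trialData", "PatternSet", function(x) {
  as.data.frame(colData(x))
})

#' @rdname PatternSet-accessors
setMethod("voxelTSNR", "PatternSet", function(x) rowData(x)$tsnr)

#' @rdname PatternSet-accessors
setMethod("roiName", "PatternSet", function(x) metadata(x)$roi)

#' @rdname PatternSet-accessors
setMethod("usableTrials", "PatternSet", function(x) {
  td <- trialData(x)
  ok <- rep(TRUE, ncol(x))
  if ("correct" %in% names(td)) ok <- ok & td$correct
  if ("censored" %in% names(td)) ok <- ok & !td$censored
  ok
})
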