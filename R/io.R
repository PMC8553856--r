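#' Serialize a PatternSet as portable text files
#'
#' Writes a \linkS4class{PatternSet} as three sidecar files sharing one
#' prefix: \code{<prefix>_patterns.tsv} (trials x voxels matrix),
#' \code{<prefix>_events.tsv} (trial metadata, BIDS-style) and
#' \code{<prefix>_meta.json} (region name and per-voxel tSNR).  The format
#' is plain text so pattern sets travel between tools and into version
#' control without binary artifacts.
#'
#' @param ps a \linkS4class{PatternSet}.
#' @param prefix path prefix for the three files.
#' @return \code{writePatternSet} returns \code{prefix} invisibly;
#'   \code{readPatternSet} returns the reassembled
#'   \linkS4class{PatternSet}.
#' @export
writePatternSet <- function(ps, prefix) {
  utils::write.table(patterns(ps), paste0(prefix, "_patterns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeEventsTsv(trialData(ps), paste0(prefix, "_events.tsv"))
  jsonlite::write_json(
    list(roi = roiName(ps), tsnr = voxelTSNR(ps)),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(prefix)
}

#' @rdname writePatternSet
#' @export
readPatternSet <- function(prefix) {
  pat <- as.matrix(utils::read.table(paste0(prefix, "_patterns.tsv"),
                                     sep = "\t", header = FALSE))
  dimnames(pat) <- NULL
  td <- readEventsTsv(paste0(prefix, "_events.tsv"))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  tsnr <- as.numeric(meta$tsnr)
  PatternSet(pat, td, voxelTSNR = tsnr, roiName = meta$roi)
}
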