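#' Per-sample binned copy-number profile
#'
#' One sample's log2 copy-number ratios over genomic bins or segments.  Bins
#' live in a \code{GRanges} with a numeric \code{log2} metadata column; they
#' must be non-overlapping within a chromosome and all ratios finite.
#'
#' @slot sampleId sample identifier.
#' @slot bins GRanges with mcol \code{log2}.
#' @slot provenance \code{"binned"} or \code{"segmented"}.
#' @export
setClass("CNProfile",
  representation(sampleId = "character", bins = "GRanges", provenance = "character"))

setValidity("CNProfile", function(object) {
  b <- object@bins
  msgs <- character()
  if (is.null(b$log2)) return("bins must carry a 'log2' metadata column")
  if (length(b) && any(!is.finite(b$log2))) msgs <- c(msgs, "log2 ratios must be finite")
  if (length(b)) {
    sp <- split(b, as.character(seqnames(b)))
    ov <- vapply(sp, function(g) {
      g <- sort(g)
      length(g) > 1L && any(start(g)[-1L] <= end(g)[-length(g)])
    }, logical(1))
    if (any(ov)) msgs <- c(msgs, sprintf("overlapping bins on %s",
                                         paste(names(sp)[ov], collapse = ", ")))
  }
  if (!object@provenance %in% c("binned", "segmented")) {
    msgs <- c(msgs, "provenance must be 'binned' or 'segmented'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a copy-number profile
#'
#' @param sampleId sample identifier
#' @param bins GRanges with a numeric \code{log2} mcol
#' @param provenance \code{"binned"} (tiled bins) or \code{"segmented"} (SEG)
#' @return a \linkS4class{CNProfile}
#' @export
CNProfile <- function(sampleId, bins, provenance = "binned") {
  new("CNProfile", sampleId = as.character(sampleId), bins = sort(bins),
      provenance = provenance)
}

#' @export
setMethod("show", "CNProfile", function(object) {
  cat(sprintf("CNProfile '%s' (%s): %d bins on %d chromosomes, median log2 %.3f\n",
    object@sampleId, object@provenance, length(object@bins),
    length(unique(as.character(seqnames(object@bins)))),
    if (length(object@bins)) stats::median(object@bins$log2) else NA_real_))
})

#' Sample identifier of a profile
#' @param x a CNProfile
#' @export
sampleId <- function(x) x@sampleId

#' Bins of a profile
#' @param x a CNProfile
#' @return GRanges with mcol \code{log2}
#' @export
profileBins <- function(x) x@bins

#' Extract one sample of a profile matrix as a CNProfile
#'
#' @param se RangedSummarizedExperiment with assay \code{log2} (bins x samples)
#' @param j column index or sample name
#' @return a \linkS4class{CNProfile}
#' @export
profileFromSE <- function(se, j) {
  b <- SummarizedExperiment::rowRanges(se)
  b$log2 <- as.numeric(SummarizedExperiment::assay(se, "log2")[, j])
  CNProfile(colnames(se)[if (is.character(j)) match(j, colnames(se)) else j], b)
}
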