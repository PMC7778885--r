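#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @export
setGeneric("binsize", function(x) standardGeneric("binsize"))

#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @export
setGeneric("entries", function(x) standardGeneric("entries"))

#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @export
setGeneric("contactCounts", function(x, ...) standardGeneric("contactCounts"))

#' @export
setGeneric("contactValues", function(x, ...) standardGeneric("contactValues"))

#' @export
setGeneric("denseCounts", function(x, ...) standardGeneric("denseCounts"))

#' @export
setGeneric("materialize", function(x, binmaps, ...) standardGeneric("materialize"))

#' @export
setGeneric("applyEdit", function(x, edit, ...) standardGeneric("applyEdit"))

#' @export
setGeneric("renderHeatmap", function(x, file, ...) standardGeneric("renderHeatmap"))

#' @export
setGeneric("smoothnessScore", function(x) standardGeneric("smoothnessScore"))
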