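#' @rdname PangenomeGraph-class
#' @param object,x a \linkS4class{PangenomeGraph} (or, where documented,
#'   another panconserve object)
#' @export
setGeneric("gfaSegments", function(object) standardGeneric("gfaSegments"))

#' @rdname PangenomeGraph-class
#' @export
setGeneric("haplotypePaths", function(object) standardGeneric("haplotypePaths"))

#' @rdname PangenomeGraph-class
#' @export
setGeneric("pathNames", function(object) standardGeneric("pathNames"))

#' @rdname PangenomeGraph-class
#' @export
setGeneric("nPaths", function(object) standardGeneric("nPaths"))

#' @rdname PangenomeGraph-class
#' @export
setGeneric("referenceName", function(object) standardGeneric("referenceName"))

#' @rdname PangenomeGraph-class
#' @param value replacement value
#' @export
setGeneric("referenceName<-",
  function(object, value) standardGeneric("referenceName<-"))

#' @rdname PangenomeGraph-class
#' @export
setGeneric("segmentLengths", function(object) standardGeneric("segmentLengths"))

#' @rdname PangenomeGraph-class
#' @export
setGeneric("referenceLength", function(object) standardGeneric("referenceLength"))

#' @rdname PangenomeBins-class
#' @param object a \linkS4class{PangenomeBins}
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @rdname PangenomeBins-class
#' @export
setGeneric("binRanges", function(object) standardGeneric("binRanges"))

#' @rdname PangenomeBins-class
#' @export
setGeneric("binSubpaths", function(object) standardGeneric("binSubpaths"))
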