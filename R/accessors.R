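#' @rdname PangenomeGraph-class
#' @aliases gfaSegments,PangenomeGraph-method
setMethod("gfaSegments", "PangenomeGraph", function(object) object@segments)

#' @rdname PangenomeGraph-class
#' @aliases haplotypePaths,PangenomeGraph-method
setMethod("haplotypePaths", "PangenomeGraph", function(object) object@paths)

#' @rdname PangenomeGraph-class
#' @aliases pathNames,PangenomeGraph-method
setMethod("pathNames", "PangenomeGraph", function(object) names(object@paths))

#' @rdname PangenomeGraph-class
#' @aliases nPaths,PangenomeGraph-method
setMethod("nPaths", "PangenomeGraph", function(object) length(object@paths))

#' @rdname PangenomeGraph-class
#' @aliases referenceName,PangenomeGraph-method
setMethod("referenceName", "PangenomeGraph",
  function(object) object@referenceName)

#' @rdname PangenomeGraph-class
#' @aliases referenceName<-,PangenomeGraph-method
setReplaceMethod("referenceName", "PangenomeGraph", function(object, value) {
  object@referenceName <- value
  validObject(object)
  object
})

#' @rdname PangenomeGraph-class
#' @aliases segmentLengths,PangenomeGraph-method
setMethod("segmentLengths", "PangenomeGraph", function(object) {
  setNames(object@segments$length, object@segments$id)
})

#' @rdname PangenomeGraph-class
#' @aliases referenceLength,PangenomeGraph-method
setMethod("referenceLength", "PangenomeGraph", function(object) {
  p <- object@paths[[object@referenceName]]
  sum(segmentLengths(object)[p$ids])
})

setMethod("show", "PangenomeGraph", function(object) {
  cat(sprintf(
    "PangenomeGraph: %d segments, %d paths (reference: %s, %d bp)\n",
    nrow(object@segments), nPaths(object), object@referenceName,
    referenceLength(object)
  ))
  cat("  paths:", paste(utils::head(pathNames(object), 6L), collapse = ", "),
      if (nPaths(object) > 6L) "..." else "", "\n")
})

#' @rdname BoundarySet-class
#' @aliases length,BoundarySet-method
#' @param x a \linkS4class{BoundarySet}
#' @export
setMethod("length", "BoundarySet", function(x) length(x@segId))

#' @rdname BoundarySet-class
#' @aliases [,BoundarySet-method
#' @param i index
#' @param j,...,drop ignored
setMethod("[", "BoundarySet", function(x, i, j, ..., drop = FALSE) {
  new("BoundarySet",
    segId = x@segId[i],
    refStart = x@refStart[i],
    refEnd = x@refEnd[i],
    stepIndex = x@stepIndex[, i, drop = FALSE]
  )
})

#' Boundary table
#'
#' Returns the boundary segments of a [BoundarySet] as a data.frame with
#' columns \code{segId}, \code{refStart}, \code{refEnd} (0-based half-open).
#'
#' @param object a \linkS4class{BoundarySet}
#' @return a data.frame, one row per boundary, in reference order
#' @export
boundaryTable <- function(object) {
  stopifnot(is(object, "BoundarySet"))
  data.frame(
    segId = object@segId,
    refStart = object@refStart,
    refEnd = object@refEnd,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "BoundarySet", function(object) {
  cat(sprintf("BoundarySet: %d boundary segment(s), %d path(s)\n",
              length(object), nrow(object@stepIndex)))
})

#' @rdname PangenomeBins-class
#' @aliases nBins,PangenomeBins-method
setMethod("nBins", "PangenomeBins", function(object) length(object@start))

#' @rdname PangenomeBins-class
#' @aliases binRanges,PangenomeBins-method
#' @return \code{binRanges} returns a data.frame with 0-based half-open bin
#'   intervals and the delimiting boundary segment ids (\code{NA} at the
#'   path-start/path-end sentinels).
setMethod("binRanges", "PangenomeBins", function(object) {
  data.frame(
    bin = seq_along(object@start) - 1L,
    refStart = object@start,
    refEnd = object@end,
    leftBoundary = object@leftBoundary,
    rightBoundary = object@rightBoundary,
    stringsAsFactors = FALSE
  )
})

#' @rdname PangenomeBins-class
#' @aliases binSubpaths,PangenomeBins-method
setMethod("binSubpaths", "PangenomeBins", function(object) object@subpaths)

setMethod("show", "PangenomeBins", function(object) {
  cat(sprintf(
    "PangenomeBins: %d bins tiling %s [0, %d), %d boundaries\n",
    nBins(object), object@referenceName, object@referenceLength,
    length(object@boundaries)
  ))
})

setMethod("show", "ConservationMixture", function(object) {
  cat("ConservationMixture (Gaussian bulk + log-normal tail)\n")
  cat(sprintf("  Gaussian:   mu = %.6g, sigma = %.6g (weight %.3g)\n",
              object@mu, object@sigma, object@weight))
  if (object@tailFree) {
    cat("  tail-free model: no positive tail; divergence calls disabled\n")
  } else {
    cat(sprintf("  log-normal: muLog = %.6g, sigmaLog = %.6g (weight %.3g)\n",
                object@muLog, object@sigmaLog, 1 - object@weight))
  }
  cat(sprintf("  fitted on %d scores%s\n", object@nScores,
              if (object@degenerate) " (degenerate: all scores equal)" else ""))
})
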