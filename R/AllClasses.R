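#' @import methods
#' @importFrom stats median mad sd quantile dnorm pnorm qnorm dlnorm plnorm
#'   rnorm rlnorm runif p.adjust setNames
#' @importFrom utils packageVersion head combn
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
NULL

#' PangenomeGraph: a single-chromosome pangenome variation graph
#'
#' Holds the segment table (one row per GFA S-line) and the haplotype paths
#' (GFA P-lines or W-line walks) of a variation graph restricted to one
#' chromosome. Segments are sequence chunks present in at least one
#' haplotype; each path is an ordered, oriented list of segments describing
#' one haplotype's traversal of the chromosome.
#'
#' @slot segments data.frame with columns \code{id}, \code{length},
#'   \code{sequence} (\code{NA} when the GFA carried only an \code{LN} tag);
#'   row names are segment ids.
#' @slot paths named list; each element is a list with character vectors
#'   \code{ids} and \code{strands} (\code{"+"}/\code{"-"}) of equal length.
#' @slot referenceName name of the path used as coordinate backbone.
#' @slot links data.frame of L-line endpoints (kept for optional validation
#'   only; the method itself never uses links).
#'
#' @seealso [readGFA()], [writeGFA()], [referencePositions()]
#' @export
setClass("PangenomeGraph",
  slots = c(
    segments = "data.frame",
    paths = "list",
    referenceName = "character",
    links = "data.frame"
  )
)

setValidity("PangenomeGraph", function(object) {
  seg <- object@segments
  msgs <- character()
  if (!all(c("id", "length", "sequence") %in% names(seg))) {
    return("segments must have columns id, length, sequence")
  }
  if (anyDuplicated(seg$id)) {
    msgs <- c(msgs, sprintf(
      "duplicate segment id(s): %s",
      paste(unique(seg$id[duplicated(seg$id)]), collapse = ", ")
    ))
  }
  if (any(seg$length < 0)) msgs <- c(msgs, "segment lengths must be >= 0")
  hasSeq <- !is.na(seg$sequence)
  bad <- hasSeq & nchar(seg$sequence) != seg$length
  if (any(bad)) {
    msgs <- c(msgs, sprintf(
      "segment %s: sequence length disagrees with declared length",
      seg$id[which(bad)[1L]]
    ))
  }
  if (length(object@paths) < 2L) {
    msgs <- c(msgs, "not a pangenome: fewer than 2 haplotype paths")
  }
  if (is.null(names(object@paths)) || anyDuplicated(names(object@paths))) {
    msgs <- c(msgs, "paths must be uniquely named")
  }
  if (!(object@referenceName %in% names(object@paths))) {
    msgs <- c(msgs, sprintf(
      "reference path '%s' not among path names", object@referenceName
    ))
  }
  lens <- setNames(seg$length, seg$id)
  for (nm in names(object@paths)) {
    p <- object@paths[[nm]]
    if (length(p$ids) == 0L) {
      msgs <- c(msgs, sprintf("path '%s' is empty", nm))
      next
    }
    unknown <- setdiff(p$ids, seg$id)
    if (length(unknown)) {
      msgs <- c(msgs, sprintf(
        "path '%s' references missing segment(s): %s",
        nm, paste(utils::head(unknown, 3L), collapse = ", ")
      ))
      next
    }
    if (length(p$ids) != length(p$strands) ||
        !all(p$strands %in% c("+", "-"))) {
      msgs <- c(msgs, sprintf("path '%s': malformed strands", nm))
    }
    if (sum(lens[p$ids]) <= 0) {
      msgs <- c(msgs, sprintf("path '%s' has zero total length", nm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' BoundarySet: anchor segments shared by every haplotype
#'
#' An ordered collection of boundary segments: segments traversed exactly
#' once by every path of the graph (orientation consistent with each path's
#' dominant orientation), annotated with their reference-coordinate interval
#' and, for each path, the step index of their unique occurrence.
#'
#' @slot segId character vector of segment ids, in reference order.
#' @slot refStart,refEnd 0-based half-open reference intervals.
#' @slot stepIndex integer matrix, paths x boundaries: 1-based step index of
#'   each boundary in each path.
#'
#' @seealso [findBoundaryCandidates()], [selectBoundaries()]
#' @export
setClass("BoundarySet",
  slots = c(
    segId = "character",
    refStart = "numeric",
    refEnd = "numeric",
    stepIndex = "matrix"
  )
)

setValidity("BoundarySet", function(object) {
  n <- length(object@segId)
  if (length(object@refStart) != n || length(object@refEnd) != n) {
    return("segId, refStart, refEnd must have equal length")
  }
  if (n > 0L && ncol(object@stepIndex) != n) {
    return("stepIndex must have one column per boundary")
  }
  if (n > 1L && any(diff(object@refStart) <= 0)) {
    return("boundaries must be strictly increasing in reference coordinates")
  }
  TRUE
})

#' PangenomeBins: windows of the reference delimited by boundary segments
#'
#' The reference path is cut at the midpoints of the selected boundary
#' segments, producing bins that tile \code{[0, referenceLength)} exactly.
#' Each bin stores, per haplotype, the sub-path strictly between its two
#' delimiting boundary occurrences (boundary segments themselves excluded;
#' sub-paths traversed in reverse are flipped to forward orientation).
#'
#' @slot referenceName reference path name (used as the chrom field of
#'   BED/bedGraph output).
#' @slot referenceLength total reference path length in bases.
#' @slot start,end 0-based half-open bin intervals, tiling the reference.
#' @slot leftBoundary,rightBoundary segment id of the delimiting boundary, or
#'   \code{NA} at the path-start/path-end sentinel.
#' @slot subpaths list (one element per bin) of named lists (one per path),
#'   each a list with \code{ids} and \code{strands}.
#' @slot boundaries the [BoundarySet] the bins were built from.
#'
#' @seealso [buildBins()], [scoreBins()]
#' @export
setClass("PangenomeBins",
  slots = c(
    referenceName = "character",
    referenceLength = "numeric",
    start = "numeric",
    end = "numeric",
    leftBoundary = "character",
    rightBoundary = "character",
    subpaths = "list",
    boundaries = "BoundarySet"
  )
)

setValidity("PangenomeBins", function(object) {
  n <- length(object@start)
  if (length(object@end) != n || length(object@subpaths) != n) {
    return("start, end, subpaths must have equal length")
  }
  if (n == 0L) return("at least one bin is required")
  if (any(object@end <= object@start)) return("bins must have end > start")
  if (object@start[1L] != 0) return("first bin must start at 0")
  if (object@end[n] != object@referenceLength) {
    return("last bin must end at the reference length")
  }
  if (n > 1L && any(object@start[-1L] != object@end[-n])) {
    return("bins must tile the reference without gaps or overlaps")
  }
  TRUE
})

#' ConservationMixture: Gaussian + log-normal model of the score distribution
#'
#' Two-component null model for the per-bin scores x = -log(mean Jaccard):
#' the conserved bulk is Gaussian(mu, sigma) and the divergent heavy right
#' tail is log-normal(muLog, sigmaLog); the mixture weight of the Gaussian
#' component is \code{weight}. Tail probabilities under the mixture CDF give
#' per-bin conservation/divergence p-values.
#'
#' @slot mu,sigma Gaussian location and scale of the conserved score bulk.
#' @slot muLog,sigmaLog log-normal parameters (mean and sd of log score) of
#'   the divergent tail; \code{NA} for a tail-free model.
#' @slot weight mixing weight of the Gaussian component (0.5 by default; 1
#'   when tail-free).
#' @slot epsilon the Jaccard floor used when scores were computed (recorded
#'   for the model dump; \code{NA} if unknown).
#' @slot nScores number of scores the model was fitted to.
#' @slot tailFree TRUE when no log-normal tail could be fitted; divergence
#'   calls are then disabled.
#' @slot degenerate TRUE when the score distribution was degenerate (all
#'   scores equal) and sigma is a machine-epsilon-scaled fallback.
#'
#' @seealso [fitConservationMixture()], [mixtureCDF()], [classifyBins()]
#' @export
setClass("ConservationMixture",
  slots = c(
    mu = "numeric",
    sigma = "numeric",
    muLog = "numeric",
    sigmaLog = "numeric",
    weight = "numeric",
    epsilon = "numeric",
    nScores = "numeric",
    tailFree = "logical",
    degenerate = "logical"
  )
)

setValidity("ConservationMixture", function(object) {
  if (object@sigma <= 0) return("sigma must be > 0")
  if (!object@tailFree && (is.na(object@sigmaLog) || object@sigmaLog <= 0)) {
    return("sigmaLog must be > 0 unless the model is tail-free")
  }
  if (object@weight < 0 || object@weight > 1) {
    return("weight must lie in [0, 1]")
  }
  if (object@tailFree && object@weight != 1) {
    return("a tail-free model must have weight 1")
  }
  TRUE
})
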