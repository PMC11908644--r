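## Boundary-segment detection and window construction.
##
## A boundary segment is an anchor traversed exactly once by every haplotype
## path (orientation consistent with each path's dominant orientation).
## Selected boundaries spaced >= s apart on the reference cut the chromosome
## into bins; each haplotype's sub-path strictly between its two boundary
## occurrences is stored per bin.

#' Find boundary-segment candidates
#'
#' Returns, in reference-coordinate order, every segment that is traversed
#' exactly once by every path of the graph (including the reference).
#' Segments absent from any path or traversed more than once by any path are
#' excluded. A candidate whose orientation varies across paths is kept only
#' when each path's flip relative to the reference matches that path's
#' dominant orientation (the majority flip over all single-copy shared
#' segments); this drops spurious anchors inside local inversions while
#' accepting globally reverse-complemented haplotypes.
#'
#' @param graph a \linkS4class{PangenomeGraph}.
#' @param strictForward if TRUE, only segments traversed forward by every
#'   path qualify.
#' @return a \linkS4class{BoundarySet} (possibly of length 0; downstream
#'   degrades to a single whole-chromosome bin).
#' @export
findBoundaryCandidates <- function(graph, strictForward = FALSE) {
  stopifnot(is(graph, "PangenomeGraph"))
  pn <- pathNames(graph)

  ## ids single-copy in every path
  perPath <- lapply(graph@paths, function(p) {
    cnt <- table(p$ids)
    names(cnt)[cnt == 1L]
  })
  cand <- Reduce(intersect, perPath)
  emptySet <- function() new("BoundarySet",
    segId = character(), refStart = numeric(), refEnd = numeric(),
    stepIndex = matrix(integer(), nrow = length(pn), ncol = 0L,
                       dimnames = list(pn, NULL))
  )
  if (!length(cand)) return(emptySet())

  ## step index and strand of each candidate in each path
  idx <- matrix(NA_integer_, nrow = length(pn), ncol = length(cand),
                dimnames = list(pn, cand))
  str <- matrix(NA_character_, nrow = length(pn), ncol = length(cand),
                dimnames = list(pn, cand))
  for (nm in pn) {
    p <- graph@paths[[nm]]
    pos <- match(cand, p$ids)
    idx[nm, ] <- pos
    str[nm, ] <- p$strands[pos]
  }

  refStr <- str[graph@referenceName, ]
  if (strictForward) {
    keep <- colSums(str != "+") == 0L
  } else {
    flip <- sweep(str, 2L, refStr, FUN = "!=")  # path x cand: flipped vs ref?
    dominant <- rowMeans(flip) > 0.5            # per-path dominant flip
    keep <- colSums(flip != dominant) == 0L
  }
  cand <- cand[keep]
  if (!length(cand)) return(emptySet())
  idx <- idx[, keep, drop = FALSE]

  rp <- referencePositions(graph)
  pos <- match(cand, rp$segId)  # single-copy on reference: unique match
  ord <- order(rp$start[pos])
  new("BoundarySet",
    segId = cand[ord],
    refStart = rp$start[pos][ord],
    refEnd = rp$end[pos][ord],
    stepIndex = idx[, ord, drop = FALSE]
  )
}

#' Greedily select boundaries spaced by the window size
#'
#' Left-to-right greedy selection: the first candidate is always selected;
#' thereafter the first candidate whose reference start is at least
#' \code{windowSize} bases past the end of the previously selected boundary
#' is taken. Consecutive selected boundaries are therefore >= windowSize
#' apart (gap measured end-to-start) and strictly increasing.
#'
#' @param candidates a \linkS4class{BoundarySet} in reference order, from
#'   [findBoundaryCandidates()].
#' @param windowSize target bin size s in bases (>= 1).
#' @return a \linkS4class{BoundarySet} with the selected subset.
#' @export
selectBoundaries <- function(candidates, windowSize) {
  stopifnot(is(candidates, "BoundarySet"))
  if (windowSize < 1) stop("windowSize must be >= 1")
  n <- length(candidates)
  if (n == 0L) return(candidates)
  keep <- logical(n)
  keep[1L] <- TRUE
  lastEnd <- candidates@refEnd[1L]
  for (i in seq_len(n)[-1L]) {
    if (candidates@refStart[i] >= lastEnd + windowSize) {
      keep[i] <- TRUE
      lastEnd <- candidates@refEnd[i]
    }
  }
  candidates[which(keep)]
}

## steps (il, ir) exclusive, flipped when traversed right-to-left
.extractBetween <- function(p, il, ir) {
  if (il <= ir) {
    sel <- if (ir - il >= 2L) (il + 1L):(ir - 1L) else integer()
    list(ids = p$ids[sel], strands = p$strands[sel])
  } else {
    sel <- if (il - ir >= 2L) (ir + 1L):(il - 1L) else integer()
    list(ids = rev(p$ids[sel]),
         strands = unname(rev(c(`+` = "-", `-` = "+")[p$strands[sel]])))
  }
}

#' Build bins between consecutive boundary segments
#'
#' Cuts the reference at the midpoint of each selected boundary segment,
#' producing intervals that tile \code{[0, referenceLength)} exactly: a
#' leading bin from the reference start to the first boundary's midpoint,
#' one bin per consecutive boundary pair, and a trailing bin to the
#' reference end. Each bin stores, per path, the sub-path strictly between
#' that path's occurrences of the two delimiting boundaries (boundary
#' segments excluded - being shared by construction, they would only dilute
#' the similarity signal). When a path traverses a region in reverse (its
#' occurrence of the right boundary precedes the left one), the extracted
#' steps are reversed with orientations flipped before storage. With no
#' boundary at all the whole chromosome becomes a single bin and a warning
#' is emitted.
#'
#' @param graph a \linkS4class{PangenomeGraph}.
#' @param boundaries a \linkS4class{BoundarySet} of selected boundaries.
#' @return a \linkS4class{PangenomeBins}.
#' @export
buildBins <- function(graph, boundaries) {
  stopifnot(is(graph, "PangenomeGraph"), is(boundaries, "BoundarySet"))
  pn <- pathNames(graph)
  refLen <- referenceLength(graph)
  k <- length(boundaries)

  if (k == 0L) {
    warning("no boundary segment found; the whole chromosome is one bin")
    sub <- lapply(setNames(pn, pn), function(nm) graph@paths[[nm]])
    return(new("PangenomeBins",
      referenceName = graph@referenceName, referenceLength = refLen,
      start = 0, end = refLen,
      leftBoundary = NA_character_, rightBoundary = NA_character_,
      subpaths = list(sub), boundaries = boundaries
    ))
  }

  mids <- floor((boundaries@refStart + boundaries@refEnd) / 2)
  cuts <- c(0, mids, refLen)
  ## bin j (1..k+1) spans [cuts[j], cuts[j+1]); left boundary j-1, right j
  binStart <- cuts[-length(cuts)]
  binEnd <- cuts[-1L]
  leftB <- c(NA_character_, boundaries@segId)
  rightB <- c(boundaries@segId, NA_character_)

  ## per-path global flip: decided by the order of boundary occurrences
  flipped <- setNames(rep(FALSE, length(pn)), pn)
  if (k >= 2L) {
    for (nm in pn) {
      d <- diff(boundaries@stepIndex[nm, ])
      if (all(d < 0)) flipped[nm] <- TRUE
      else if (!all(d > 0)) {
        panconserveError(sprintf(
          "path '%s': boundary occurrences are not collinear with the reference",
          nm
        ), "binningError")
      }
    }
  }

  subpaths <- vector("list", k + 1L)
  for (j in seq_len(k + 1L)) {
    sub <- vector("list", length(pn))
    names(sub) <- pn
    for (nm in pn) {
      p <- graph@paths[[nm]]
      n <- length(p$ids)
      ix <- boundaries@stepIndex[nm, ]
      if (any(is.na(ix))) {
        panconserveError(sprintf(
          "path '%s' lacks a boundary occurrence: corrupted boundary set", nm
        ), "binningError")
      }
      sub[[nm]] <- if (j == 1L) {           # leading flank
        if (flipped[nm]) .extractBetween(p, n + 1L, ix[1L])
        else .extractBetween(p, 0L, ix[1L])
      } else if (j == k + 1L) {             # trailing flank
        if (flipped[nm]) .extractBetween(p, ix[k], 0L)
        else .extractBetween(p, ix[k], n + 1L)
      } else {
        .extractBetween(p, ix[j - 1L], ix[j])
      }
    }
    subpaths[[j]] <- sub
  }

  ## drop zero-width flank bins (boundary midpoint falling on 0 or refLen)
  keep <- binEnd > binStart
  new("PangenomeBins",
    referenceName = graph@referenceName, referenceLength = refLen,
    start = binStart[keep], end = binEnd[keep],
    leftBoundary = leftB[keep], rightBoundary = rightB[keep],
    subpaths = subpaths[keep], boundaries = boundaries
  )
}
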