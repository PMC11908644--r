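## Length-weighted Jaccard similarity between haplotype sub-paths.
##
## A sub-path is reduced to a multiset of segment traversal counts
## (orientation ignored: an inverted traversal still carries the same
## sequence content). The weighted Jaccard index of two multisets is
##   J(A, B) = sum_g min(cA(g), cB(g)) * len(g) /
##             sum_g max(cA(g), cB(g)) * len(g),
## the length-weighted multiset intersection over union. J = 1 for identical
## multisets (including two empty ones: a deletion shared by two haplotypes
## is an identical null sequence), J = 0 for disjoint non-empty ones.

#' Segment multiset of a sub-path
#'
#' Counts the traversals of each segment in a sub-path, ignoring
#' orientation.
#'
#' @param subpath a list with character vectors \code{ids} and
#'   \code{strands} (as stored in [binSubpaths()]), or a plain character
#'   vector of segment ids.
#' @return a named integer vector of traversal counts (no zero entries;
#'   empty for an empty sub-path).
#' @export
segmentMultiset <- function(subpath) {
  ids <- if (is.list(subpath)) subpath$ids else subpath
  if (!length(ids)) return(setNames(integer(), character()))
  tab <- table(ids)
  setNames(as.integer(tab), names(tab))
}

#' Total length-weight of a segment multiset
#'
#' @param counts a named integer vector of traversal counts.
#' @param lengths named numeric vector of segment lengths (from
#'   [segmentLengths()]).
#' @return sum over segments of count x length.
#' @export
multisetWeight <- function(counts, lengths) {
  if (!length(counts)) return(0)
  sum(counts * lengths[names(counts)])
}

#' Weighted Jaccard index of two segment multisets
#'
#' @param a,b named integer vectors of traversal counts (see
#'   [segmentMultiset()]).
#' @param lengths named numeric vector of segment lengths.
#' @return the length-weighted Jaccard index in \code{[0, 1]}; 1 when both
#'   multisets are empty.
#' @examples
#' lens <- c(s1 = 10, s2 = 5, s3 = 5)
#' weightedJaccard(c(s1 = 1L, s2 = 1L), c(s1 = 1L, s3 = 1L), lens)  # 0.5
#' @export
weightedJaccard <- function(a, b, lengths) {
  u <- union(names(a), names(b))
  if (!length(u)) return(1)
  ca <- rep(0L, length(u)); names(ca) <- u; ca[names(a)] <- a
  cb <- rep(0L, length(u)); names(cb) <- u; cb[names(b)] <- b
  w <- lengths[u]
  den <- sum(pmax(ca, cb) * w)
  if (den == 0) return(1)
  sum(pmin(ca, cb) * w) / den
}

## multisets + pairwise mean J + union weight for one bin's subpaths
.binSimilarity <- function(sub, lengths) {
  ms <- lapply(sub, segmentMultiset)
  P <- length(ms)
  pairs <- utils::combn(P, 2L)
  js <- apply(pairs, 2L, function(pr) {
    weightedJaccard(ms[[pr[1L]]], ms[[pr[2L]]], lengths)
  })
  allIds <- unique(unlist(lapply(ms, names), use.names = FALSE))
  unionW <- if (!length(allIds)) 0 else {
    mx <- rep(0L, length(allIds)); names(mx) <- allIds
    for (m in ms) mx[names(m)] <- pmax(mx[names(m)], m)
    sum(mx * lengths[allIds])
  }
  list(meanJ = mean(js), nPairs = ncol(pairs), unionWeight = unionW)
}

#' Mean pairwise weighted Jaccard of one bin
#'
#' Arithmetic mean of the weighted Jaccard index over all P(P-1)/2 unordered
#' pairs of haplotype sub-paths in a bin.
#'
#' @param subpaths named list of sub-paths (one per path), as stored per bin
#'   in a \linkS4class{PangenomeBins}.
#' @param lengths named numeric vector of segment lengths.
#' @return a list with \code{meanJ}, \code{nPairs} and \code{unionWeight}
#'   (length-weight of the across-path union multiset, used to set the
#'   Jaccard floor).
#' @export
binMeanJaccard <- function(subpaths, lengths) {
  stopifnot(length(subpaths) >= 2L)
  .binSimilarity(subpaths, lengths)
}

#' Score all bins of a graph
#'
#' Computes, for every bin, the mean pairwise weighted Jaccard J and the
#' conservation score x = -ln(max(J, epsilon)). The floor epsilon maps the
#' rare exact-zero Jaccard (fully disjoint sub-paths) to a finite maximal
#' score; by default epsilon = 1 / (1 + max bin union weight), i.e. just
#' below the smallest non-zero Jaccard any bin could attain.
#'
#' @param bins a \linkS4class{PangenomeBins}.
#' @param graph the \linkS4class{PangenomeGraph} the bins were built from.
#' @param jaccardFloor optional explicit epsilon in (0, 1).
#' @return a data.frame with one row per bin: \code{bin} (0-based index),
#'   \code{refStart}, \code{refEnd} (0-based half-open), \code{nPairs},
#'   \code{meanJaccard}, \code{score}; the floor is attached as attribute
#'   \code{"epsilon"}.
#' @export
scoreBins <- function(bins, graph, jaccardFloor = NULL) {
  stopifnot(is(bins, "PangenomeBins"), is(graph, "PangenomeGraph"))
  lengths <- segmentLengths(graph)
  sims <- lapply(bins@subpaths, .binSimilarity, lengths = lengths)
  meanJ <- vapply(sims, `[[`, numeric(1L), "meanJ")
  unionW <- vapply(sims, `[[`, numeric(1L), "unionWeight")
  eps <- if (is.null(jaccardFloor)) 1 / (1 + max(unionW, 1)) else jaccardFloor
  stopifnot(eps > 0, eps < 1)
  out <- data.frame(
    bin = seq_along(meanJ) - 1L,
    refStart = bins@start,
    refEnd = bins@end,
    nPairs = vapply(sims, `[[`, numeric(1L), "nPairs"),
    meanJaccard = meanJ,
    score = -log(pmax(meanJ, eps))
  )
  attr(out, "epsilon") <- eps
  out
}
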