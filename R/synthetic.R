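## Seeded generator of single-chromosome pangenome graphs with known
## per-region divergence, for validation of every pipeline stage.
##
## The graph is a backbone of universal anchor segments interleaved with
## bubble regions: anchor_0, R_1, anchor_1, ..., R_n, anchor_n. Every
## haplotype traverses every anchor forward exactly once, so anchors are
## boundary candidates by construction. Each region is split into
## fixed-length chunks; a haplotype keeps each reference chunk independently
## with probability 1 - d and otherwise receives a private segment of the
## same length, so d is the expected fraction of region sequence private to
## that haplotype. Optionally a haplotype's whole region allele is dropped
## (deletion) or traversed twice (duplication) with probability
## svProbability; the first haplotype (the reference) is exempt from SV
## events so ground-truth reference intervals stay exact, but it does
## receive chunk substitutions like any other haplotype.

.randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a pangenome graph with known per-region divergence
#'
#' @param nHaplotypes number of haplotype paths (>= 2); the first one is the
#'   reference. Default 4.
#' @param nRegions number of bubble regions between anchors. Default 20.
#' @param anchorLength anchor segment length in bases (>= 1). Default 50.
#' @param regionLength region length in bases. Default 200.
#' @param divergence vector of length \code{nRegions} in \code{[0, 1]}: the
#'   expected fraction of each region's sequence that is private to each
#'   haplotype. Default: linearly spaced from 0 to 0.9.
#' @param svProbability per-haplotype, per-region probability of a
#'   segment-level structural variant: the allele is deleted or duplicated
#'   (equal odds). Default 0.05.
#' @param chunkLength granularity at which divergence is injected (a region
#'   of L bases is realized as ceiling(L / chunkLength) segments). Default 20.
#' @param seed integer seed driving all randomness; identical parameters and
#'   seed yield an identical graph.
#' @return a list with \code{graph} (a \linkS4class{PangenomeGraph}, paths
#'   named \code{h<i>#1#chr1} so both P- and W-line output are possible) and
#'   \code{truth}, a data.frame with one row per region: \code{region}
#'   (0-based index), \code{refStart}, \code{refEnd} (0-based half-open
#'   reference interval), \code{divergence}.
#' @examples
#' sim <- simulatePangenome(nRegions = 3, divergence = c(0, 0.5, 1), seed = 1)
#' sim$truth
#' @export
simulatePangenome <- function(nHaplotypes = 4L, nRegions = 20L,
                              anchorLength = 50L, regionLength = 200L,
                              divergence = seq(0, 0.9,
                                               length.out = nRegions),
                              svProbability = 0.05, chunkLength = 20L,
                              seed = 1L) {
  stopifnot(
    nHaplotypes >= 2L, nRegions >= 1L, anchorLength >= 1L,
    regionLength >= 1L, chunkLength >= 1L,
    length(divergence) == nRegions,
    all(divergence >= 0 & divergence <= 1),
    svProbability >= 0, svProbability <= 1
  )
  set.seed(seed)

  segId <- character()
  segSeq <- character()
  addSeg <- function(id, len) {
    segId <<- c(segId, id)
    segSeq <<- c(segSeq, .randSeq(len))
  }

  ## chunk lengths per region (last chunk absorbs the remainder)
  nChunks <- ceiling(regionLength / chunkLength)
  chunkLens <- rep(chunkLength, nChunks)
  chunkLens[nChunks] <- regionLength - chunkLength * (nChunks - 1L)

  for (a in 0:nRegions) addSeg(sprintf("A%d", a), anchorLength)
  for (r in seq_len(nRegions)) {
    for (j in seq_len(nChunks)) {
      addSeg(sprintf("R%dC%d", r, j), chunkLens[j])
    }
  }

  hapNames <- sprintf("h%d#1#chr1", seq_len(nHaplotypes))
  ## draw per-haplotype region alleles
  alleles <- vector("list", nHaplotypes)
  for (h in seq_len(nHaplotypes)) alleles[[h]] <- vector("list", nRegions)
  for (r in seq_len(nRegions)) {
    for (h in seq_len(nHaplotypes)) {
      priv <- runif(nChunks) < divergence[r]
      ids <- ifelse(priv,
                    sprintf("R%dC%dH%d", r, seq_len(nChunks), h),
                    sprintf("R%dC%d", r, seq_len(nChunks)))
      for (j in which(priv)) addSeg(ids[j], chunkLens[j])
      sv <- if (h > 1L && runif(1L) < svProbability) {
        if (runif(1L) < 0.5) "del" else "dup"
      } else {
        "none"
      }
      alleles[[h]][[r]] <- switch(sv,
        none = ids,
        del = character(),
        dup = c(ids, ids)
      )
    }
  }

  paths <- vector("list", nHaplotypes)
  names(paths) <- hapNames
  for (h in seq_len(nHaplotypes)) {
    ids <- "A0"
    for (r in seq_len(nRegions)) {
      ids <- c(ids, alleles[[h]][[r]], sprintf("A%d", r))
    }
    paths[[h]] <- list(ids = ids, strands = rep("+", length(ids)))
  }

  seg <- data.frame(
    id = segId, length = nchar(segSeq), sequence = segSeq,
    stringsAsFactors = FALSE
  )
  rownames(seg) <- segId
  graph <- new("PangenomeGraph",
    segments = seg, paths = paths, referenceName = hapNames[1L],
    links = data.frame(
      from = character(), fromOrient = character(),
      to = character(), toOrient = character(), stringsAsFactors = FALSE
    )
  )

  starts <- anchorLength + (seq_len(nRegions) - 1L) *
    (anchorLength + regionLength)
  truth <- data.frame(
    region = seq_len(nRegions) - 1L,
    refStart = starts,
    refEnd = starts + regionLength,
    divergence = divergence
  )
  list(graph = graph, truth = truth)
}

#' Expected divergence ranking of synthetic regions
#'
#' Orders the regions of a ground-truth table by decreasing injected
#' divergence, ties broken by region index; used to assert rank agreement
#' with computed bin scores.
#'
#' @param truth the ground-truth data.frame from [simulatePangenome()].
#' @return integer vector of 0-based region indices, most divergent first.
#' @export
expectedBinRanking <- function(truth) {
  stopifnot(is.data.frame(truth),
            all(c("region", "divergence") %in% names(truth)))
  truth$region[order(-truth$divergence, truth$region)]
}

#' Match scored bins to synthetic ground-truth regions
#'
#' For each ground-truth region, finds the bin whose interval covers the
#' region's midpoint (with midpoint-cut bins and anchors at both chromosome
#' ends, exactly one inner bin per region). Convenience for ranking checks.
#'
#' @param scores per-bin score data.frame from [scoreBins()].
#' @param truth ground-truth data.frame from [simulatePangenome()].
#' @return \code{scores} subset to the matched bins, in region order, with a
#'   \code{divergence} column appended.
#' @export
matchBinsToRegions <- function(scores, truth) {
  mid <- (truth$refStart + truth$refEnd) / 2
  idx <- vapply(mid, function(m) {
    which(scores$refStart <= m & scores$refEnd > m)[1L]
  }, integer(1L))
  out <- scores[idx, , drop = FALSE]
  out$divergence <- truth$divergence
  rownames(out) <- NULL
  out
}
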