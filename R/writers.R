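## Plain-text emitters for the pipeline artifacts. All coordinates written
## 0-based half-open (BED/bedGraph convention); numbers formatted with
## sprintf so identical runs produce byte-identical files.

.fmt <- function(x) sprintf("%.6g", x)

#' Write the per-bin score table
#'
#' Tab-separated, one row per bin, with a commented header documenting the
#' score definition and the Jaccard floor.
#'
#' @param classified data.frame from [classifyBins()] (or [scoreBins()];
#'   p-value/class columns are included when present).
#' @param file output path.
#' @param epsilon the Jaccard floor (defaults to the \code{"epsilon"}
#'   attribute of \code{classified}).
#' @return invisibly, \code{file}.
#' @export
writeBinTable <- function(classified, file, epsilon = NULL) {
  if (is.null(epsilon)) epsilon <- attr(classified, "epsilon")
  hasClass <- "class" %in% names(classified)
  hdr <- c(
    "# panconserve per-bin scores; coordinates 0-based half-open",
    sprintf("# score = -ln(max(meanJaccard, epsilon)), epsilon = %s",
            .fmt(if (is.null(epsilon)) NA_real_ else epsilon)),
    paste(c("bin", "ref_start", "ref_end", "n_pairs", "mean_jaccard", "score",
            if (hasClass) c("p_conserved", "p_divergent", "class")),
          collapse = "\t")
  )
  rows <- paste(
    classified$bin, classified$refStart, classified$refEnd,
    classified$nPairs, .fmt(classified$meanJaccard), .fmt(classified$score),
    sep = "\t"
  )
  if (hasClass) {
    rows <- paste(rows, .fmt(classified$pConserved),
                  .fmt(classified$pDivergent),
                  as.character(classified$class), sep = "\t")
  }
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' Write the score track as bedGraph
#'
#' @param scores per-bin score data.frame.
#' @param referenceName chrom column value (the reference path name,
#'   verbatim).
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeBedGraph <- function(scores, referenceName, file) {
  writeLines(c(
    "track type=bedGraph name=\"panconserve score\" description=\"-ln mean pairwise weighted Jaccard\"",
    paste(referenceName, scores$refStart, scores$refEnd, .fmt(scores$score),
          sep = "\t")
  ), file)
  invisible(file)
}

#' Write significant regions as BED5
#'
#' One file per class. Columns: chrom (reference path name), start, end
#' (0-based half-open), name (the class), score = -10*log10(min p) capped at
#' 1000.
#'
#' @param regions GRanges from [mergeRegions()].
#' @param class \code{"conserved"} or \code{"divergent"}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeRegionsBed <- function(regions, class = c("conserved", "divergent"),
                            file) {
  class <- match.arg(class)
  r <- regions[regions$class == class]
  bedScore <- if (length(r)) {
    pmin(1000, round(-10 * log10(pmax(r$minP, 1e-100))))
  } else {
    numeric()
  }
  writeLines(
    if (length(r)) {
      paste(as.character(GenomicRanges::seqnames(r)),
            GenomicRanges::start(r) - 1L,  # back to 0-based
            GenomicRanges::end(r),
            class, bedScore, sep = "\t")
    } else {
      character()
    },
    file
  )
  invisible(file)
}

#' Write the fitted model as key = value text
#'
#' @param model a \linkS4class{ConservationMixture}.
#' @param nBins number of bins the model was fitted on.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeModelDump <- function(model, nBins, file) {
  writeLines(c(
    sprintf("mu = %.10g", model@mu),
    sprintf("sigma = %.10g", model@sigma),
    sprintf("mu_L = %.10g", model@muLog),
    sprintf("sigma_L = %.10g", model@sigmaLog),
    sprintf("pi = %.10g", model@weight),
    sprintf("epsilon = %.10g", model@epsilon),
    sprintf("n_bins = %d", as.integer(nBins))
  ), file)
  invisible(file)
}
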