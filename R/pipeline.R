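## End-to-end orchestration: parse -> bin -> score -> fit -> classify ->
## write. One chromosome per run; bins are independent, so the run is
## single-threaded and fully deterministic for a fixed configuration.

#' Run the full conservation scan on a GFA file
#'
#' Reads a single-chromosome pangenome graph, selects boundary segments
#' spaced by \code{windowSize} along the reference path, scores every bin by
#' mean pairwise weighted Jaccard, fits the Gaussian + log-normal mixture to
#' the -log scores, classifies bins at level \code{alpha} per tail and
#' writes six artifacts: \code{<prefix>.bins.tsv} (per-bin table),
#' \code{<prefix>.score.bedgraph}, \code{<prefix>.conserved.bed},
#' \code{<prefix>.divergent.bed} (BED5), \code{<prefix>.model.txt}
#' (key = value dump) and \code{<prefix>.log} (version, configuration echo,
#' boundary and bin counts). On failure a \code{<prefix>.failed} marker is
#' left next to any partial output.
#'
#' @param input path to a GFA v1 file.
#' @param outputPrefix path prefix for the artifacts.
#' @param referenceName reference path name; default: first path in file
#'   order.
#' @param windowSize window size s in bases (default 10000).
#' @param alpha per-tail significance level (default 0.05).
#' @param jaccardFloor optional explicit Jaccard floor epsilon.
#' @param tailK log-normal tail threshold in Gaussian sd units (default 2).
#' @param estimateWeight re-estimate the mixture weight by EM (default:
#'   fixed 0.5).
#' @param fdr Benjamini-Hochberg correction per tail before thresholding.
#' @param strictForward restrict boundary candidates to all-forward
#'   occurrences.
#' @param validateLinks check path adjacency against GFA L-lines.
#' @param seed RNG seed recorded in the log (the scan itself is
#'   deterministic; the seed matters for downstream resampling utilities).
#' @param verbose print progress messages.
#' @return invisibly, a list with elements \code{graph}, \code{boundaries},
#'   \code{bins}, \code{classified} (per-bin table), \code{model},
#'   \code{regions} (GRanges) and \code{files} (named character vector of
#'   artifact paths).
#' @examples
#' sim <- simulatePangenome(nRegions = 5, seed = 7)
#' gfa <- tempfile(fileext = ".gfa")
#' writeGFA(sim$graph, gfa)
#' res <- runConservationScan(gfa, tempfile(), windowSize = 200)
#' summarizeRegions(res$regions)
#' @export
runConservationScan <- function(input, outputPrefix,
                                referenceName = NULL,
                                windowSize = 10000, alpha = 0.05,
                                jaccardFloor = NULL, tailK = 2,
                                estimateWeight = FALSE, fdr = FALSE,
                                strictForward = FALSE,
                                validateLinks = FALSE,
                                seed = 1L, verbose = FALSE) {
  if (!(is.numeric(windowSize) && length(windowSize) == 1L &&
        windowSize >= 1)) {
    stop("windowSize must be a single number >= 1")
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  say <- function(...) if (verbose) message(sprintf(...))

  files <- c(
    bins = paste0(outputPrefix, ".bins.tsv"),
    bedgraph = paste0(outputPrefix, ".score.bedgraph"),
    conserved = paste0(outputPrefix, ".conserved.bed"),
    divergent = paste0(outputPrefix, ".divergent.bed"),
    model = paste0(outputPrefix, ".model.txt"),
    log = paste0(outputPrefix, ".log")
  )
  failedMarker <- paste0(outputPrefix, ".failed")
  if (file.exists(failedMarker)) file.remove(failedMarker)

  tryCatch({
    say("reading %s", input)
    graph <- readGFA(input, referenceName = referenceName,
                     validateLinks = validateLinks)
    set.seed(seed)

    cand <- findBoundaryCandidates(graph, strictForward = strictForward)
    bounds <- selectBoundaries(cand, windowSize)
    say("%d boundary candidates, %d selected at s = %d",
        length(cand), length(bounds), windowSize)
    bins <- buildBins(graph, bounds)
    say("%d bins", nBins(bins))

    scores <- scoreBins(bins, graph, jaccardFloor = jaccardFloor)
    eps <- attr(scores, "epsilon")
    model <- fitConservationMixture(scores$score, tailK = tailK,
                                    estimateWeight = estimateWeight,
                                    epsilon = eps)
    classified <- classifyBins(scores, model, alpha = alpha, fdr = fdr)
    attr(classified, "epsilon") <- eps
    regions <- mergeRegions(classified, referenceName(graph))

    writeBinTable(classified, files[["bins"]], epsilon = eps)
    writeBedGraph(classified, referenceName(graph), files[["bedgraph"]])
    writeRegionsBed(regions, "conserved", files[["conserved"]])
    writeRegionsBed(regions, "divergent", files[["divergent"]])
    writeModelDump(model, nrow(classified), files[["model"]])
    writeLines(c(
      sprintf("panconserve %s", as.character(packageVersion("panconserve"))),
      sprintf("input = %s", input),
      sprintf("reference = %s", referenceName(graph)),
      sprintf("window_size = %d", as.integer(windowSize)),
      sprintf("alpha = %g", alpha),
      sprintf("tail_k = %g", tailK),
      sprintf("estimate_weight = %s", estimateWeight),
      sprintf("fdr = %s", fdr),
      sprintf("seed = %d", as.integer(seed)),
      sprintf("n_paths = %d", nPaths(graph)),
      sprintf("n_boundary_candidates = %d", length(cand)),
      sprintf("n_boundaries_selected = %d", length(bounds)),
      sprintf("n_bins = %d", nBins(bins)),
      sprintf("epsilon = %.10g", eps)
    ), files[["log"]])

    invisible(list(
      graph = graph, boundaries = bounds, bins = bins,
      classified = classified, model = model, regions = regions,
      files = files
    ))
  }, error = function(e) {
    if (any(file.exists(files))) writeLines(conditionMessage(e), failedMarker)
    stop(e)
  })
}

#' Summarize significant regions
#'
#' Totals the bases and region counts per class. Conserved and divergent
#' regions never overlap (bins tile the reference and each bin has a single
#' class), so no base is double-counted.
#'
#' @param regions GRanges from [mergeRegions()] (or the \code{regions}
#'   element returned by [runConservationScan()]).
#' @param quiet suppress the printed report.
#' @return invisibly, a list with \code{conservedBp}, \code{divergentBp},
#'   \code{conservedRegions}, \code{divergentRegions}.
#' @export
summarizeRegions <- function(regions, quiet = FALSE) {
  stopifnot(is(regions, "GRanges"))
  bp <- function(cl) {
    r <- regions[regions$class == cl]
    if (length(r)) sum(GenomicRanges::width(r)) else 0
  }
  out <- list(
    conservedBp = bp("conserved"),
    divergentBp = bp("divergent"),
    conservedRegions = sum(regions$class == "conserved"),
    divergentRegions = sum(regions$class == "divergent")
  )
  if (!quiet) {
    cat(sprintf("conserved: %d bp in %d region(s)\n",
                out$conservedBp, out$conservedRegions))
    cat(sprintf("divergent: %d bp in %d region(s)\n",
                out$divergentBp, out$divergentRegions))
  }
  invisible(out)
}
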