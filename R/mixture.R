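## Two-component null model of the per-bin score distribution.
##
## Scores x = -log(mean Jaccard) of the conserved bulk cluster in a narrow,
## approximately Gaussian mode near 0, while divergent windows form a heavy
## right tail that a Gaussian cannot accommodate; that tail is modelled as
## log-normal. The full null is the equal-weight average of the two fitted
## densities (the weight can optionally be re-estimated by EM with the
## component parameters held fixed). Tail probabilities under the mixture
## CDF give per-bin p-values: the left tail flags unusually high similarity
## (conserved), the right tail unusually low similarity (divergent).
##
## Fitting is staged and fully deterministic:
##  1. Gaussian bulk: iterative 3-sigma clipping with median/MAD estimates,
##     initialised from left-hand quantiles (Q25 and Q10) so the starting
##     window never includes the divergent tail even under heavy
##     contamination.
##  2. Log-normal tail: log-moment fit on scores above mu + k*sigma,
##     de-contaminated from Gaussian stragglers by responsibility-weighted
##     iterations with the Gaussian component held fixed.

#' Fit the Gaussian bulk of the score distribution
#'
#' Robust location/scale estimate of the dominant low-score mode, insensitive
#' to the divergent right tail: starting from left-quantile initial values
#' (location Q25, scale from the Q10-Q25 spread), observations outside
#' location +/- 3 scale are clipped and median/MAD re-estimated until the
#' retained set is stable (at most 50 iterations).
#'
#' @param scores numeric vector of bin scores; non-finite values are dropped.
#'   Scores of exactly 0 (J = 1) are kept: they are the most conserved
#'   observations, not artifacts.
#' @return a list with \code{mu}, \code{sigma} and logical \code{degenerate}
#'   (TRUE when all scores are equal; \code{sigma} is then a
#'   machine-epsilon-scaled fallback and a warning is emitted). Fewer than 30
#'   scores also triggers a warning.
#' @export
fitGaussianCore <- function(scores) {
  x <- scores[is.finite(scores)]
  if (!length(x)) stop("no finite scores to fit")
  if (length(x) < 30L) {
    warning(sprintf("only %d scores: Gaussian fit will be unstable", length(x)))
  }
  if (diff(range(x)) == 0) {
    warning("degenerate score distribution (all scores equal)")
    return(list(
      mu = x[1L],
      sigma = max(abs(x[1L]), 1) * sqrt(.Machine$double.eps),
      degenerate = TRUE
    ))
  }
  q <- quantile(x, c(0.10, 0.25), names = FALSE, type = 7)
  mu <- q[2L]
  s <- (q[2L] - q[1L]) / (qnorm(0.25) - qnorm(0.10))
  if (s <= 0) s <- mad(x)
  if (s <= 0) s <- sd(x)
  prevKeep <- rep(FALSE, length(x))
  for (it in seq_len(50L)) {
    keep <- x >= mu - 3 * s & x <= mu + 3 * s
    if (identical(keep, prevKeep)) break
    prevKeep <- keep
    xi <- x[keep]
    if (length(xi) < 2L) break
    mu <- median(xi)
    sNew <- mad(xi, center = mu)
    if (sNew > 0) s <- sNew
  }
  list(mu = unname(mu), sigma = unname(s), degenerate = FALSE)
}

#' Fit the log-normal divergent tail
#'
#' Log-moment (maximum-likelihood) fit of a log-normal to the scores above
#' \code{mu + tailK * sigma}. Gaussian observations leaking past the
#' threshold are down-weighted by responsibility iterations (equal prior,
#' Gaussian component fixed) so they do not drag the log-mean down. With
#' fewer than 10 tail points the fit falls back to all positive scores with
#' a warning; with no positive score at all the model is tail-free and
#' divergence calls are disabled.
#'
#' @param scores numeric vector of bin scores.
#' @param gaussian the list returned by [fitGaussianCore()].
#' @param tailK tail threshold in Gaussian standard deviations (default 2).
#' @return a list with \code{muLog}, \code{sigmaLog} (NA when tail-free) and
#'   logical \code{tailFree}.
#' @export
fitLognormalTail <- function(scores, gaussian, tailK = 2) {
  x <- scores[is.finite(scores)]
  pos <- x[x > 0]
  if (!length(pos)) {
    warning("no positive scores: tail-free model, divergence calls disabled")
    return(list(muLog = NA_real_, sigmaLog = NA_real_, tailFree = TRUE))
  }
  t <- pos[pos > gaussian$mu + tailK * gaussian$sigma]
  if (length(t) < 10L) {
    warning(sprintf(
      "only %d scores above the tail threshold: fitting on all positive scores",
      length(t)
    ))
    t <- pos
  }
  lt <- log(t)
  muL <- mean(lt)
  sL <- if (length(lt) > 1L) sd(lt) else 0
  if (sL <= 0) sL <- 1e-8
  ## responsibility-weighted refinement, Gaussian fixed, equal priors
  if (!gaussian$degenerate) {
    for (it in seq_len(50L)) {
      dG <- dnorm(t, gaussian$mu, gaussian$sigma)
      dL <- dlnorm(t, muL, sL)
      w <- dL / (dG + dL)
      w[!is.finite(w)] <- 0.5
      sw <- sum(w)
      if (sw < 1e-8) break
      muNew <- sum(w * lt) / sw
      sNew <- sqrt(sum(w * (lt - muNew)^2) / sw)
      if (sNew <= 0) sNew <- 1e-8
      if (abs(muNew - muL) < 1e-8 && abs(sNew - sL) < 1e-8) {
        muL <- muNew; sL <- sNew
        break
      }
      muL <- muNew; sL <- sNew
    }
  }
  list(muLog = muL, sigmaLog = sL, tailFree = FALSE)
}

#' Combine the two fitted components into a mixture model
#'
#' By default the full score distribution is modelled as the equal-weight
#' average of the fitted Gaussian and log-normal densities (weight = 0.5).
#' With \code{estimateWeight = TRUE} the weight is re-estimated by EM
#' iterations that update only the mixing weight (component parameters
#' frozen), stopping when the change falls below 1e-6 or after 200
#' iterations. A tail-free model gets weight 1.
#'
#' @param gaussian list from [fitGaussianCore()].
#' @param lognormal list from [fitLognormalTail()].
#' @param scores the scores (required when \code{estimateWeight = TRUE}).
#' @param estimateWeight re-estimate the Gaussian weight by EM.
#' @param epsilon the Jaccard floor used for the scores (recorded in the
#'   model for provenance; NA if unknown).
#' @return a \linkS4class{ConservationMixture}.
#' @export
combineComponents <- function(gaussian, lognormal, scores = NULL,
                              estimateWeight = FALSE, epsilon = NA_real_) {
  w <- if (lognormal$tailFree) 1 else 0.5
  n <- if (is.null(scores)) NA_real_ else sum(is.finite(scores))
  if (estimateWeight && !lognormal$tailFree) {
    if (is.null(scores)) stop("estimateWeight = TRUE requires scores")
    x <- scores[is.finite(scores)]
    for (it in seq_len(200L)) {
      dG <- w * dnorm(x, gaussian$mu, gaussian$sigma)
      dL <- (1 - w) * dlnorm(x, lognormal$muLog, lognormal$sigmaLog)
      tot <- dG + dL
      r <- ifelse(tot > 0, dG / tot, w)
      wNew <- mean(r)
      if (abs(wNew - w) < 1e-6) {
        w <- wNew
        break
      }
      w <- wNew
    }
  }
  new("ConservationMixture",
    mu = gaussian$mu, sigma = gaussian$sigma,
    muLog = lognormal$muLog, sigmaLog = lognormal$sigmaLog,
    weight = w, epsilon = epsilon,
    nScores = if (is.na(n)) 0 else n,
    tailFree = lognormal$tailFree,
    degenerate = isTRUE(gaussian$degenerate)
  )
}

#' Fit the full conservation mixture model
#'
#' Convenience wrapper running [fitGaussianCore()], [fitLognormalTail()] and
#' [combineComponents()] on a vector of bin scores.
#'
#' @inheritParams fitLognormalTail
#' @inheritParams combineComponents
#' @return a \linkS4class{ConservationMixture}.
#' @export
fitConservationMixture <- function(scores, tailK = 2, estimateWeight = FALSE,
                                   epsilon = NA_real_) {
  g <- fitGaussianCore(scores)
  l <- fitLognormalTail(scores, g, tailK = tailK)
  combineComponents(g, l, scores = scores, estimateWeight = estimateWeight,
                    epsilon = epsilon)
}

#' Mixture cumulative distribution function
#'
#' F(x) = w * Phi((x - mu) / sigma) + (1 - w) * Lognormal CDF(x). The small
#' Gaussian mass below 0 is retained (mu is typically many sigma above 0, so
#' it is negligible; no truncation is applied).
#'
#' @param model a \linkS4class{ConservationMixture}.
#' @param q numeric vector of scores.
#' @return F(q), same length as \code{q}.
#' @export
mixtureCDF <- function(model, q) {
  stopifnot(is(model, "ConservationMixture"))
  g <- pnorm(q, model@mu, model@sigma)
  if (model@tailFree) return(g)
  model@weight * g + (1 - model@weight) * plnorm(q, model@muLog, model@sigmaLog)
}

#' Sample scores from a fitted mixture model
#'
#' Draws component membership Bernoulli(weight), then a Gaussian or
#' log-normal variate. Uses the current RNG state; call \code{set.seed()}
#' beforehand for reproducibility.
#'
#' @param model a \linkS4class{ConservationMixture}.
#' @param n number of draws.
#' @return numeric vector of n scores.
#' @export
sampleMixture <- function(model, n) {
  stopifnot(is(model, "ConservationMixture"))
  fromG <- runif(n) < model@weight
  x <- numeric(n)
  x[fromG] <- rnorm(sum(fromG), model@mu, model@sigma)
  if (!model@tailFree && any(!fromG)) {
    x[!fromG] <- rlnorm(sum(!fromG), model@muLog, model@sigmaLog)
  }
  x
}

#' Classify bins as conserved, divergent or neutral
#'
#' For each bin, the conservation p-value is the left-tail probability
#' F(x) of its score under the mixture (an unusually small score means
#' unusually high similarity) and the divergence p-value is the right tail
#' 1 - F(x). A bin is called conserved when pConserved <= alpha, divergent
#' when pDivergent <= alpha, neutral otherwise; for alpha < 0.5 the two
#' calls are mutually exclusive. Optionally the p-values are
#' Benjamini-Hochberg adjusted per tail before thresholding.
#'
#' @param scores the per-bin score data.frame from [scoreBins()] (or any
#'   data.frame with columns \code{bin}, \code{refStart}, \code{refEnd},
#'   \code{score}).
#' @param model a \linkS4class{ConservationMixture}.
#' @param alpha per-tail significance level in (0, 1); default 0.05.
#' @param fdr apply Benjamini-Hochberg correction per tail.
#' @return the input data.frame with added columns \code{pConserved},
#'   \code{pDivergent} and \code{class} (factor conserved/neutral/divergent).
#' @export
classifyBins <- function(scores, model, alpha = 0.05, fdr = FALSE) {
  stopifnot(is.data.frame(scores), is(model, "ConservationMixture"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  f <- mixtureCDF(model, scores$score)
  pC <- f
  pD <- 1 - f
  if (model@tailFree) pD <- rep(1, length(pD))  # divergence calls disabled
  pCadj <- if (fdr) p.adjust(pC, method = "BH") else pC
  pDadj <- if (fdr) p.adjust(pD, method = "BH") else pD
  cls <- rep("neutral", nrow(scores))
  cls[pCadj <= alpha] <- "conserved"
  cls[pDadj <= alpha] <- "divergent"
  out <- scores
  out$pConserved <- pC
  out$pDivergent <- pD
  out$class <- factor(cls, levels = c("conserved", "neutral", "divergent"))
  out
}

#' Merge adjacent same-class significant bins into regions
#'
#' Maximal runs of adjacent non-neutral bins with identical class are merged
#' into single regions annotated with the smallest p-value of the run.
#'
#' @param classified data.frame from [classifyBins()].
#' @param referenceName chromosome name for the output ranges (the reference
#'   path name).
#' @return a [GenomicRanges::GRanges] sorted by start with metadata columns
#'   \code{class}, \code{minP} and \code{nBins}; empty when no bin is
#'   significant.
#' @export
mergeRegions <- function(classified, referenceName) {
  stopifnot(is.data.frame(classified), "class" %in% names(classified))
  sig <- classified$class != "neutral"
  emptyGR <- GenomicRanges::GRanges(
    seqnames = character(), ranges = IRanges::IRanges(),
    class = character(), minP = numeric(), nBins = integer()
  )
  if (!any(sig)) return(emptyGR)
  r <- rle(paste0(as.character(classified$class)))
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  keep <- r$values != "neutral"
  if (!any(keep)) return(emptyGR)
  startIdx <- startIdx[keep]; endIdx <- endIdx[keep]; cls <- r$values[keep]
  minP <- mapply(function(s, e, cl) {
    p <- if (cl == "conserved") classified$pConserved else classified$pDivergent
    min(p[s:e])
  }, startIdx, endIdx, cls)
  gr <- GenomicRanges::GRanges(
    seqnames = referenceName,
    ranges = IRanges::IRanges(
      start = classified$refStart[startIdx] + 1L,  # 0-based -> 1-based
      end = classified$refEnd[endIdx]
    ),
    class = cls,
    minP = unname(minP),
    nBins = endIdx - startIdx + 1L
  )
  sort(gr)
}
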