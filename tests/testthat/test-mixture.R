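rmixScores <- function(n, piG, mu = 0.05, sigma = 0.02, muL = 0, sL = 0.5) {
  fromG <- runif(n) < piG
  ifelse(fromG, rnorm(n, mu, sigma), rlnorm(n, muL, sL))
}

test_that("the Gaussian bulk is recovered, pure and contaminated", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- fitGaussianCore(rnorm(10000, 0.05, 0.02))
    expect_lt(abs(g$mu - 0.05), 0.005)
    expect_lt(abs(g$sigma - 0.02), 0.005)
  }
  # 10% heavy right tail must not drag mu
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(rnorm(9000, 0.05, 0.02), rlnorm(1000, 1, 0.5))
    g <- fitGaussianCore(x)
    expect_lt(abs(g$mu - 0.05), 0.01)
  }
})

test_that("a degenerate score vector falls back with a warning", {
  expect_warning(g <- fitGaussianCore(rep(0.1, 100)), "degenerate")
  expect_equal(g$mu, 0.1)
  expect_true(g$degenerate)
  expect_gt(g$sigma, 0)
  expect_lt(g$sigma, 1e-6)
})

test_that("the log-normal tail is recovered from tail scores", {
  for (seed in 1:5) {
    set.seed(seed)
    # bulk + a 2000-point log-normal tail, as after thresholding
    x <- c(rnorm(8000, 0.05, 0.02), rlnorm(2000, 0, 0.5))
    g <- fitGaussianCore(x)
    l <- fitLognormalTail(x, g)
    expect_false(l$tailFree)
    expect_lt(abs(l$muLog - 0), 0.05)
    expect_lt(abs(l$sigmaLog - 0.5), 0.05)
  }
})

test_that("sparse or absent tails take the documented fallbacks", {
  set.seed(1)
  x <- rnorm(1000, 0.05, 0.002)
  g <- fitGaussianCore(x)
  # ~5 points beyond 2 sd is below the 10-point minimum -> fallback warning
  expect_warning(
    l <- fitLognormalTail(c(x[abs(x - 0.05) < 2 * 0.002], 0.06, 0.061), g),
    "all positive scores"
  )
  expect_false(l$tailFree)

  expect_warning(g0 <- fitGaussianCore(rep(0, 50)), "degenerate")
  expect_warning(l0 <- fitLognormalTail(rep(0, 50), g0), "tail-free")
  expect_true(l0$tailFree)
  m0 <- combineComponents(g0, l0)
  expect_equal(m0@weight, 1)
  expect_true(m0@tailFree)
})

test_that("components combine with weight 0.5, or EM-estimated on request", {
  set.seed(3)
  x <- rmixScores(10000, 0.5)
  m <- fitConservationMixture(x)
  expect_equal(m@weight, 0.5)

  set.seed(4)
  x8 <- rmixScores(10000, 0.8)
  m8 <- fitConservationMixture(x8, estimateWeight = TRUE)
  expect_lt(abs(m8@weight - 0.8), 0.03)
})

test_that("the mixture CDF is a proper nondecreasing CDF", {
  set.seed(5)
  m <- fitConservationMixture(rmixScores(5000, 0.5))
  grid <- seq(-1, 50, length.out = 2000)
  f <- mixtureCDF(m, grid)
  expect_true(all(diff(f) >= 0))
  expect_lt(mixtureCDF(m, -100), 1e-12)
  expect_gt(mixtureCDF(m, 1e6), 1 - 1e-9)
})

test_that("bins are classified by mixture tail probabilities", {
  set.seed(6)
  x <- rmixScores(2000, 0.5)
  m <- fitConservationMixture(x)
  df <- data.frame(bin = 0:2, refStart = c(0, 10, 20), refEnd = c(10, 20, 30),
                   nPairs = 1,
                   score = c(0, median(x), quantile(x, 0.999)))
  cl <- classifyBins(df, m, alpha = 0.05)
  # x = 0 with mu >> sigma sits far in the conserved tail
  expect_lt(mixtureCDF(m, 0), 0.05)
  expect_equal(as.character(cl$class), c("conserved", "neutral", "divergent"))
  expect_true(all(cl$pConserved + cl$pDivergent == 1))

  # a score at the mixture median is neutral at alpha = 0.05
  medScore <- df$score[2]
  expect_gt(cl$pConserved[2], 0.05)
  expect_gt(cl$pDivergent[2], 0.05)

  expect_error(classifyBins(df, m, alpha = 0), "alpha")
})

test_that("increasing a score never moves a bin toward conserved", {
  set.seed(8)
  m <- fitConservationMixture(rmixScores(5000, 0.5))
  grid <- seq(0, 10, length.out = 200)
  df <- data.frame(bin = seq_along(grid) - 1, refStart = grid * 10,
                   refEnd = grid * 10 + 10, nPairs = 1, score = grid)
  cl <- classifyBins(df, m, alpha = 0.05)
  code <- c(conserved = 0, neutral = 1, divergent = 2)[as.character(cl$class)]
  expect_true(all(diff(code) >= 0))  # monotone in the score
})

test_that("null reclassification is calibrated at alpha per tail", {
  set.seed(9)
  m <- fitConservationMixture(rmixScores(10000, 0.5))
  set.seed(10)
  xnull <- sampleMixture(m, 10000)
  df <- data.frame(bin = seq_along(xnull) - 1, refStart = 0, refEnd = 1,
                   nPairs = 1, score = xnull)
  cl <- classifyBins(df, m, alpha = 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(mean(cl$class == "conserved") - 0.05), se3)
  expect_lt(abs(mean(cl$class == "divergent") - 0.05), se3)
})

test_that("parameter recovery holds across seeds (property)", {
  for (seed in 1:10) {
    set.seed(seed * 13)
    m <- fitConservationMixture(rmixScores(10000, 0.5))
    expect_lt(abs(m@mu - 0.05), 0.005)
    expect_lt(abs(m@sigma - 0.02), 0.005)
    expect_lt(abs(m@muLog - 0), 0.05)
    expect_lt(abs(m@sigmaLog - 0.5), 0.05)
  }
})

test_that("adjacent same-class bins merge into maximal regions", {
  df <- data.frame(
    bin = 0:5,
    refStart = seq(0, 50, 10), refEnd = seq(10, 60, 10),
    nPairs = 1, score = 0,
    pConserved = c(0.01, 0.02, 0.5, 0.9, 0.9, 0.9),
    pDivergent = c(0.99, 0.98, 0.5, 0.04, 0.01, 0.02),
    class = factor(c("conserved", "conserved", "neutral",
                     "divergent", "divergent", "divergent"),
                   levels = c("conserved", "neutral", "divergent"))
  )
  gr <- mergeRegions(df, "chrT")
  expect_equal(length(gr), 2L)
  expect_equal(as.character(gr$class), c("conserved", "divergent"))
  expect_equal(GenomicRanges::start(gr), c(1, 31))   # 1-based GRanges
  expect_equal(GenomicRanges::end(gr), c(20, 60))
  expect_equal(gr$minP, c(0.01, 0.01))
  expect_equal(gr$nBins, c(2L, 3L))

  # all-neutral input gives an empty result
  df$class[] <- "neutral"
  expect_equal(length(mergeRegions(df, "chrT")), 0L)

  # alternating classes never merge
  df$class <- factor(rep(c("conserved", "divergent"), 3),
                     levels = levels(df$class))
  expect_equal(length(mergeRegions(df, "chrT")), 6L)
})
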