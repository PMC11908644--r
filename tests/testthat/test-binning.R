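test_that("universal single-copy segments are boundary candidates", {
  g <- makeGraph(
    list(p1 = c("a+", "b+", "c+"), p2 = c("a+", "b+", "c+")),
    c(a = 5, b = 3, c = 5)
  )
  expect_equal(findBoundaryCandidates(g)@segId, c("a", "b", "c"))

  g2 <- makeGraph(
    list(p1 = c("a+", "b+", "c+"), p2 = c("a+", "d+", "c+")),
    c(a = 5, b = 3, c = 5, d = 3)
  )
  expect_equal(findBoundaryCandidates(g2)@segId, c("a", "c"))

  # multiplicity: a traversed twice by p1 disqualifies it
  g3 <- makeGraph(
    list(p1 = c("a+", "b+", "a+"), p2 = c("a+", "b+")),
    c(a = 5, b = 3)
  )
  expect_equal(findBoundaryCandidates(g3)@segId, "b")
})

test_that("candidates are ordered by reference coordinate with intervals", {
  g <- makeGraph(
    list(p1 = c("a+", "b+", "c+"), p2 = c("a+", "b+", "c+")),
    c(a = 5, b = 3, c = 5)
  )
  tab <- boundaryTable(findBoundaryCandidates(g))
  expect_equal(tab$refStart, c(0, 5, 8))
  expect_equal(tab$refEnd, c(5, 8, 13))
})

test_that("globally inverted haplotypes keep their anchors", {
  g <- makeGraph(
    list(p1 = c("a+", "x+", "c+"), p2 = c("c-", "y-", "a-")),
    c(a = 5, x = 3, c = 5, y = 3)
  )
  cand <- findBoundaryCandidates(g)
  expect_equal(cand@segId, c("a", "c"))
  # but strict-forward mode drops them
  expect_equal(length(findBoundaryCandidates(g, strictForward = TRUE)), 0L)
})

test_that("a locally flipped anchor is dropped as a candidate", {
  # p2 is forward-dominant (a, c forward) but traverses b inverted
  g <- makeGraph(
    list(p1 = c("a+", "b+", "c+"), p2 = c("a+", "b-", "c+")),
    c(a = 5, b = 3, c = 5)
  )
  expect_equal(findBoundaryCandidates(g)@segId, c("a", "c"))
})

test_that("greedy selection enforces >= s end-to-start gaps", {
  g <- makeGraph(
    list(p1 = c("b1+", "u+", "b2+", "v+", "b3+", "w+", "b4+"),
         p2 = c("b1+", "u+", "b2+", "v+", "b3+", "w+", "b4+")),
    c(b1 = 10, u = 490, b2 = 10, v = 690, b3 = 10, w = 1390, b4 = 10)
  )
  cand <- findBoundaryCandidates(g)
  # candidate intervals: b1 (0,10), b2 (500,510), b3 (1200,1210), b4 (2600,2610)
  tab <- boundaryTable(cand)
  expect_equal(tab$refStart[tab$segId %in% paste0("b", 1:4)],
               c(0, 500, 1200, 2600))
  sel <- selectBoundaries(cand, 1000)
  st <- boundaryTable(sel)
  st <- st[st$segId %in% paste0("b", 1:4), ]
  expect_equal(st$segId, c("b1", "b3", "b4"))
  # gap invariant
  full <- boundaryTable(sel)
  expect_true(all(full$refStart[-1] - full$refEnd[-nrow(full)] >= 1000))
})

test_that("degenerate selections behave", {
  g <- makeGraph(
    list(p1 = c("a+", "x+"), p2 = c("a+", "y+")),
    c(a = 5, x = 100, y = 100)
  )
  cand <- findBoundaryCandidates(g)
  expect_equal(length(selectBoundaries(cand, 1)), 1L)   # single candidate
  expect_equal(length(selectBoundaries(cand, 1e6)), 1L) # s > reference length
  bins <- buildBins(g, selectBoundaries(cand, 1e6))
  expect_equal(nBins(bins), 2L)  # half-anchor flank + rest
  expect_equal(binRanges(bins)$refEnd[2], referenceLength(g))
})

test_that("sub-paths are extracted strictly between boundaries", {
  g <- makeGraph(
    list(p1 = c("a+", "x+", "c+"), p2 = c("a+", "y+", "z+", "c+")),
    c(a = 4, x = 3, c = 4, y = 2, z = 1)
  )
  bins <- buildBins(g, findBoundaryCandidates(g))
  # middle bin sits between a and c
  mid <- which(binRanges(bins)$leftBoundary == "a")
  sub <- binSubpaths(bins)[[mid]]
  expect_equal(sub$p1$ids, "x")
  expect_equal(sub$p2$ids, c("y", "z"))
  # neither boundary segment appears in any sub-path
  for (b in binSubpaths(bins)) {
    for (s in b) expect_false(any(c("a", "c") %in% s$ids))
  }
})

test_that("a deletion yields an empty sub-path", {
  g <- makeGraph(
    list(p1 = c("a+", "x+", "c+"), p2 = c("a+", "c+")),
    c(a = 4, x = 3, c = 4)
  )
  bins <- buildBins(g, findBoundaryCandidates(g))
  mid <- which(binRanges(bins)$leftBoundary == "a")
  expect_equal(length(binSubpaths(bins)[[mid]]$p2$ids), 0L)
})

test_that("a region traversed in reverse is normalized to forward", {
  g <- makeGraph(
    list(p1 = c("a+", "x+", "c+"), p2 = c("c-", "x-", "a-")),
    c(a = 4, x = 3, c = 4)
  )
  # x is universal here too; bin between a and c only
  cand <- findBoundaryCandidates(g)
  bounds <- cand[which(cand@segId %in% c("a", "c"))]
  bins <- buildBins(g, bounds)
  mid <- which(binRanges(bins)$leftBoundary == "a")
  sub <- binSubpaths(bins)[[mid]]
  expect_equal(sub$p2, list(ids = "x", strands = "+"))
  expect_equal(sub$p1, list(ids = "x", strands = "+"))
})

test_that("with no boundary the whole chromosome is one bin", {
  g <- makeGraph(
    list(p1 = c("x+", "y+"), p2 = c("u+", "v+")),
    c(x = 5, y = 5, u = 4, v = 6)
  )
  cand <- findBoundaryCandidates(g)
  expect_equal(length(cand), 0L)
  expect_warning(bins <- buildBins(g, cand), "one bin")
  expect_equal(nBins(bins), 1L)
  expect_equal(binRanges(bins)$refEnd, referenceLength(g))
  expect_equal(binSubpaths(bins)[[1]]$p1$ids, c("x", "y"))
})

test_that("bins tile the reference and boundaries are universal (property)", {
  for (seed in 1:8) {
    nh <- 2L + (seed %% 4L)
    sim <- simulatePangenome(
      nHaplotypes = nh, nRegions = 10, seed = seed,
      divergence = runif(10), svProbability = 0.1
    )
    g <- sim$graph
    bounds <- selectBoundaries(findBoundaryCandidates(g), 200)
    bins <- buildBins(g, bounds)
    br <- binRanges(bins)
    expect_equal(br$refStart[1], 0)
    expect_equal(br$refEnd[nrow(br)], referenceLength(g))
    expect_equal(br$refStart[-1], br$refEnd[-nrow(br)])
    for (nm in pathNames(g)) {
      p <- haplotypePaths(g)[[nm]]
      expect_true(all(table(p$ids)[bounds@segId] == 1L))
    }
  }
})

test_that("binning is deterministic and identical paths give identical sub-paths", {
  sim <- simulatePangenome(nRegions = 6, seed = 11)
  b1 <- buildBins(sim$graph,
                  selectBoundaries(findBoundaryCandidates(sim$graph), 100))
  b2 <- buildBins(sim$graph,
                  selectBoundaries(findBoundaryCandidates(sim$graph), 100))
  expect_identical(binSubpaths(b1), binSubpaths(b2))
  expect_identical(binRanges(b1), binRanges(b2))

  ident <- simulatePangenome(nRegions = 4, divergence = rep(0, 4),
                             svProbability = 0, seed = 5)
  bins <- buildBins(ident$graph, findBoundaryCandidates(ident$graph))
  for (b in binSubpaths(bins)) {
    for (s in b[-1]) expect_identical(s, b[[1]])
  }
})
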