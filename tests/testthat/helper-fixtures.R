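# Shared fixtures and the independent brute-force Jaccard oracle.

# Build a PangenomeGraph directly from a list of step-token vectors like
# c("a+", "x-", "c+"); segment sequences are deterministic runs of "A".
makeGraph <- function(paths, lengths, referenceName = names(paths)[1]) {
  seg <- data.frame(
    id = names(lengths),
    length = unname(lengths),
    sequence = vapply(lengths, function(n) strrep("A", n), character(1)),
    stringsAsFactors = FALSE
  )
  rownames(seg) <- seg$id
  plist <- lapply(paths, function(toks) {
    list(
      ids = substring(toks, 1, nchar(toks) - 1),
      strands = substring(toks, nchar(toks))
    )
  })
  new("PangenomeGraph",
    segments = seg, paths = plist, referenceName = referenceName,
    links = data.frame(
      from = character(), fromOrient = character(),
      to = character(), toOrient = character(), stringsAsFactors = FALSE
    )
  )
}

# Brute-force weighted Jaccard: materialize each multiset as a bag of unit
# elements "<segment>:<copy>:<base>" and count multiset intersection/union.
# Independent of the min/max-sum formula used by weightedJaccard().
oracleJaccard <- function(a, b, lengths) {
  bag <- function(counts) {
    out <- character()
    for (g in names(counts)) {
      for (i in seq_len(counts[[g]])) {
        out <- c(out, paste(g, i, seq_len(lengths[[g]]), sep = ":"))
      }
    }
    out
  }
  ba <- bag(a)
  bb <- bag(b)
  if (!length(ba) && !length(bb)) return(1)
  ta <- table(ba)
  tb <- table(bb)
  keys <- union(names(ta), names(tb))
  ca <- ifelse(keys %in% names(ta), as.integer(ta[keys]), 0L)
  cb <- ifelse(keys %in% names(tb), as.integer(tb[keys]), 0L)
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

randomMultiset <- function(universe, maxCount = 3L) {
  picked <- universe[runif(length(universe)) < 0.5]
  setNames(sample.int(maxCount, length(picked), replace = TRUE), picked)
}

# Structural graph equality up to record order.
expectSameGraph <- function(g1, g2) {
  s1 <- gfaSegments(g1)[order(gfaSegments(g1)$id), ]
  s2 <- gfaSegments(g2)[order(gfaSegments(g2)$id), ]
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
  expect_setequal(pathNames(g1), pathNames(g2))
  for (nm in pathNames(g1)) {
    expect_equal(haplotypePaths(g1)[[nm]], haplotypePaths(g2)[[nm]],
                 info = nm)
  }
}

writeTempGFA <- function(lines) {
  tf <- tempfile(fileext = ".gfa")
  writeLines(lines, tf)
  tf
}
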