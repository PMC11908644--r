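## GFA v1 reader/writer for single-chromosome pangenome graphs.
## Honors S, P, W and L records; everything else (H, C, ...) is skipped.
## Coordinates are 0-based half-open throughout.

panconserveError <- function(msg, class) {
  stop(structure(
    class = c(class, "panconserveError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Read a pangenome graph from GFA v1
#'
#' Parses one chromosome of a pangenome variation graph. Haplotypes may be
#' given as P-lines, as W-line walks, or a mixture; W-lines are normalized to
#' PanSN-style path names \code{sample#haplotype#seqid}, and consecutive
#' W-lines of the same sample/haplotype/seqid are concatenated in file order.
#' S-lines may appear before or after the paths that reference them (two-pass
#' resolution). Segment lengths come from the sequence, or from an
#' \code{LN:i} tag when the sequence is \code{"*"}.
#'
#' P-line overlap fields must be \code{"*"} or all-match CIGARs
#' (e.g. \code{"0M"}): the method assumes blunt segment concatenation.
#' W-lines naming more than one distinct seqid are rejected - the tool
#' operates on one chromosome per file. Lowercase and ambiguity codes in
#' sequences are accepted; only segment lengths enter the computation.
#'
#' @param file path to a GFA v1 file, or a connection.
#' @param referenceName name of the path to use as coordinate backbone;
#'   defaults to the first path in file order.
#' @param validateLinks if TRUE, check that every consecutive step of every
#'   path is backed by an L-line (paths alone determine the computation, so
#'   this is off by default).
#' @return a validated \linkS4class{PangenomeGraph}.
#' @examples
#' gfa <- c("S\ts1\tACGTA", "S\ts2\tTTG", "S\ts3\tGGCCA",
#'          "P\thapA\ts1+,s2+,s3+\t*", "P\thapB\ts1+,s3+\t*")
#' tf <- tempfile(fileext = ".gfa"); writeLines(gfa, tf)
#' g <- readGFA(tf)
#' referenceLength(g)
#' @export
readGFA <- function(file, referenceName = NULL, validateLinks = FALSE) {
  lines <- readLines(file)
  recType <- substr(lines, 1L, 1L)

  ## --- segments -------------------------------------------------------
  sIdx <- which(recType == "S")
  segId <- character(length(sIdx))
  segSeq <- character(length(sIdx))
  segLen <- numeric(length(sIdx))
  for (k in seq_along(sIdx)) {
    f <- strsplit(lines[sIdx[k]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      panconserveError(sprintf("malformed S-line %d", sIdx[k]), "gfaParseError")
    }
    segId[k] <- f[2L]
    seq <- f[3L]
    lnTag <- grep("^LN:i:", f[-(1:3)], value = TRUE)
    ln <- if (length(lnTag)) as.numeric(sub("^LN:i:", "", lnTag[1L])) else NA
    if (seq == "*") {
      if (is.na(ln)) {
        panconserveError(sprintf(
          "segment '%s' (line %d) has neither sequence nor LN tag",
          f[2L], sIdx[k]
        ), "gfaParseError")
      }
      segSeq[k] <- NA_character_
      segLen[k] <- ln
    } else {
      if (!is.na(ln) && ln != nchar(seq)) {
        panconserveError(sprintf(
          "segment '%s' (line %d): LN tag disagrees with sequence length",
          f[2L], sIdx[k]
        ), "gfaParseError")
      }
      segSeq[k] <- seq
      segLen[k] <- nchar(seq)
    }
  }
  if (anyDuplicated(segId)) {
    panconserveError(sprintf(
      "duplicate segment id '%s'", segId[duplicated(segId)][1L]
    ), "gfaParseError")
  }

  ## --- paths ----------------------------------------------------------
  paths <- list()
  pathLine <- list()  # first defining line number, for error messages
  addSteps <- function(name, ids, strands, lineNo) {
    if (is.null(paths[[name]])) {
      paths[[name]] <<- list(ids = ids, strands = strands)
      pathLine[[name]] <<- lineNo
    } else {
      paths[[name]]$ids <<- c(paths[[name]]$ids, ids)
      paths[[name]]$strands <<- c(paths[[name]]$strands, strands)
    }
  }

  wSeqIds <- character()
  for (i in which(recType %in% c("P", "W"))) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (recType[i] == "P") {
      if (length(f) < 3L) {
        panconserveError(sprintf("malformed P-line %d", i), "gfaParseError")
      }
      ov <- if (length(f) >= 4L) f[4L] else "*"
      if (ov != "*") {
        cig <- strsplit(ov, ",", fixed = TRUE)[[1L]]
        if (!all(grepl("^[0-9]+M$", cig))) {
          panconserveError(sprintf(
            "P-line %d ('%s'): only '*' or all-match overlaps are supported",
            i, f[2L]
          ), "gfaParseError")
        }
      }
      toks <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
      ori <- substring(toks, nchar(toks))
      if (!all(ori %in% c("+", "-"))) {
        panconserveError(sprintf(
          "P-line %d ('%s'): step without +/- orientation", i, f[2L]
        ), "gfaParseError")
      }
      addSteps(f[2L], substring(toks, 1L, nchar(toks) - 1L), ori, i)
    } else {
      if (length(f) < 7L) {
        panconserveError(sprintf("malformed W-line %d", i), "gfaParseError")
      }
      wSeqIds <- union(wSeqIds, f[4L])
      if (length(wSeqIds) > 1L) {
        panconserveError(paste0(
          "W-lines name more than one seqid (",
          paste(wSeqIds, collapse = ", "),
          "): one GFA file must describe a single chromosome"
        ), "gfaParseError")
      }
      name <- paste(f[2L], f[3L], f[4L], sep = "#")
      m <- regmatches(f[7L], gregexpr("[><][^><]+", f[7L]))[[1L]]
      if (!length(m)) {
        panconserveError(sprintf("W-line %d: empty walk", i), "gfaParseError")
      }
      addSteps(name, substring(m, 2L),
               ifelse(substring(m, 1L, 1L) == ">", "+", "-"), i)
    }
  }

  if (length(paths) < 2L) {
    panconserveError(
      "not a pangenome: fewer than 2 haplotype paths in the GFA",
      "gfaNotPangenome"
    )
  }

  ## deferred segment resolution: name the offending line
  knownIds <- segId
  for (nm in names(paths)) {
    unknown <- setdiff(paths[[nm]]$ids, knownIds)
    if (length(unknown)) {
      panconserveError(sprintf(
        "path '%s' (line %d) references unknown segment '%s'",
        nm, pathLine[[nm]], unknown[1L]
      ), "gfaParseError")
    }
  }

  ## --- links (optional validation only) -------------------------------
  lIdx <- which(recType == "L")
  links <- if (length(lIdx)) {
    lf <- do.call(rbind, strsplit(lines[lIdx], "\t", fixed = TRUE))
    data.frame(
      from = lf[, 2L], fromOrient = lf[, 3L],
      to = lf[, 4L], toOrient = lf[, 5L],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      from = character(), fromOrient = character(),
      to = character(), toOrient = character(),
      stringsAsFactors = FALSE
    )
  }

  if (is.null(referenceName)) referenceName <- names(paths)[1L]
  if (!(referenceName %in% names(paths))) {
    panconserveError(sprintf(
      "reference path '%s' not found; available: %s",
      referenceName, paste(names(paths), collapse = ", ")
    ), "gfaParseError")
  }

  seg <- data.frame(
    id = segId, length = segLen, sequence = segSeq,
    stringsAsFactors = FALSE
  )
  rownames(seg) <- segId
  g <- new("PangenomeGraph",
    segments = seg, paths = paths,
    referenceName = referenceName, links = links
  )
  if (validateLinks) .checkLinks(g)
  g
}

## every consecutive oriented step pair must appear as a link (either
## direction); purely diagnostic
.checkLinks <- function(graph) {
  if (!nrow(graph@links)) {
    warning("link validation requested but the GFA has no L-lines")
    return(invisible(FALSE))
  }
  key <- function(a, ao, b, bo) paste(a, ao, b, bo, sep = "\r")
  fwd <- key(graph@links$from, graph@links$fromOrient,
             graph@links$to, graph@links$toOrient)
  flip <- c(`+` = "-", `-` = "+")
  rev <- key(graph@links$to, flip[graph@links$toOrient],
             graph@links$from, flip[graph@links$fromOrient])
  have <- c(fwd, rev)
  for (nm in pathNames(graph)) {
    p <- graph@paths[[nm]]
    n <- length(p$ids)
    if (n < 2L) next
    k <- key(p$ids[-n], p$strands[-n], p$ids[-1L], p$strands[-1L])
    miss <- which(!(k %in% have))
    if (length(miss)) {
      warning(sprintf(
        "path '%s': %d consecutive step(s) not backed by an L-line (first: %s -> %s)",
        nm, length(miss), p$ids[miss[1L]], p$ids[miss[1L] + 1L]
      ))
    }
  }
  invisible(TRUE)
}

#' Write a pangenome graph to GFA v1
#'
#' Emits S-lines with inlined sequences followed by paths, either as P-lines
#' or as W-line walks (\code{format = "W"}; path names must then follow the
#' PanSN convention \code{sample#haplotype#seqid}). Reading the result back
#' with [readGFA()] reproduces the graph.
#'
#' @param graph a \linkS4class{PangenomeGraph}; every segment must carry a
#'   non-empty sequence.
#' @param file output path or connection.
#' @param format \code{"P"} (default) or \code{"W"} path dialect.
#' @return invisibly, \code{file}.
#' @export
writeGFA <- function(graph, file, format = c("P", "W")) {
  format <- match.arg(format)
  stopifnot(is(graph, "PangenomeGraph"))
  validObject(graph)
  seg <- graph@segments
  if (any(is.na(seg$sequence) | nchar(seg$sequence) == 0L)) {
    bad <- seg$id[which(is.na(seg$sequence) | nchar(seg$sequence) == 0L)[1L]]
    panconserveError(sprintf(
      "cannot write GFA: segment '%s' has no sequence", bad
    ), "gfaWriteError")
  }
  out <- c("H\tVN:Z:1.0", sprintf("S\t%s\t%s", seg$id, seg$sequence))
  lens <- segmentLengths(graph)
  for (nm in pathNames(graph)) {
    p <- graph@paths[[nm]]
    if (format == "P") {
      out <- c(out, sprintf(
        "P\t%s\t%s\t*", nm, paste0(p$ids, p$strands, collapse = ",")
      ))
    } else {
      parts <- strsplit(nm, "#", fixed = TRUE)[[1L]]
      if (length(parts) != 3L) {
        panconserveError(sprintf(
          "W-line output requires PanSN path names (sample#hap#seqid); got '%s'",
          nm
        ), "gfaWriteError")
      }
      walk <- paste0(ifelse(p$strands == "+", ">", "<"), p$ids, collapse = "")
      out <- c(out, sprintf(
        "W\t%s\t%s\t%s\t0\t%d\t%s",
        parts[1L], parts[2L], parts[3L], sum(lens[p$ids]), walk
      ))
    }
  }
  writeLines(out, file)
  invisible(file)
}

#' Reference-coordinate intervals of every segment on the reference path
#'
#' Walks the reference path and returns the 0-based half-open interval of
#' each step, obtained by cumulative sum of segment lengths. A segment
#' traversed k times yields k rows.
#'
#' @param graph a \linkS4class{PangenomeGraph}.
#' @return a data.frame with columns \code{segId}, \code{start}, \code{end},
#'   one row per reference step, in traversal order.
#' @export
referencePositions <- function(graph) {
  stopifnot(is(graph, "PangenomeGraph"))
  p <- graph@paths[[graph@referenceName]]
  lens <- unname(segmentLengths(graph)[p$ids])
  ends <- cumsum(lens)
  data.frame(
    segId = p$ids,
    start = ends - lens,
    end = ends,
    stringsAsFactors = FALSE
  )
}
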