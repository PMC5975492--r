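## Exact-match anchor finding and collinear chaining between two sequences.
## This is the alignment core behind reference-based assembly metrics,
## reference-guided contig merging, inverted-repeat detection and
## whole-genome variant comparison.

#' Maximal exact matches between a query and a reference
#'
#' Finds maximal runs of exact `minLen`-mer matches on both strands. A
#' `-` strand anchor means `ref[rstart..rend]` equals the reverse
#' complement of `query[qstart..qend]`.
#'
#' @param query,ref DNA strings (or objects with a sequence, via
#'   [genomeSeq()]).
#' @param minLen minimum exact match length (default 20).
#' @param maxOcc reference k-mers occurring more often than this are
#'   skipped (repeat masking; default 50).
#' @return data.frame with columns `qstart`, `qend`, `rstart`, `rend`,
#'   `strand`, `len`.
#' @export
findAnchors <- function(query, ref, minLen = 20L, maxOcc = 50L) {
  query <- genomeSeq(query); ref <- genomeSeq(ref)
  k <- as.integer(minLen)
  empty <- data.frame(qstart = integer(0), qend = integer(0),
                      rstart = integer(0), rend = integer(0),
                      strand = character(0), len = integer(0))
  Lq <- nchar(query); Lr <- nchar(ref)
  if (Lq < k || Lr < k) return(empty)
  rstarts <- seq_len(Lr - k + 1L)
  refK <- data.table::data.table(kmer = substring(ref, rstarts,
                                                  rstarts + k - 1L),
                                 rpos = rstarts)
  occ <- refK[, list(n = .N), by = "kmer"]
  refK <- refK[!occ[occ$n > maxOcc], on = "kmer"]
  data.table::setkeyv(refK, "kmer")
  runsOf <- function(qseq) {
    qstarts <- seq_len(nchar(qseq) - k + 1L)
    qK <- data.table::data.table(kmer = substring(qseq, qstarts,
                                                  qstarts + k - 1L),
                                 qpos = qstarts)
    hits <- refK[qK, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0L) return(NULL)
    hits[, "diag" := hits$rpos - hits$qpos]
    data.table::setorderv(hits, c("diag", "qpos"))
    newRun <- c(TRUE, diff(hits$qpos) != 1L | diff(hits$diag) != 0L)
    hits[, "run" := cumsum(newRun)]
    hits[, list(q0 = min(qpos), q1 = max(qpos), r0 = min(rpos)),
         by = "run"]
  }
  out <- list()
  fw <- runsOf(query)
  if (!is.null(fw)) {
    out$fw <- data.frame(qstart = fw$q0, qend = fw$q1 + k - 1L,
                         rstart = fw$r0,
                         rend = fw$r0 + (fw$q1 - fw$q0) + k - 1L,
                         strand = "+",
                         len = fw$q1 - fw$q0 + k)
  }
  rc <- runsOf(revComp(query))
  if (!is.null(rc)) {
    out$rc <- data.frame(qstart = Lq - (rc$q1 + k - 1L) + 1L,
                         qend = Lq - rc$q0 + 1L,
                         rstart = rc$r0,
                         rend = rc$r0 + (rc$q1 - rc$q0) + k - 1L,
                         strand = "-",
                         len = rc$q1 - rc$q0 + k)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$qstart, res$rstart), ]
}

#' Best collinear chain of anchors
#'
#' Dynamic-programming chain maximizing total anchor length among anchors
#' of one strand with consistent query/reference order (small overlaps up
#' to `slack` bases are tolerated). Ties break toward the leftmost
#' reference position. Both strands are tried; the higher-scoring chain
#' wins.
#'
#' @param anchors data.frame from [findAnchors()].
#' @param slack permitted anchor overlap in bases (default 25).
#' @param maxAnchors keep only the longest this-many anchors per strand
#'   before the quadratic DP (default 2000).
#' @param leftTol chains scoring within this many bases of the optimum are
#'   considered tied and the leftmost (smallest chain `rstart`) wins; this
#'   pins content shared by the two inverted-repeat copies to the
#'   leftmost copy deterministically (default 30).
#' @return list with `anchors` (the chained subset, ordered by `qstart`),
#'   `strand`, `score` (total chained anchor length) and `offChain` (the
#'   anchors not in the chain); `NULL` if there are no anchors.
#' @export
chainAnchors <- function(anchors, slack = 25L, maxAnchors = 2000L,
                         leftTol = 30L) {
  if (is.null(anchors) || nrow(anchors) == 0L) return(NULL)
  bestOf <- function(a, strand) {
    a <- a[a$strand == strand, , drop = FALSE]
    if (nrow(a) == 0L) return(NULL)
    if (nrow(a) > maxAnchors)
      a <- a[order(-a$len), ][seq_len(maxAnchors), ]
    a <- a[order(a$qstart, a$rstart), ]
    n <- nrow(a)
    score <- a$len
    prev <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
      for (i in seq_len(j - 1L)) {
        okQ <- a$qstart[j] > a$qend[i] - slack
        okR <- if (strand == "+") a$rstart[j] > a$rend[i] - slack
               else a$rend[j] < a$rstart[i] + slack
        if (okQ && okR && score[i] + a$len[j] > score[j]) {
          score[j] <- score[i] + a$len[j]
          prev[j] <- i
        }
      }
    }
    pathFrom <- function(end) {
      path <- integer(0)
      while (!is.na(end)) { path <- c(end, path); end <- prev[end] }
      path
    }
    ## near-tied chains resolve to the leftmost reference placement
    ends <- which(score >= max(score) - leftTol)
    paths <- lapply(ends, pathFrom)
    rstarts <- vapply(paths, function(p) a$rstart[p[1L]], numeric(1))
    pick <- order(rstarts, -score[ends])[1L]
    path <- paths[[pick]]
    list(anchors = a[path, ], strand = strand, score = score[ends[pick]],
         offChain = a[-path, , drop = FALSE])
  }
  cands <- Filter(Negate(is.null), list(bestOf(anchors, "+"),
                                        bestOf(anchors, "-")))
  if (length(cands) == 0L) return(NULL)
  scores <- vapply(cands, `[[`, numeric(1), "score")
  keep <- which(scores >= max(scores) - leftTol)
  minR <- vapply(cands[keep], function(x) min(x$anchors$rstart), numeric(1))
  strandOrd <- vapply(cands[keep], function(x) x$strand == "-", logical(1))
  cands[[keep[order(minR, -scores[keep], strandOrd)[1L]]]]
}

#' Anchor a contig to a reference
#'
#' Convenience wrapper: anchors + best chain, plus summary fields used by
#' the merger and the metrics module.
#'
#' @param contig,ref DNA strings.
#' @param minAnchor minimum exact-match length (default 20).
#' @param slack chaining overlap slack (default 25).
#' @return `NULL` when the contig has no anchors, else a list with the
#'   [chainAnchors()] fields plus `refStart`/`refEnd` (reference span of
#'   the chain), `qAligned` (query bases inside chained anchors) and
#'   `offset` (implied reference position of contig base 1, `+` strand
#'   chains).
#' @export
anchorContig <- function(contig, ref, minAnchor = 20L, slack = 25L) {
  ch <- chainAnchors(findAnchors(contig, ref, minLen = minAnchor),
                     slack = slack)
  if (is.null(ch)) return(NULL)
  a <- ch$anchors
  ch$refStart <- min(a$rstart)
  ch$refEnd <- max(a$rend)
  ch$qAligned <- sum(a$len)
  ch$offset <- if (ch$strand == "+") a$rstart[1L] - a$qstart[1L] + 1L
               else NA_integer_
  ch
}

#' Project reference positions through an anchor chain onto the query
#'
#' Positions inside a chained anchor map exactly; positions in inter-anchor
#' gaps are interpolated from the nearest anchor edge. `+` strand chains
#' only (orient the query first).
#'
#' @param chain a [chainAnchors()] result with `strand == "+"`.
#' @param refPos integer vector of reference positions.
#' @return integer vector of query positions (NA outside the chain span).
#' @export
projectRefToQuery <- function(chain, refPos) {
  a <- chain$anchors
  stopifnot(chain$strand == "+")
  vapply(refPos, function(p) {
    inA <- which(a$rstart <= p & p <= a$rend)
    if (length(inA)) {
      i <- inA[1L]
      return(a$qstart[i] + (p - a$rstart[i]))
    }
    if (p < a$rstart[1L] || p > a$rend[nrow(a)]) return(NA_integer_)
    i <- max(which(a$rend < p)) # gap between anchors i and i+1
    a$qend[i] + (p - a$rend[i])
  }, integer(1))
}

## Align the inter-anchor gaps of a chain and emit variant rows.
## query/ref must be oriented (+ strand chain). Returns a data.frame of
## normalized variants in reference coordinates.
.chainVariants <- function(query, ref, chain) {
  a <- chain$anchors
  ## trim anchor overlaps (slack) so gap coordinates are consistent
  if (nrow(a) > 1L) {
    for (i in 2:nrow(a)) {
      cut <- max(a$qend[i - 1L] - a$qstart[i] + 1L,
                 a$rend[i - 1L] - a$rstart[i] + 1L, 0L)
      if (cut > 0L) {
        a$qstart[i] <- a$qstart[i] + cut
        a$rstart[i] <- a$rstart[i] + cut
        a$len[i] <- a$len[i] - cut
      }
    }
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  rows <- list()
  emit <- function(pos, refA, altA) {
    if (pos < 1L) return(invisible(NULL))
    nv <- leftNormalize(as.integer(pos), refA, altA, ref)
    rows[[length(rows) + 1L]] <<- data.frame(pos = nv$pos, ref = nv$ref,
                                             alt = nv$alt,
                                             type = variantType(nv$ref, nv$alt))
  }
  gapPair <- function(q0, q1, r0, r1) {
    qgap <- if (q1 >= q0) substr(query, q0, q1) else ""
    rgap <- if (r1 >= r0) substr(ref, r0, r1) else ""
    if (nchar(qgap) == 0L && nchar(rgap) == 0L) return()
    if (nchar(rgap) == 0L) { # pure insertion, anchored at r0 - 1
      p <- r0 - 1L
      emit(p, substr(ref, p, p), paste0(substr(ref, p, p), qgap))
      return()
    }
    if (nchar(qgap) == 0L) { # pure deletion
      p <- r0 - 1L
      emit(p, paste0(substr(ref, p, p), rgap), substr(ref, p, p))
      return()
    }
    if (nchar(qgap) == nchar(rgap) && nchar(qgap) <= 3L) {
      ## small same-length gap: emit column mismatches directly
      qc <- strsplit(qgap, "")[[1]]; rc <- strsplit(rgap, "")[[1]]
      for (t in which(qc != rc)) emit(r0 + t - 1L, rc[t], qc[t])
      return()
    }
    al <- Biostrings::pairwiseAlignment(qgap, rgap, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 2, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    s <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    rpos <- r0 - 1L
    i <- 1L
    while (i <= length(p)) {
      if (p[i] != "-" && s[i] != "-") {
        rpos <- rpos + 1L
        if (p[i] != s[i]) emit(rpos, s[i], p[i])
        i <- i + 1L
      } else if (s[i] == "-") { # run of query-only bases: insertion
        j <- i
        while (j <= length(p) && s[j] == "-") j <- j + 1L
        ins <- paste(p[i:(j - 1L)], collapse = "")
        anchor <- max(rpos, 1L)
        emit(anchor, substr(ref, anchor, anchor),
             paste0(substr(ref, anchor, anchor), ins))
        i <- j
      } else {                  # run of reference-only bases: deletion
        j <- i
        while (j <= length(p) && p[j] == "-") j <- j + 1L
        del <- paste(s[i:(j - 1L)], collapse = "")
        anchor <- max(rpos, 1L)
        emit(anchor, paste0(substr(ref, anchor, anchor), del),
             substr(ref, anchor, anchor))
        rpos <- rpos + (j - i)
        i <- j
      }
    }
  }
  if (nrow(a) > 1L) {
    for (i in seq_len(nrow(a) - 1L)) {
      gapPair(a$qend[i] + 1L, a$qstart[i + 1L] - 1L,
              a$rend[i] + 1L, a$rstart[i + 1L] - 1L)
    }
  }
  if (length(rows) == 0L) return(emptyVariantTable()[, 1:4])
  out <- do.call(rbind, rows)
  out[order(out$pos), ]
}
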