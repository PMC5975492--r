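## Reference-guided merging of contigs, quadripartite-structure detection,
## and IRb completion from IRa.

#' Merge contigs from many assemblies into super contigs
#'
#' Contigs are anchored to the reference, oriented and ordered by their
#' implied reference start, then chained into super contigs: a contig is
#' merged into the growing consensus when its overlap with it is at least
#' `minOverlap` bases at `minOverlapIdentity` identity (overlap placement
#' comes from contig-vs-consensus anchors, so it is exact even when the
#' assembled genome carries indels relative to the reference).
#' Disagreements inside overlaps are resolved by per-column majority over
#' the contributing contigs; a tie falls back to the reference base at the
#' projected position (or the alphabetically first base when the
#' projection is unavailable). Contigs with contradictory orientations or
#' no reference anchors are excluded with a logged reason; merging never
#' introduces bases absent from every input contig except at tie columns.
#'
#' @param assemblies an [Assembly-class] or list of them.
#' @param reference a [QuadripartiteGenome-class] or DNA string guiding
#'   order and orientation.
#' @param minOverlap minimum merge overlap in bases (default 100; use
#'   `k - 1` when merging unitigs from a k-mer assembler).
#' @param minOverlapIdentity minimum overlap identity (default 0.99).
#' @param minAnchor minimum exact anchor length (default 20).
#' @return An [Assembly-class] of super contigs sorted by reference start;
#'   `provenance$excluded` logs dropped contigs.
#' @export
mergeContigs <- function(assemblies, reference, minOverlap = 100L,
                         minOverlapIdentity = 0.99, minAnchor = 20L) {
  ref <- genomeSeq(reference)
  if (is(assemblies, "Assembly")) assemblies <- list(assemblies)
  ctg <- unlist(lapply(assemblies, contigs))
  excluded <- character(0)
  placed <- list()
  for (i in seq_along(ctg)) {
    ch <- anchorContig(ctg[i], ref, minAnchor = minAnchor)
    if (is.null(ch)) {
      excluded <- c(excluded, sprintf("contig %d: no reference anchors", i))
      next
    }
    oc <- if (ch$strand == "+") ctg[i] else revComp(ctg[i])
    och <- if (ch$strand == "+") ch else anchorContig(oc, ref,
                                                      minAnchor = minAnchor)
    if (is.null(och) || och$strand != "+") {
      excluded <- c(excluded,
                    sprintf("contig %d: contradictory orientation", i))
      next
    }
    ## clip unanchored overhangs (e.g. the wrap-around tail a unitig of a
    ## circular genome carries past the reference origin)
    qlo <- min(och$anchors$qstart)
    qhi <- max(och$anchors$qend)
    oc <- substr(oc, qlo, qhi)
    placed[[length(placed) + 1L]] <-
      list(seq = oc, refStart = och$refStart,
           offset = och$anchors$rstart[1L] - (och$anchors$qstart[1L] - qlo + 1L) + 1L)
  }
  prov <- list(minOverlap = minOverlap,
               minOverlapIdentity = minOverlapIdentity, excluded = excluded)
  if (length(placed) == 0L)
    return(Assembly(character(0), runId = "merged", provenance = prov))
  ord <- order(vapply(placed, `[[`, numeric(1), "refStart"))
  placed <- placed[ord]

  supers <- list()
  cur <- NULL   # list(contribs = list of (offset, seq), len, refStart, offset)
  finalize <- function(cur) {
    .consensusColumns(cur, ref)
  }
  for (p in placed) {
    if (is.null(cur)) {
      cur <- list(contribs = list(list(offset = 1L, seq = p$seq)),
                  consensus = p$seq, refStart = p$refStart,
                  refOffset = p$offset)
      next
    }
    ## place the new contig against the current consensus
    ch <- anchorContig(p$seq, cur$consensus, minAnchor = minAnchor)
    merged <- FALSE
    if (!is.null(ch) && ch$strand == "+" && !is.na(ch$offset)) {
      o <- ch$offset
      ovl <- min(nchar(cur$consensus) - o + 1L, nchar(p$seq))
      if (o >= 1L && ovl >= minOverlap) {
        ident <- 1 - hammingDist(substr(cur$consensus, o, o + ovl - 1L),
                                 substr(p$seq, 1L, ovl)) / ovl
        if (ident >= minOverlapIdentity) {
          cur$contribs[[length(cur$contribs) + 1L]] <-
            list(offset = o, seq = p$seq)
          if (o + nchar(p$seq) - 1L > nchar(cur$consensus))
            cur$consensus <- paste0(cur$consensus,
                                    substr(p$seq, ovl + 1L, nchar(p$seq)))
          merged <- TRUE
        }
      }
    }
    if (!merged) {
      supers[[length(supers) + 1L]] <- finalize(cur)
      cur <- list(contribs = list(list(offset = 1L, seq = p$seq)),
                  consensus = p$seq, refStart = p$refStart,
                  refOffset = p$offset)
    }
  }
  supers[[length(supers) + 1L]] <- finalize(cur)
  Assembly(vapply(supers, identity, character(1)), runId = "merged",
           provenance = prov)
}

## majority-vote consensus over the contigs contributing to one super contig
.consensusColumns <- function(cur, ref) {
  if (length(cur$contribs) == 1L) return(cur$contribs[[1L]]$seq)
  offs <- vapply(cur$contribs, `[[`, integer(1), "offset")
  seqs <- vapply(cur$contribs, `[[`, character(1), "seq")
  lens <- nchar(seqs)
  total <- max(offs + lens - 1L)
  pos <- unlist(Map(function(o, l) seq.int(o, o + l - 1L), offs, lens))
  base <- unlist(strsplit(seqs, "", fixed = TRUE))
  dt <- data.table::data.table(pos = pos, base = base)
  dt <- dt[, list(n = .N), by = c("pos", "base")]
  data.table::setorderv(dt, c("pos", "n", "base"), order = c(1L, -1L, 1L))
  top <- dt[!duplicated(dt$pos)]
  ## detect ties at the top and fall back to the reference base
  maxN <- dt[, list(m = max(n), k = sum(n == max(n))), by = "pos"]
  tied <- maxN$pos[maxN$k > 1L]
  out <- character(total)
  out[top$pos] <- top$base
  if (length(tied) && !is.null(cur$refOffset) && !is.na(cur$refOffset)) {
    refPos <- cur$refOffset + tied - 1L
    ok <- refPos >= 1L & refPos <= nchar(ref)
    out[tied[ok]] <- substring(ref, refPos[ok], refPos[ok])
  }
  paste(out, collapse = "")
}

#' Detect the quadripartite structure of a chloroplast sequence
#'
#' Finds the maximal pair of disjoint intervals (X before Y) where the
#' reverse complement of `seq[Y]` matches `seq[X]` at high identity, calls
#' X = IRa and Y = IRb, and labels the longer of the two flanked
#' single-copy stretches LSC and the shorter SSC. On a circular sequence
#' the rotation placing the LSC first is canonical and the rotated genome
#' is returned; the assembled strand is kept as is (no flip
#' normalization).
#'
#' @param seq DNA string (or [QuadripartiteGenome-class], whose boundaries
#'   are ignored).
#' @param minIr minimum inverted-repeat length (default 1000; lower it for
#'   toy genomes).
#' @param minAnchor exact-match seed length for repeat finding (default 20).
#' @param circular treat the sequence as circular (default TRUE).
#' @return `NULL` when no inverted repeat of at least `minIr` bases exists
#'   (structure not found), else a `QuadripartiteCall` list: `genome` (the
#'   canonically rotated [QuadripartiteGenome-class]), `irLength`,
#'   `irIdentity`, `rotation` (bases the input was rotated left by).
#' @export
detectQuadripartite <- function(seq, minIr = 1000L, minAnchor = 20L,
                                circular = TRUE) {
  s <- genomeSeq(seq)
  L <- nchar(s)
  if (circular) {
    ## an IR copy may straddle the linearization origin; at most one of two
    ## half-turn rotations can be affected, so take the larger call
    half <- L %/% 2L
    sHalf <- paste0(substr(s, half + 1L, L), substr(s, 1L, half))
    b0 <- .bestInvertedPair(s, minAnchor)
    b1 <- .bestInvertedPair(sHalf, minAnchor)
    if (!is.null(b1) && (is.null(b0) || b1$len > b0$len)) {
      s <- sHalf
      best <- b1
      preRot <- half
    } else {
      best <- b0
      preRot <- 0L
    }
  } else {
    best <- .bestInvertedPair(s, minAnchor)
    preRot <- 0L
  }
  if (is.null(best) || best$len < minIr) return(NULL)
  ident <- min(1, best$matched / best$len)
  ## single-copy stretches: between X and Y, and wrapping around
  scMidLen <- best$y0 - best$x1 - 1L
  scWrapLen <- (L - best$y1) + (best$x0 - 1L)
  if (!circular) {
    ## linear input is reported in place (assumed LSC-IRa-SSC-IRb layout)
    g <- QuadripartiteGenome(s, lscEnd = max(best$x0 - 1L, 1L),
                             iraEnd = best$x1, sscEnd = best$y0 - 1L,
                             name = "quadripartite", circular = FALSE)
    return(structure(list(genome = g, irLength = best$len,
                          irIdentity = ident, rotation = 0L),
                     class = "QuadripartiteCall"))
  }
  if (scWrapLen >= scMidLen) {
    ## LSC wraps the origin: rotate so it starts at position 1
    rot <- best$y1 %% L # left-rotate by this many bases
    lscLen <- scWrapLen
  } else {
    ## LSC is the middle stretch: rotate so it starts at position 1
    rot <- best$x1 %% L
    lscLen <- scMidLen
  }
  rs <- if (rot == 0L) s else paste0(substr(s, rot + 1L, L),
                                     substr(s, 1L, rot))
  sscLen <- min(scMidLen, scWrapLen)
  g <- QuadripartiteGenome(rs, lscEnd = lscLen,
                           iraEnd = lscLen + best$len,
                           sscEnd = lscLen + best$len + sscLen,
                           name = "quadripartite", circular = TRUE)
  structure(list(genome = g, irLength = best$len, irIdentity = ident,
                 rotation = (preRot + rot) %% L),
            class = "QuadripartiteCall")
}

## the maximal-length pair of disjoint inverted-repeat intervals of s:
## "-" strand self-anchors merged along anti-diagonals (mismatch-split runs
## of one repeat share qstart + rend)
.bestInvertedPair <- function(s, minAnchor) {
  a <- findAnchors(s, s, minLen = minAnchor)
  a <- a[a$strand == "-" & a$qend < a$rstart, , drop = FALSE]
  if (nrow(a) == 0L) return(NULL)
  a$anti <- a$qstart + a$rend
  a <- a[order(a$anti, a$qstart), ]
  grp <- cumsum(c(TRUE, diff(a$anti) != 0L))
  best <- NULL
  for (g in unique(grp)) {
    ai <- a[grp == g, , drop = FALSE]
    x0 <- min(ai$qstart); x1 <- max(ai$qend)
    y0 <- min(ai$rstart); y1 <- max(ai$rend)
    len <- x1 - x0 + 1L
    if (x1 >= y0) next
    if (is.null(best) || len > best$len)
      best <- list(x0 = x0, x1 = x1, y0 = y0, y1 = y1, len = len,
                   matched = sum(ai$len))
  }
  best
}

#' @export
print.QuadripartiteCall <- function(x, ...) {
  cat(sprintf("QuadripartiteCall: IR %d bp at %.4f identity, rotation %d\n",
              x$irLength, x$irIdentity, x$rotation))
  show(x$genome)
  invisible(x)
}

#' Collect and merge contigs overlapping the reference IRb
#'
#' Selects, from all assemblies, the contigs whose anchor chain intersects
#' the reference IRb interval and merges them into the longest achievable
#' IRb-overlapping contig. Contigs that place only in IRa (the mapper's
#' leftmost tie-break for pure-IR sequence) are not selected.
#'
#' @param assemblies an [Assembly-class] or list of them.
#' @param reference a [QuadripartiteGenome-class] with known boundaries.
#' @param minAnchor minimum anchor length (default 20).
#' @param ... passed to [mergeContigs()] (e.g. `minOverlap`).
#' @return An [Assembly-class] (empty when no contig overlaps IRb).
#' @export
collectIrbContigs <- function(assemblies, reference, minAnchor = 20L, ...) {
  if (is(assemblies, "Assembly")) assemblies <- list(assemblies)
  ctg <- unlist(lapply(assemblies, contigs))
  irbStart <- sscEnd(reference) + 1L
  irbEnd <- length(reference)
  keep <- vapply(ctg, function(s) {
    ch <- anchorContig(s, genomeSeq(reference), minAnchor = minAnchor)
    !is.null(ch) && ch$refEnd >= irbStart && ch$refStart <= irbEnd
  }, logical(1))
  if (!any(keep))
    return(Assembly(character(0), runId = "irb"))
  mergeContigs(Assembly(unname(ctg[keep]), runId = "irb.in"), reference,
               minAnchor = minAnchor, ...)
}

#' Complete a partial IRb from the assembled IRa
#'
#' Takes a (linear) assembly covering LSC+IRa+SSC plus at most a partial
#' IRb, projects the reference region boundaries onto it through its
#' anchor chain, verifies that any assembled IRb prefix agrees with the
#' reverse complement of the assembled IRa at `minAgreement` identity, and
#' replaces the missing IRb bases with the reverse complement of the
#' corresponding IRa bases. Assembled IRb bases are kept; only the missing
#' stretch is inferred.
#'
#' @param partial DNA string (or [QuadripartiteGenome-class]) covering
#'   LSC+IRa+SSC and optionally part of IRb, in reference orientation.
#' @param reference a [QuadripartiteGenome-class] with known boundaries.
#' @param minAgreement minimum identity between the assembled IRb prefix
#'   and the IRa-implied sequence (default 0.995); conflicts above this
#'   refuse completion.
#' @param minAnchor minimum anchor length (default 20).
#' @param name name of the completed genome.
#' @return A circular [QuadripartiteGenome-class]; the attribute
#'   `completionReport` records the inferred interval.
#' @export
completeIrb <- function(partial, reference, minAgreement = 0.995,
                        minAnchor = 20L, name = "completed") {
  s <- genomeSeq(partial)
  ref <- genomeSeq(reference)
  ch <- anchorContig(s, ref, minAnchor = minAnchor)
  if (is.null(ch) || ch$strand != "+")
    stop("completion refused: partial assembly does not anchor to the ",
         "reference in forward orientation")
  bounds <- projectRefToQuery(ch, c(lscEnd(reference), iraEnd(reference),
                                    sscEnd(reference)))
  if (anyNA(bounds))
    stop("completion refused: IRa or SSC is not fully assembled ",
         "(reference boundaries not covered)")
  qLsc <- bounds[1L]; qIra <- bounds[2L]; qSsc <- bounds[3L]
  ira <- substr(s, qLsc + 1L, qIra)
  target <- revComp(ira)          # the full IRb implied by IRa
  tail <- if (qSsc < nchar(s)) substr(s, qSsc + 1L, nchar(s)) else ""
  nt <- nchar(tail)
  if (nt > nchar(target))
    stop("completion refused: assembled IRb longer than IRa")
  if (nt > 0L) {
    agree <- 1 - hammingDist(tail, substr(target, 1L, nt)) / nt
    if (agree < minAgreement)
      stop(sprintf(paste0("completion refused: assembled IRb bases %d-%d ",
                          "disagree with revcomp(IRa) (identity %.4f)"),
                   qSsc + 1L, qSsc + nt, agree))
  }
  completed <- paste0(substr(s, 1L, qSsc), tail,
                      substr(target, nt + 1L, nchar(target)))
  g <- QuadripartiteGenome(completed, lscEnd = qLsc, iraEnd = qIra,
                           sscEnd = qSsc, name = name, circular = TRUE)
  attr(g, "completionReport") <-
    data.frame(inferredStart = qSsc + nt + 1L,
               inferredEnd = nchar(completed),
               assembledIrb = nt, irLength = nchar(target))
  g
}
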