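## Lightweight k-mer seed-and-extend read mapper: cpDNA read extraction,
## mapping-ratio checks, per-base depth, and pileup input.

#' Build an exact-match seed index over a reference
#'
#' Indexes every canonical `seedK`-mer of the reference to its positions
#' and strands. Circular references are indexed over the sequence extended
#' by its own prefix so origin-spanning seeds (and reads) are found; all
#' reported positions stay in `1..length`.
#'
#' @param reference a [QuadripartiteGenome-class] or plain DNA string.
#' @param seedK seed k-mer size (default 21).
#' @param circular circularity for plain-string references.
#' @param pad length of the circular extension (must be at least the read
#'   length mapped against this index; default 300).
#' @param maxOcc seeds occurring more often than this in the reference are
#'   dropped (simple repeat masking).
#' @param refName reference name used in alignments.
#' @return A `SeedIndex` list.
#' @export
seedIndex <- function(reference, seedK = 21L, circular = NULL, pad = 300L,
                      maxOcc = 50L, refName = NULL) {
  seq <- genomeSeq(reference)
  if (is.null(circular))
    circular <- if (is(reference, "QuadripartiteGenome")) reference@circular else FALSE
  if (is.null(refName))
    refName <- if (is(reference, "QuadripartiteGenome")) genomeName(reference) else "ref"
  L <- nchar(seq)
  seedK <- as.integer(seedK)
  if (seedK > L) stop("seedK must not exceed the reference length")
  idxSeq <- if (circular) paste0(seq, substr(seq, 1L, min(pad, L))) else seq
  nStart <- if (circular) L else L - seedK + 1L
  starts <- seq_len(nStart)
  km <- substring(idxSeq, starts, starts + seedK - 1L)
  canon <- canonicalKmers(km)
  dt <- data.table::data.table(kmer = canon, pos = starts, fwd = km == canon)
  occ <- dt[, list(n = .N), by = "kmer"]
  dt <- dt[!occ[occ$n > maxOcc], on = "kmer"]
  data.table::setkeyv(dt, "kmer")
  structure(list(seeds = dt, seq = seq, idxSeq = idxSeq, L = L,
                 seedK = seedK, circular = circular, pad = min(pad, L),
                 refName = refName),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  cat(sprintf("SeedIndex: '%s', %d bp (%s), k=%d, %d seed positions\n",
              x$refName, x$L, if (x$circular) "circular" else "linear",
              x$seedK, nrow(x$seeds)))
  invisible(x)
}

## parse CIGAR strings into per-alignment op/length lists
.cigarParse <- function(cigars) {
  lens <- regmatches(cigars, gregexpr("[0-9]+", cigars))
  ops <- regmatches(cigars, gregexpr("[A-Z]", cigars))
  Map(function(l, o) list(len = as.integer(l), op = o), lens, ops)
}

## reference bases consumed by a CIGAR (M and D ops)
.cigarRefSpan <- function(cigars) {
  vapply(.cigarParse(cigars), function(p)
    sum(p$len[p$op %in% c("M", "D")]), integer(1))
}

## run-length encode alignment columns into a CIGAR; end insertions -> S
.alnToCigar <- function(patChars, subChars) {
  op <- ifelse(patChars == "-", "D", ifelse(subChars == "-", "I", "M"))
  r <- rle(op)
  if (r$values[1] == "I") r$values[1] <- "S"
  if (r$values[length(r$values)] == "I") r$values[length(r$values)] <- "S"
  paste0(r$lengths, r$values, collapse = "")
}

#' Map reads against a seed index
#'
#' Candidate loci are collected by seed voting (the best-voted
#' offset/strand wins; ties go to the leftmost reference position, then the
#' + strand). Candidates are scored by an ungapped comparison and, when
#' that fails, by banded gapped extension of the read against a reference
#' window (band +/- 10). A read is mapped iff its identity over aligned
#' bases is at least `minIdentity` across at least `minAlignedFrac` of the
#' read; unmapped is a value, not an error.
#'
#' @param reads character vector of read sequences (or a single read).
#' @param index a [seedIndex()].
#' @param minIdentity minimum identity over aligned read bases (default
#'   0.95, mirroring a 95%-identity screening threshold).
#' @param minAlignedFrac minimum fraction of the read aligned (default 0.9).
#' @param seedStep spacing between query seeds (default 5).
#' @return data.frame with one row per read: `readIdx`, `refName`,
#'   `refStart` (1-based), `strand`, `cigar`, `nMismatch`, `identity`,
#'   `mapped`, and `oseq` (the read in reference orientation).
#' @export
mapReads <- function(reads, index, minIdentity = 0.95,
                     minAlignedFrac = 0.9, seedStep = 5L) {
  stopifnot(inherits(index, "SeedIndex"))
  n <- length(reads)
  out <- data.frame(readIdx = seq_len(n), refName = index$refName,
                    refStart = NA_integer_, strand = NA_character_,
                    cigar = NA_character_, nMismatch = NA_integer_,
                    identity = NA_real_, mapped = FALSE,
                    oseq = NA_character_, stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  k <- index$seedK
  rl <- nchar(reads)
  if (any(rl < k)) stop("read length must be at least seedK")
  ## query seeds
  nSeed <- pmax((rl - k) %/% seedStep + 1L, 1L)
  ridx <- rep.int(seq_len(n), nSeed)
  j <- (sequence(nSeed) - 1L) * seedStep + 1L
  qkm <- substring(reads[ridx], j, j + k - 1L)
  qcan <- canonicalKmers(qkm)
  qdt <- data.table::data.table(read = ridx, j = j, rlen = rl[ridx],
                                kmer = qcan, qfwd = qkm == qcan)
  hits <- index$seeds[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits)) {
    same <- hits$fwd == hits$qfwd
    jeff <- ifelse(same, hits$j, hits$rlen - hits$j - k + 2L)
    off <- hits$pos - jeff + 1L
    if (index$circular) off <- ((off - 1L) %% index$L) + 1L
    strand <- ifelse(same, "+", "-")
    votes <- data.table::data.table(read = hits$read, strand = strand,
                                    off = off)[off >= 1L]
    votes <- votes[, list(nv = .N), by = c("read", "strand", "off")]
    data.table::setorderv(votes, c("read", "nv", "off", "strand"),
                          order = c(1L, -1L, 1L, 1L))
    best <- votes[!duplicated(votes$read)]
  } else {
    best <- data.table::data.table(read = integer(0), strand = character(0),
                                   off = integer(0), nv = integer(0))
  }
  if (nrow(best) == 0L) return(out)
  oseq <- ifelse(best$strand == "+", reads[best$read],
                 revComp(reads[best$read]))
  maxMM <- floor((1 - minIdentity) * rl[best$read])
  needSlow <- logical(nrow(best))
  idxLen <- nchar(index$idxSeq)
  for (i in seq_len(nrow(best))) {
    r <- best$read[i]; o <- best$off[i]; len <- rl[r]
    if (o + len - 1L <= idxLen) {
      refsub <- substr(index$idxSeq, o, o + len - 1L)
      mm <- hammingDist(oseq[i], refsub)
      if (mm <= maxMM[i]) {
        out$refStart[r] <- o
        out$strand[r] <- best$strand[i]
        out$cigar[r] <- paste0(len, "M")
        out$nMismatch[r] <- mm
        out$identity[r] <- 1 - mm / len
        out$mapped[r] <- TRUE
        out$oseq[r] <- oseq[i]
        next
      }
    }
    needSlow[i] <- TRUE
  }
  ## gapped extension for the remainder
  slow <- which(needSlow)
  if (length(slow)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    for (i in slow) {
      r <- best$read[i]; o <- best$off[i]; len <- rl[r]
      ws <- max(1L, o - 10L)
      we <- min(idxLen, o + len + 9L)
      win <- substr(index$idxSeq, ws, we)
      al <- Biostrings::pairwiseAlignment(oseq[i], win,
                                          type = "global-local",
                                          substitutionMatrix = mat,
                                          gapOpening = 4, gapExtension = 1)
      p <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
      s <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
      nmatch <- sum(p == s & p != "-")
      nmism <- sum(p != s & p != "-" & s != "-")
      alnFrac <- (nmatch + nmism) / len
      ident <- if (nmatch + nmism > 0) nmatch / (nmatch + nmism) else 0
      out$oseq[r] <- oseq[i]
      out$strand[r] <- best$strand[i]
      if (ident >= minIdentity && alnFrac >= minAlignedFrac) {
        subStart <- ws + Biostrings::start(Biostrings::subject(al)) - 1L
        out$refStart[r] <- subStart
        out$cigar[r] <- .alnToCigar(p, s)
        out$nMismatch[r] <- nmism
        out$identity[r] <- ident
        out$mapped[r] <- TRUE
      } else {
        out$identity[r] <- ident
      }
    }
  }
  out
}

#' @rdname mapReads
#' @param read a single read sequence.
#' @export
mapRead <- function(read, index, minIdentity = 0.95, minAlignedFrac = 0.9,
                    seedStep = 5L) {
  mapReads(read, index, minIdentity = minIdentity,
           minAlignedFrac = minAlignedFrac, seedStep = seedStep)[1, ]
}

#' Map both mates of a read dataset
#'
#' @param dataset a [ReadDataset-class].
#' @param index a [seedIndex()].
#' @param ... passed to [mapReads()].
#' @return data.frame of alignments for all mates, with columns `readId`
#'   (`pairId/1` or `/2`), `pair` (pair index) and `mate` in addition to
#'   the [mapReads()] columns.
#' @export
mapDataset <- function(dataset, index, ...) {
  n <- length(dataset)
  a1 <- mapReads(dataset@read1, index, ...)
  a2 <- mapReads(dataset@read2, index, ...)
  a1$readId <- paste0(dataset@pairId, "/1")
  a2$readId <- paste0(dataset@pairId, "/2")
  a1$pair <- seq_len(n); a2$pair <- seq_len(n)
  a1$mate <- 1L; a2$mate <- 2L
  rbind(a1, a2)
}

#' Extract chloroplast read pairs from a whole-genome dataset
#'
#' Maps both mates against the chloroplast reference index and retains
#' pairs with at least one mapped mate (`mode = "either"`, the default) or
#' both mates mapped (`mode = "both"`).
#'
#' @param dataset a [ReadDataset-class].
#' @param index a [seedIndex()] over the chloroplast reference.
#' @param mode `"either"` or `"both"`.
#' @param ... passed to [mapReads()].
#' @return list with `dataset` (the retained pairs), `ratio` (retained /
#'   input pairs; 0 with a warning for empty input) and `keep` (logical per
#'   input pair).
#' @export
extractCpReads <- function(dataset, index, mode = c("either", "both"), ...) {
  mode <- match.arg(mode)
  n <- length(dataset)
  if (n == 0L) {
    warning("empty dataset: extraction ratio reported as 0")
    return(list(dataset = dataset, ratio = 0, keep = logical(0)))
  }
  m1 <- mapReads(dataset@read1, index, ...)$mapped
  m2 <- mapReads(dataset@read2, index, ...)$mapped
  keep <- if (mode == "either") m1 | m2 else m1 & m2
  list(dataset = dataset[keep], ratio = mean(keep), keep = keep)
}

#' Per-base depth profile from alignments
#'
#' Counts, for every reference base, the reads whose aligned span (M and D
#' CIGAR operations) covers it. Alignments on a circular reference may wrap
#' the origin; on a linear reference an alignment beyond the end is an
#' error. Adjacent zero-coverage positions are merged into gap intervals.
#'
#' @param alignments data.frame from [mapReads()]/[mapDataset()] (unmapped
#'   rows are ignored).
#' @param refLength reference length in bases.
#' @param circular whether the reference is circular.
#' @return A `DepthProfile` list: `depth` (integer vector of length
#'   `refLength`), `min`, `mean`, `max`, and `zeroIntervals`
#'   (data.frame `start`, `end`, 1-based inclusive).
#' @export
depthProfile <- function(alignments, refLength, circular = TRUE) {
  refLength <- as.integer(refLength)
  aln <- alignments[alignments$mapped %in% TRUE, , drop = FALSE]
  if (nrow(aln)) {
    span <- .cigarRefSpan(aln$cigar)
    start <- aln$refStart
    end <- start + span - 1L
    if (!circular && any(end > refLength))
      stop("alignment extends beyond the end of a linear reference")
    wrap <- end > refLength
    ir <- IRanges::IRanges(start = c(start, rep(1L, sum(wrap))),
                           end = c(pmin(end, refLength),
                                   end[wrap] - refLength))
    cov <- IRanges::coverage(ir, width = refLength)
    depth <- as.integer(cov)
  } else {
    depth <- integer(refLength)
  }
  zero <- IRanges::slice(S4Vectors::Rle(as.integer(depth == 0L)), lower = 1L,
                         rangesOnly = TRUE)
  structure(list(depth = depth, min = min(depth), mean = mean(depth),
                 max = max(depth),
                 zeroIntervals = data.frame(start = IRanges::start(zero),
                                            end = IRanges::end(zero))),
            class = "DepthProfile")
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat(sprintf("DepthProfile: %d bp, depth min/mean/max = %d/%.1f/%d, %d gap(s)\n",
              length(x$depth), x$min, x$mean, x$max, nrow(x$zeroIntervals)))
  invisible(x)
}
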