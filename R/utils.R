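## Internal helpers shared across modules.

#' @import methods
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils head tail write.table
#' @importFrom data.table := .N data.table setkeyv setorderv rbindlist
NULL

.datatable.aware <- TRUE

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Reverse complement of a character vector of DNA strings
#' @noRd
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

## scalar reverse complement without Biostrings object overhead (hot loops)
rcScalar <- function(s) {
  ch <- strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]
  paste(rev(ch), collapse = "")
}

#' Random DNA string at a given GC fraction
#' @noRd
randomSeq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' All k-mers of a character vector of sequences (one flat vector)
#' @noRd
allKmers <- function(seqs, k) {
  L <- nchar(seqs)
  nk <- pmax(L - k + 1L, 0L)
  if (sum(nk) == 0L) return(character(0))
  idx <- rep.int(seq_along(seqs), nk)
  starts <- sequence(nk)
  substring(seqs[idx], starts, starts + k - 1L)
}

#' Canonical form (lexicographic min of k-mer and reverse complement)
#' @noRd
canonicalKmers <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- revComp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Count canonical k-mers of sequences; drops k-mers with non-ACGT symbols
#' @noRd
countCanonicalKmers <- function(seqs, k) {
  km <- allKmers(seqs, k)
  if (length(km) == 0L)
    return(data.table::data.table(kmer = character(0), count = integer(0)))
  bad <- grepl("[^ACGT]", km)
  if (any(bad)) km <- km[!bad]
  can <- canonicalKmers(km)
  dt <- data.table::data.table(kmer = can)
  dt <- dt[, list(count = .N), by = "kmer"]
  data.table::setkeyv(dt, "kmer")
  dt
}

#' Phred+33 decode
#' @noRd
decodeQuals <- function(q) lapply(q, function(s) utf8ToInt(s) - 33L)

#' Hamming distance of two equal-length strings (fast raw comparison)
#' @noRd
hammingDist <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Extract a substring from a circular sequence (1-based, may wrap)
#' @noRd
circularSubstr <- function(seq, start, len) {
  L <- nchar(seq)
  start <- ((start - 1L) %% L) + 1L
  if (start + len - 1L <= L) return(substr(seq, start, start + len - 1L))
  paste0(substr(seq, start, L), substr(seq, 1L, start + len - 1L - L))
}

#' Longest homopolymer run overlapping positions [from, to] of seq
#' @noRd
maxHomopolymerAt <- function(seq, from, to, flank = 10L) {
  a <- max(1L, from - flank)
  b <- min(nchar(seq), to + flank)
  win <- substr(seq, a, b)
  r <- rle(strsplit(win, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths) + a - 1L
  starts <- ends - r$lengths + 1L
  hit <- which(ends >= from & starts <= to)
  if (length(hit) == 0L) return(0L)
  max(r$lengths[hit])
}

#' Shannon entropy (bits) of overlapping dinucleotides in a window
#' @noRd
dinucEntropy <- function(win) {
  n <- nchar(win)
  if (n < 2L) return(0)
  d <- substring(win, 1:(n - 1L), 2:n)
  p <- table(d) / length(d)
  -sum(p * log2(p))
}

#' Left-align and trim an anchored variant against the reference sequence
#'
#' Standard variant normalization: trim shared trailing bases, extend left
#' when an allele empties, then trim shared leading bases. Alleles must be
#' anchored (share their first base) on entry for indels.
#' @noRd
leftNormalize <- function(pos, ref, alt, refseq) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1L || na > 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) { # cannot extend left of the sequence
          base <- substr(refseq, pos, pos)
          ref <- paste0(ref, base); alt <- paste0(alt, base)
          break
        }
        pos <- pos - 1L
        base <- substr(refseq, pos, pos)
        ref <- paste0(base, ref)
        alt <- paste0(base, alt)
      }
      next
    }
    break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Variant type from normalized alleles
#' @noRd
variantType <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' Empty variant table with the canonical columns
#' @noRd
emptyVariantTable <- function() {
  data.frame(pos = integer(0), ref = character(0), alt = character(0),
             type = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
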