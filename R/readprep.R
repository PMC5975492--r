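## Read QC analogs: end trimming, exact duplicate-pair removal, k-mer
## spectra, and k-mer-based genome-size estimation.

#' Trim low-quality 3' ends from a paired read dataset
#'
#' Each read is truncated by removing the maximal 3' run of bases with
#' quality below `qualityThreshold` (FASTX-style end trimming). Pairs where
#' either trimmed mate falls below `minLength` are dropped as a pair.
#'
#' @param dataset a [ReadDataset-class].
#' @param qualityThreshold Phred score below which trailing bases are
#'   trimmed (default 20).
#' @param minLength minimum surviving mate length (default 30).
#' @return A trimmed [ReadDataset-class]; never more pairs than the input.
#' @export
trimLowQualityEnds <- function(dataset, qualityThreshold = 20L,
                               minLength = 30L) {
  n <- length(dataset)
  if (n == 0L) return(dataset)
  keepLen <- function(quals) {
    vapply(decodeQuals(quals), function(q) {
      ok <- which(q >= qualityThreshold)
      if (length(ok) == 0L) 0L else max(ok)
    }, integer(1))
  }
  l1 <- keepLen(dataset@qual1)
  l2 <- keepLen(dataset@qual2)
  keep <- l1 >= minLength & l2 >= minLength
  out <- dataset[keep]
  out@read1 <- substr(out@read1, 1L, l1[keep])
  out@qual1 <- substr(out@qual1, 1L, l1[keep])
  out@read2 <- substr(out@read2, 1L, l2[keep])
  out@qual2 <- substr(out@qual2, 1L, l2[keep])
  validObject(out)
  out
}

#' Remove exact duplicate read pairs
#'
#' A pair is a duplicate of another iff both mate sequences are identical
#' (FastUniq semantics: sequence identity, not alignment position). One
#' representative (the first seen) is retained. Idempotent.
#'
#' @param dataset a [ReadDataset-class].
#' @return list with `dataset` (deduplicated [ReadDataset-class]) and
#'   `duplicateFraction` (removed pairs / input pairs; 0 for empty input).
#' @export
dedupPairs <- function(dataset) {
  n <- length(dataset)
  if (n == 0L) return(list(dataset = dataset, duplicateFraction = 0))
  key <- paste(dataset@read1, dataset@read2, sep = "\r")
  dup <- duplicated(key)
  list(dataset = dataset[!dup], duplicateFraction = mean(dup))
}

#' Canonical k-mer multiplicity histogram of a read dataset
#'
#' Counts canonical k-mers (lexicographic minimum of each k-mer and its
#' reverse complement) over both mates and tabulates how many distinct
#' k-mers occur at each multiplicity. k-mers containing non-ACGT symbols
#' are skipped. Strand canonicalization is what lets the two inverted
#' repeat copies collapse onto the same k-mers.
#'
#' @param dataset a [ReadDataset-class], or a character vector of sequences.
#' @param k odd k-mer size, at most the read length.
#' @return A `KmerHistogram` list: `k`, `counts` (named integer vector,
#'   multiplicity -> number of distinct canonical k-mers), `nDistinct`,
#'   `totalInstances`.
#' @export
kmerHistogram <- function(dataset, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  seqs <- if (is(dataset, "ReadDataset")) {
    if (k > dataset@readLength) stop("k must not exceed the read length")
    c(dataset@read1, dataset@read2)
  } else as.character(dataset)
  counts <- countCanonicalKmers(seqs, k)
  tab <- table(counts$count)
  structure(list(k = k,
                 counts = setNames(as.integer(tab), names(tab)),
                 nDistinct = nrow(counts),
                 totalInstances = sum(counts$count)),
            class = "KmerHistogram")
}

#' @export
print.KmerHistogram <- function(x, ...) {
  cat(sprintf("KmerHistogram: k=%d, %d distinct canonical k-mers, %d instances\n",
              x$k, x$nDistinct, x$totalInstances))
  invisible(x)
}

#' Estimate genome size from a k-mer spectrum
#'
#' Separates the sequencing-error mode (the low-multiplicity spike) from the
#' genomic component at the first local minimum of the dense spectrum (the
#' "error valley"; ties broken toward lower multiplicity), then estimates
#' genome size as the number of distinct canonical k-mers above the valley
#' -- the distinct-genomic-k-mer estimate a k-mer spectrum model converges
#' to. Because the two inverted repeats share canonical k-mers, a genome
#' with two (near-)identical IR copies is estimated at its collapsed size
#' `total length - one IR`, i.e. LSC+IRa+SSC.
#'
#' @param hist a [kmerHistogram()] result.
#' @return A `SizeEstimate` list: `estimatedSize` (bases), `kUsed`,
#'   `coveragePeak` (modal multiplicity of the genomic component),
#'   `errorValley`.
#' @export
estimateGenomeSize <- function(hist) {
  stopifnot(inherits(hist, "KmerHistogram"))
  mult <- as.integer(names(hist$counts))
  if (length(mult) == 0L) stop("empty k-mer histogram: estimation failed")
  M <- max(mult)
  h <- integer(M)
  h[mult] <- hist$counts
  valley <- 0L
  if (M >= 2L && h[1L] > h[2L]) { # an error mode exists; find its valley
    valley <- NA_integer_
    for (m in seq_len(M - 1L)) {
      if (h[m + 1L] > h[m]) { valley <- m; break }
    }
    if (is.na(valley))
      stop("no coverage peak separable from the error mode: estimation failed")
  }
  genomic <- (valley + 1L):M
  peak <- genomic[which.max(h[genomic])]
  est <- sum(h[genomic])
  if (est <= 0L) stop("no k-mers above the error valley: estimation failed")
  structure(list(estimatedSize = est, kUsed = hist$k, coveragePeak = peak,
                 errorValley = valley),
            class = "SizeEstimate")
}

#' @export
print.SizeEstimate <- function(x, ...) {
  cat(sprintf("SizeEstimate: %d bp (k=%d, coverage peak %d, error valley %d)\n",
              x$estimatedSize, x$kUsed, x$coveragePeak, x$errorValley))
  invisible(x)
}
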