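## On-disk formats: FASTA/FASTQ via Biostrings; SAM, BED/BEDGRAPH, TSV and
## VCF 4.2 as plain text. Coordinates are 1-based inclusive everywhere in
## memory; 0-based half-open conversions happen only inside BED emission.

#' Write a genome (or any named sequences) as FASTA (60-char lines)
#'
#' @param x a [QuadripartiteGenome-class], [Assembly-class], or named
#'   character vector.
#' @param path output file.
#' @export
writeFasta <- function(x, path) {
  seqs <- if (is(x, "QuadripartiteGenome")) {
    setNames(genomeSeq(x), genomeName(x))
  } else if (is(x, "Assembly")) {
    setNames(contigs(x), paste0(runId(x), ".", seq_along(contigs(x))))
  } else as.character(x)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 60L)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write a read dataset as a pair of FASTQ files
#'
#' @param dataset a [ReadDataset-class].
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with read ids suffixed `/1` and `/2`.
#' @return the two paths, invisibly.
#' @export
writeReadsFastq <- function(dataset, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    s <- Biostrings::DNAStringSet(readSeqs(dataset, m))
    names(s) <- paste0(dataset@pairId, "/", m)
    Biostrings::writeXStringSet(s, paths[m], format = "fastq",
                                qualities =
                                  Biostrings::BStringSet(readQuals(dataset, m)))
  }
  invisible(paths)
}

#' Read a pair of FASTQ files into a ReadDataset
#'
#' @param path1,path2 mate FASTQ files.
#' @param datasetId dataset label.
#' @return A [ReadDataset-class].
#' @export
readReadsFastq <- function(path1, path2, datasetId = "reads") {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                     with.qualities = TRUE)
  ReadDataset(as.character(r1), as.character(r2),
              qual1 = as.character(S4Vectors::mcols(r1)$qualities),
              qual2 = as.character(S4Vectors::mcols(r2)$qualities),
              pairId = sub("/[12]$", "", names(r1)),
              datasetId = datasetId)
}

#' Write alignments as plain-text SAM (minimal mandatory columns)
#'
#' @param alignments data.frame from [mapReads()]/[mapDataset()].
#' @param refName,refLength reference name and length for the header.
#' @param path output file.
#' @export
writeSam <- function(alignments, refName, refLength, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", refName, as.integer(refLength))),
             con)
  qname <- if (!is.null(alignments$readId)) alignments$readId
           else paste0("read", alignments$readIdx)
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    if (isTRUE(a$mapped)) {
      flag <- if (a$strand == "-") 16L else 0L
      writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                         qname[i], flag, refName, a$refStart, a$cigar,
                         a$oseq, a$nMismatch), con)
    } else {
      writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", qname[i]), con)
    }
  }
  invisible(path)
}

#' Write a depth profile as BEDGRAPH
#'
#' @param profile a [depthProfile()] result.
#' @param refName reference name.
#' @param path output file.
#' @export
writeDepthBedgraph <- function(profile, refName, path) {
  r <- rle(profile$depth)
  end <- cumsum(r$lengths)
  start0 <- c(0L, end[-length(end)])
  write.table(data.frame(refName, start0, end, r$values), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data.frame with 1-based inclusive `start`, `end`.
#' @param refName reference name.
#' @param path output file.
#' @param names optional feature names.
#' @export
writeBed <- function(intervals, refName, path, names = NULL) {
  df <- data.frame(refName, intervals$start - 1L, intervals$end)
  if (!is.null(names)) df$name <- names
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write region boundaries of a genome as BED
#'
#' @param genome a [QuadripartiteGenome-class].
#' @param path output file.
#' @export
writeRegionsBed <- function(genome, path) {
  rt <- regionTable(genome)
  writeBed(rt, genomeName(genome), path, names = rt$region)
}

#' Write a unified variant table as VCF 4.2
#'
#' One sample column per clone; INFO keys `SRC` (strategies), `REGION`,
#' `EFF` and `FLAGS`. Genotypes are haploid 0/1/`.`.
#'
#' @param variants unified variant table (see [integrateVariants()],
#'   optionally [annotateVariants()]).
#' @param refName reference name.
#' @param path output file.
#' @param source tool tag in the header.
#' @export
writeVariantsVcf <- function(variants, refName, path,
                             source = "chlorotrace") {
  gtCols <- grep("^gt_", names(variants), value = TRUE)
  clones <- sub("^gt_", "", gtCols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=%s", source),
               "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Calling strategies\">",
               "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Quadripartite region\">",
               "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect\">",
               "##INFO=<ID=FLAGS,Number=1,Type=String,Description=\"Context flags\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", clones), collapse = "\t")), con)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- c(sprintf("SRC=%s", gsub(",", "&", v$source %||% ".")),
              if (!is.null(v$region)) sprintf("REGION=%s", v$region),
              if (!is.null(v$effect)) sprintf("EFF=%s", v$effect),
              if (!is.null(v$flags) && nzchar(v$flags))
                sprintf("FLAGS=%s", gsub(",", "&", v$flags)))
    gts <- vapply(gtCols, function(g) {
      a <- v[[g]]
      if (is.na(a)) "." else if (a == v$ref) "0" else "1"
    }, character(1))
    writeLines(paste(c(refName, v$pos, ".", v$ref, v$alt, ".", "PASS",
                       paste(info, collapse = ";"), "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a variant table as TSV
#'
#' Columns: position, reference base, alternative base, type coded as
#' Replace/Insert/Delete, then one genotype column per clone.
#'
#' @param variants unified variant table.
#' @param path output file.
#' @export
writeVariantsTsv <- function(variants, path) {
  gtCols <- grep("^gt_", names(variants), value = TRUE)
  out <- data.frame(position = variants$pos, reference = variants$ref,
                    alternative = variants$alt,
                    type = c(SNP = "Replace", insertion = "Insert",
                             deletion = "Delete")[variants$type])
  for (g in gtCols) out[[sub("^gt_", "", g)]] <- variants[[g]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a k-mer histogram as two-column TSV (multiplicity, count)
#'
#' @param hist a [kmerHistogram()] result.
#' @param path output file.
#' @export
writeKmerHistogram <- function(hist, path) {
  write.table(data.frame(multiplicity = as.integer(names(hist$counts)),
                         count = hist$counts), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
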