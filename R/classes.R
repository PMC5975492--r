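## S4 containers: QuadripartiteGenome, ReadDataset, Assembly.

#' QuadripartiteGenome: a circular plastome with annotated region boundaries
#'
#' The central coordinate frame of the package. A chloroplast genome is a
#' circular DNA molecule laid out as large single-copy region (LSC),
#' inverted repeat A (IRa), small single-copy region (SSC) and inverted
#' repeat B (IRb), where IRb is (near-)identical to the reverse complement
#' of IRa. All coordinates are 1-based inclusive; `lscEnd < iraEnd < sscEnd`
#' and IRb runs from `sscEnd + 1` to the sequence end.
#'
#' @slot name character label.
#' @slot sequence DNA string over A/C/G/T.
#' @slot lscEnd,iraEnd,sscEnd integer 1-based inclusive end coordinates of
#'   the LSC, IRa and SSC regions.
#' @slot circular logical, whether the molecule is circular.
#'
#' @examples
#' g <- buildGenome(1000, 300, 200, seed = 7)
#' g
#' regionTable(g)
#' @export
setClass("QuadripartiteGenome",
         representation(name = "character", sequence = "character",
                        lscEnd = "integer", iraEnd = "integer",
                        sscEnd = "integer", circular = "logical"))

setValidity("QuadripartiteGenome", function(object) {
  s <- object@sequence
  if (length(s) != 1L) return("sequence must be a single string")
  if (grepl("[^ACGT]", s)) return("sequence contains non-ACGT symbols")
  L <- nchar(s)
  a <- object@lscEnd; b <- object@iraEnd; c <- object@sscEnd
  if (!(1L <= a && a < b && b < c && c < L))
    return("region boundaries must satisfy 1 <= lscEnd < iraEnd < sscEnd < length")
  TRUE
})

#' Construct a QuadripartiteGenome from a sequence and boundaries
#'
#' @param sequence DNA string.
#' @param lscEnd,iraEnd,sscEnd 1-based inclusive region end coordinates.
#' @param name label.
#' @param circular logical.
#' @return A [QuadripartiteGenome-class] object.
#' @export
QuadripartiteGenome <- function(sequence, lscEnd, iraEnd, sscEnd,
                                name = "genome", circular = TRUE) {
  new("QuadripartiteGenome", name = name, sequence = sequence,
      lscEnd = as.integer(lscEnd), iraEnd = as.integer(iraEnd),
      sscEnd = as.integer(sscEnd), circular = circular)
}

#' @describeIn QuadripartiteGenome-class genome sequence as a character string
#' @param x,object a `QuadripartiteGenome`.
#' @export
genomeSeq <- function(x) {
  if (is(x, "QuadripartiteGenome")) x@sequence else as.character(x)
}

#' @describeIn QuadripartiteGenome-class genome name
#' @export
genomeName <- function(x) x@name

#' Region boundary accessors
#'
#' @param x a `QuadripartiteGenome`.
#' @return `lscEnd`, `iraEnd`, `sscEnd` return the 1-based inclusive end
#'   coordinate of the LSC, IRa and SSC regions; `irLength` the inverted
#'   repeat length.
#' @name region-accessors
#' @export
lscEnd <- function(x) x@lscEnd

#' @rdname region-accessors
#' @export
iraEnd <- function(x) x@iraEnd

#' @rdname region-accessors
#' @export
sscEnd <- function(x) x@sscEnd

#' @rdname region-accessors
#' @export
irLength <- function(x) x@iraEnd - x@lscEnd

#' @export
setMethod("length", "QuadripartiteGenome", function(x) nchar(x@sequence))

#' Table of region intervals of a quadripartite genome
#'
#' @param x a `QuadripartiteGenome`.
#' @return data.frame with columns `region`, `start`, `end`, `length`.
#' @export
regionTable <- function(x) {
  L <- length(x)
  data.frame(region = c("LSC", "IRa", "SSC", "IRb"),
             start = c(1L, x@lscEnd + 1L, x@iraEnd + 1L, x@sscEnd + 1L),
             end = c(x@lscEnd, x@iraEnd, x@sscEnd, L),
             length = c(x@lscEnd, x@iraEnd - x@lscEnd, x@sscEnd - x@iraEnd,
                        L - x@sscEnd),
             stringsAsFactors = FALSE)
}

#' Region label of positions on a quadripartite genome
#'
#' @param x a `QuadripartiteGenome` (or the quadripartite call of one).
#' @param pos integer vector of 1-based positions.
#' @return character vector over LSC/IRa/SSC/IRb.
#' @export
regionOf <- function(x, pos) {
  cut(pos, breaks = c(0L, x@lscEnd, x@iraEnd, x@sscEnd, length(x)),
      labels = c("LSC", "IRa", "SSC", "IRb")) |> as.character()
}

#' Identity between IRb and the reverse complement of IRa
#'
#' @param x a `QuadripartiteGenome`.
#' @return fraction in \[0, 1\] (computed over the shorter of the two when
#'   lengths differ).
#' @export
irIdentity <- function(x) {
  ira <- substr(x@sequence, x@lscEnd + 1L, x@iraEnd)
  irb <- substr(x@sequence, x@sscEnd + 1L, length(x))
  rc <- revComp(ira)
  n <- min(nchar(rc), nchar(irb))
  if (n == 0L) return(NA_real_)
  1 - hammingDist(substr(rc, 1L, n), substr(irb, 1L, n)) / n
}

setMethod("show", "QuadripartiteGenome", function(object) {
  rt <- regionTable(object)
  cat(sprintf("QuadripartiteGenome '%s': %d bp (%s)\n", object@name,
              length(object), if (object@circular) "circular" else "linear"))
  cat(sprintf("  %s\n", paste(sprintf("%s %d-%d (%d bp)", rt$region,
                                      rt$start, rt$end, rt$length),
                              collapse = ", ")))
  cat(sprintf("  IRb vs revcomp(IRa) identity: %.4f\n", irIdentity(object)))
})

## ---------------------------------------------------------------------------

#' ReadDataset: paired-end reads from one sequencing pass
#'
#' A named collection of Illumina-like read pairs. Mates are stored as
#' parallel character vectors; qualities are Phred+33 strings of the same
#' length as their reads. The `meta` slot carries simulator provenance
#' (fragment origins) when the dataset was generated in silico.
#'
#' @slot datasetId text label, e.g. `"offspring.Set1"`.
#' @slot read1,read2 character vectors of mate sequences.
#' @slot qual1,qual2 character vectors of Phred+33 quality strings.
#' @slot pairId character vector of pair identifiers.
#' @slot readLength nominal read length (before trimming).
#' @slot insertMean,insertSd insert-size model in bases.
#' @slot errorRate per-base substitution probability used in simulation.
#' @slot duplicateRate fraction of pairs emitted twice in simulation.
#' @slot meta list of provenance (e.g. `origin` data.frame).
#' @export
setClass("ReadDataset",
         representation(datasetId = "character",
                        read1 = "character", qual1 = "character",
                        read2 = "character", qual2 = "character",
                        pairId = "character", readLength = "integer",
                        insertMean = "numeric", insertSd = "numeric",
                        errorRate = "numeric", duplicateRate = "numeric",
                        meta = "list"))

setValidity("ReadDataset", function(object) {
  n <- length(object@read1)
  if (length(object@read2) != n || length(object@qual1) != n ||
      length(object@qual2) != n || length(object@pairId) != n)
    return("read1/read2/qual1/qual2/pairId must have equal length")
  if (n > 0L && (any(nchar(object@qual1) != nchar(object@read1)) ||
                 any(nchar(object@qual2) != nchar(object@read2))))
    return("qualities must have the same length as their sequences")
  if (object@errorRate < 0 || object@errorRate > 1 ||
      object@duplicateRate < 0 || object@duplicateRate > 1)
    return("errorRate and duplicateRate must be in [0, 1]")
  TRUE
})

#' Construct a ReadDataset from parallel vectors
#' @param read1,read2,qual1,qual2,pairId parallel vectors (qualities default
#'   to uniform Phred 35).
#' @param datasetId label.
#' @param readLength nominal read length; inferred from `read1` if missing.
#' @param insertMean,insertSd,errorRate,duplicateRate simulation metadata.
#' @param meta provenance list.
#' @return A [ReadDataset-class].
#' @export
ReadDataset <- function(read1, read2, qual1 = NULL, qual2 = NULL,
                        pairId = NULL, datasetId = "reads",
                        readLength = NULL, insertMean = NA_real_,
                        insertSd = NA_real_, errorRate = 0,
                        duplicateRate = 0, meta = list()) {
  n <- length(read1)
  if (is.null(qual1)) qual1 <- strrep("D", nchar(read1))
  if (is.null(qual2)) qual2 <- strrep("D", nchar(read2))
  if (is.null(pairId)) pairId <- if (n) paste0(datasetId, ".", seq_len(n)) else character(0)
  if (is.null(readLength))
    readLength <- if (n) as.integer(max(nchar(read1))) else 0L
  new("ReadDataset", datasetId = datasetId, read1 = read1, qual1 = qual1,
      read2 = read2, qual2 = qual2, pairId = pairId,
      readLength = as.integer(readLength), insertMean = insertMean,
      insertSd = insertSd, errorRate = errorRate,
      duplicateRate = duplicateRate, meta = meta)
}

#' @export
setMethod("length", "ReadDataset", function(x) length(x@read1))

#' Number of read pairs in a dataset
#' @param x a `ReadDataset`.
#' @export
nPairs <- function(x) length(x@read1)

#' Dataset identifier
#' @param x a `ReadDataset`.
#' @export
datasetId <- function(x) x@datasetId

#' Mate sequences of a read dataset
#' @param x a `ReadDataset`.
#' @param mate 1 or 2.
#' @export
readSeqs <- function(x, mate = 1L) if (mate == 1L) x@read1 else x@read2

#' Mate qualities of a read dataset (Phred+33 strings)
#' @param x a `ReadDataset`.
#' @param mate 1 or 2.
#' @export
readQuals <- function(x, mate = 1L) if (mate == 1L) x@qual1 else x@qual2

setMethod("show", "ReadDataset", function(object) {
  cat(sprintf("ReadDataset '%s': %d pairs, read length %d\n",
              object@datasetId, length(object), object@readLength))
})

#' Subset a read dataset by pair index
#' @param x a `ReadDataset`; `i` integer/logical index of pairs.
#' @param i pair index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ReadDataset", function(x, i, j, ..., drop = FALSE) {
  meta <- x@meta
  if (!is.null(meta$origin)) meta$origin <- meta$origin[i, , drop = FALSE]
  new("ReadDataset", datasetId = x@datasetId,
      read1 = x@read1[i], qual1 = x@qual1[i],
      read2 = x@read2[i], qual2 = x@qual2[i], pairId = x@pairId[i],
      readLength = x@readLength, insertMean = x@insertMean,
      insertSd = x@insertSd, errorRate = x@errorRate,
      duplicateRate = x@duplicateRate, meta = meta)
})

## ---------------------------------------------------------------------------

#' Assembly: contigs from one assembler run
#'
#' @slot runId text tag identifying the (dataset, parameter) run.
#' @slot contigs character vector of contig sequences (A/C/G/T).
#' @slot provenance list of run parameters (k, minCount, datasetId, ...).
#' @export
setClass("Assembly",
         representation(runId = "character", contigs = "character",
                        provenance = "list"))

setValidity("Assembly", function(object) {
  if (length(object@contigs) && any(grepl("[^ACGT]", object@contigs)))
    return("contigs must contain only A/C/G/T")
  TRUE
})

#' Construct an Assembly
#' @param contigs character vector of contig sequences.
#' @param runId run tag.
#' @param provenance parameter record.
#' @return An [Assembly-class].
#' @export
Assembly <- function(contigs, runId = "assembly", provenance = list()) {
  new("Assembly", runId = runId, contigs = unname(contigs),
      provenance = provenance)
}

#' Contig sequences of an assembly
#' @param x an `Assembly`.
#' @export
contigs <- function(x) x@contigs

#' Run identifier of an assembly
#' @param x an `Assembly`.
#' @export
runId <- function(x) x@runId

#' @export
setMethod("length", "Assembly", function(x) length(x@contigs))

setMethod("show", "Assembly", function(object) {
  len <- nchar(object@contigs)
  cat(sprintf("Assembly '%s': %d contigs, %d bp total%s\n", object@runId,
              length(len), sum(len),
              if (length(len)) sprintf(", max %d bp", max(len)) else ""))
})
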