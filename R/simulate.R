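## Synthetic-data generator: quadripartite genomes, mutated trios,
## Illumina-like paired-end reads, and deterministic split-read datasets.

#' Default region GC fractions (LSC / IR / SSC) of the simulator
#'
#' Values mirror the GC composition of *Populus* plastomes: 34.47% (LSC),
#' 41.97% (IR) and 30.54% (SSC).
#' @export
defaultRegionGC <- c(LSC = 0.3447, IR = 0.4197, SSC = 0.3054)

#' Simulate a quadripartite chloroplast genome
#'
#' Builds a circular genome laid out as LSC-IRa-SSC-IRb with IRb exactly the
#' reverse complement of IRa (unless `irDivergence > 0`), with per-region GC
#' content. The same seed always yields a byte-identical sequence.
#'
#' @param lengthLsc,lengthIr,lengthSsc region lengths in bases (all > 0);
#'   total genome length is `lengthLsc + 2 * lengthIr + lengthSsc`.
#' @param gcByRegion named fractions in (0,1) for LSC/IR/SSC.
#' @param seed integer RNG seed.
#' @param name genome label.
#' @param irDivergence per-base substitution rate applied to IRb, for
#'   genomes whose inverted repeats are deliberately below 100% identity.
#' @return A [QuadripartiteGenome-class].
#' @examples
#' g <- buildGenome(1000, 300, 200, seed = 7)
#' length(g)       # 1800
#' irIdentity(g)   # 1
#' @export
buildGenome <- function(lengthLsc, lengthIr, lengthSsc,
                        gcByRegion = defaultRegionGC, seed = NULL,
                        name = "synthetic_cp", irDivergence = 0) {
  if (any(c(lengthLsc, lengthIr, lengthSsc) <= 0))
    stop("region lengths must be positive")
  if (any(gcByRegion <= 0 | gcByRegion >= 1))
    stop("GC fractions must be in (0, 1)")
  if (lengthIr < 2L * 31L)
    warning("IR shorter than twice the default assembly k-mer; ",
            "the inverted repeat may be undetectable downstream")
  withSeed(seed, {
    lsc <- randomSeq(lengthLsc, gcByRegion[["LSC"]])
    ira <- randomSeq(lengthIr, gcByRegion[["IR"]])
    ssc <- randomSeq(lengthSsc, gcByRegion[["SSC"]])
    irb <- revComp(ira)
    if (irDivergence > 0) {
      n <- rbinom(1L, lengthIr, irDivergence)
      if (n > 0L) {
        pos <- sample.int(lengthIr, n)
        for (p in pos) {
          old <- substr(irb, p, p)
          substr(irb, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
    }
    QuadripartiteGenome(paste0(lsc, ira, ssc, irb),
                        lscEnd = lengthLsc, iraEnd = lengthLsc + lengthIr,
                        sscEnd = lengthLsc + lengthIr + lengthSsc,
                        name = name, circular = TRUE)
  })
}

#' Specification of the variants planted in a simulated trio
#'
#' Encodes the variant classes of a mother-father-offspring comparison
#' against a reference: variants shared by all three clones, variants
#' private to one parent, and de novo offspring variants. Offspring cpDNA is
#' the maternal cpDNA plus the de novo edits (maternal inheritance is the
#' simulator's ground truth); set `inheritance = "paternal"` for the
#' reversed negative control.
#'
#' @param nShared variants planted identically in all three clones.
#' @param nMotherPrivate,nFatherPrivate variants private to one parent
#'   (mother-private variants are inherited by the offspring).
#' @param nDeNovoOffspring de novo offspring variants.
#' @param snpIndelRatio fraction of planted variants that are SNPs; the
#'   rest are InDels of 1-10 bp.
#' @param regionWeights sampling weights for placement in LSC/SSC/IR.
#'   Only SNPs shared by all three clones may be placed in the IR (where
#'   they are mirrored into both copies); InDels and all
#'   genotype-differing variants stay in single-copy regions, the IR being
#'   the conservative compartment.
#' @param allowIrDeNovo also allow de novo offspring SNPs inside the IR
#'   (negative-control use only).
#' @param inheritance `"maternal"` (default) or `"paternal"`.
#' @param seed integer RNG seed.
#' @return A `TrioSpec` list.
#' @export
trioSpec <- function(nShared = 10L, nMotherPrivate = 5L, nFatherPrivate = 5L,
                     nDeNovoOffspring = 2L, snpIndelRatio = 0.6,
                     regionWeights = c(LSC = 3, SSC = 1, IR = 1),
                     allowIrDeNovo = FALSE, inheritance = "maternal",
                     seed = 1L) {
  counts <- c(nShared, nMotherPrivate, nFatherPrivate, nDeNovoOffspring)
  if (any(counts < 0)) stop("variant counts must be >= 0")
  if (snpIndelRatio < 0 || snpIndelRatio > 1)
    stop("snpIndelRatio must be in [0, 1]")
  if (any(regionWeights < 0) || sum(regionWeights) == 0)
    stop("region weights must be >= 0 and not all zero")
  inheritance <- match.arg(inheritance, c("maternal", "paternal"))
  structure(list(nShared = as.integer(nShared),
                 nMotherPrivate = as.integer(nMotherPrivate),
                 nFatherPrivate = as.integer(nFatherPrivate),
                 nDeNovoOffspring = as.integer(nDeNovoOffspring),
                 snpIndelRatio = snpIndelRatio,
                 regionWeights = regionWeights,
                 allowIrDeNovo = allowIrDeNovo,
                 inheritance = inheritance, seed = as.integer(seed)),
            class = "TrioSpec")
}

## sample non-overlapping planting positions >= minGap apart within intervals
.samplePositions <- function(n, intervals, taken, minGap = 20L, margin = 50L) {
  pool <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    a <- intervals$start[i] + margin; b <- intervals$end[i] - margin
    if (b < a) integer(0) else seq.int(a, b)
  }))
  pos <- integer(0)
  for (i in seq_len(n)) {
    ok <- pool[!vapply(pool, function(p) any(abs(p - c(taken, pos)) < minGap),
                       logical(1))]
    if (length(ok) == 0L)
      stop("requested variant count exceeds available non-overlapping positions")
    pos <- c(pos, sample(ok, 1L))
  }
  pos
}

#' Plant variants on a reference and derive a mother/father/offspring trio
#'
#' Builds three genomes from a simulated reference: edits shared by all
#' three, parent-private edits, and de novo offspring edits on top of the
#' transmitting parent's genome. Variants never overlap (>= 20 bp apart),
#' InDels (1-10 bp) avoid homopolymers of length >= 5 so their normalized
#' representation is unambiguous, and IR variants are SNPs mirrored into
#' both repeat copies so IR symmetry is preserved.
#'
#' @param reference a [QuadripartiteGenome-class].
#' @param spec a [trioSpec()].
#' @param cloneNames named character vector with entries `mother`, `father`,
#'   `offspring`.
#' @return list with elements `mother`, `father`, `offspring`
#'   (`QuadripartiteGenome`s) and `truth`, a data.frame of planted variants
#'   (1-based reference `pos`, anchored `ref`/`alt` alleles, `type`,
#'   `region`, `class`, `carriers`).
#' @export
makeTrio <- function(reference, spec = trioSpec(),
                     cloneNames = c(mother = "mother", father = "father",
                                    offspring = "offspring")) {
  stopifnot(is(reference, "QuadripartiteGenome"))
  refseq <- genomeSeq(reference)
  withSeed(spec$seed, {
    classes <- rep(c("shared", "mother_private", "father_private", "de_novo"),
                   c(spec$nShared, spec$nMotherPrivate, spec$nFatherPrivate,
                     spec$nDeNovoOffspring))
    n <- length(classes)
    truth <- NULL
    if (n > 0L) {
      rt <- regionTable(reference)
      scIntervals <- rt[rt$region %in% c("LSC", "SSC"), ]
      iraInterval <- rt[rt$region == "IRa", ]
      w <- spec$regionWeights
      taken <- integer(0)
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        isSnp <- runif(1) < spec$snpIndelRatio
        ## only variants shared by all three clones may sit in the IR:
        ## genotype-differing loci stay in single-copy regions (the IR is
        ## the conservative compartment), unless the negative-control flag
        ## opens the IR to de novo edits
        inIr <- FALSE
        if (isSnp && (classes[i] == "shared" ||
                      (spec$allowIrDeNovo && classes[i] == "de_novo"))) {
          regs <- c("LSC", "SSC", "IR")
          probs <- w[regs] / sum(w[regs])
          inIr <- sample(regs, 1L, prob = probs) == "IR"
        }
        intervals <- if (inIr) iraInterval else scIntervals
        repeat {
          pos <- .samplePositions(1L, intervals, taken)
          if (isSnp || maxHomopolymerAt(refseq, pos, pos + 11L) < 5L) break
          taken <- c(taken, pos) # burn indel-hostile spot, resample
        }
        taken <- c(taken, pos, if (inIr)
          sscEnd(reference) + (iraEnd(reference) - pos) + 1L)
        refBase <- substr(refseq, pos, pos)
        if (isSnp) {
          alt <- sample(setdiff(c("A", "C", "G", "T"), refBase), 1L)
          rows[[i]] <- data.frame(pos = pos, ref = refBase, alt = alt,
                                  type = "SNP", class = classes[i],
                                  mirrored = inIr)
        } else {
          len <- sample.int(10L, 1L)
          if (runif(1) < 0.5) { # insertion after pos
            ins <- randomSeq(len, 0.5)
            rows[[i]] <- data.frame(pos = pos, ref = refBase,
                                    alt = paste0(refBase, ins),
                                    type = "insertion", class = classes[i],
                                    mirrored = FALSE)
          } else {              # deletion of len bases after pos
            del <- substr(refseq, pos, pos + len)
            rows[[i]] <- data.frame(pos = pos, ref = del, alt = refBase,
                                    type = "deletion", class = classes[i],
                                    mirrored = FALSE)
          }
        }
      }
      truth <- do.call(rbind, rows)
      ## left-normalize planted alleles (planting avoids homopolymers, so
      ## this is usually a no-op, but it guarantees the invariant)
      for (i in seq_len(nrow(truth))) {
        nv <- leftNormalize(truth$pos[i], truth$ref[i], truth$alt[i], refseq)
        truth$pos[i] <- nv$pos; truth$ref[i] <- nv$ref; truth$alt[i] <- nv$alt
      }
    }
    truth <- .expandMirrored(truth, reference)
    carriersOf <- function(cl) switch(cl,
      shared = c("mother", "father", "offspring"),
      mother_private = c("mother", "offspring"),
      father_private = "father",
      de_novo = "offspring")
    if (spec$inheritance == "paternal")
      carriersOf <- function(cl) switch(cl,
        shared = c("mother", "father", "offspring"),
        mother_private = "mother",
        father_private = c("father", "offspring"),
        de_novo = "offspring")
    edits <- function(role) {
      if (is.null(truth)) return(truth)
      keep <- vapply(truth$class, function(cl) role %in% carriersOf(cl),
                     logical(1))
      truth[keep, , drop = FALSE]
    }
    buildClone <- function(role) {
      e <- edits(role)
      out <- .applyEdits(reference, e)
      out@name <- unname(cloneNames[[role]])
      out
    }
    mother <- buildClone("mother")
    father <- buildClone("father")
    offspring <- buildClone("offspring")
    if (!is.null(truth)) {
      truth$region <- regionOf(reference, truth$pos)
      truth$carriers <- vapply(truth$class, function(cl)
        paste(cloneNames[carriersOf(cl)], collapse = ","), character(1))
      truth <- truth[order(truth$pos), ]
      rownames(truth) <- NULL
    } else {
      truth <- data.frame(pos = integer(0), ref = character(0),
                          alt = character(0), type = character(0),
                          class = character(0), mirrored = logical(0),
                          region = character(0), carriers = character(0))
    }
    list(mother = mother, father = father, offspring = offspring,
         truth = truth)
  })
}

## add the mirrored IRb row for every IR-planted SNP
.expandMirrored <- function(truth, reference) {
  if (is.null(truth) || !any(truth$mirrored)) return(truth)
  m <- truth[truth$mirrored, , drop = FALSE]
  m$pos <- sscEnd(reference) + (iraEnd(reference) - m$pos) + 1L
  m$ref <- revComp(m$ref)
  m$alt <- revComp(m$alt)
  rbind(truth, m)
}

## apply a set of non-overlapping edits to a genome, shifting boundaries
.applyEdits <- function(genome, edits) {
  s <- genomeSeq(genome)
  a <- lscEnd(genome); b <- iraEnd(genome); cc <- sscEnd(genome)
  if (!is.null(edits) && nrow(edits)) {
    edits <- edits[order(edits$pos, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(edits))) {
      p <- edits$pos[i]; ref <- edits$ref[i]; alt <- edits$alt[i]
      stopifnot(substr(s, p, p + nchar(ref) - 1L) == ref)
      s <- paste0(substr(s, 1L, p - 1L), alt,
                  substr(s, p + nchar(ref), nchar(s)))
      delta <- nchar(alt) - nchar(ref)
      if (delta != 0L) {
        if (p <= a) a <- a + delta
        if (p <= b) b <- b + delta
        if (p <= cc) cc <- cc + delta
      }
    }
  }
  QuadripartiteGenome(s, a, b, cc, name = genomeName(genome),
                      circular = genome@circular)
}

#' Simulate Illumina-like paired-end reads from a genome
#'
#' wgsim-style simulation: fragment start positions are uniform over the
#' circle (fragments may wrap the origin), read 2 is the reverse complement
#' of the fragment end, substitution errors are i.i.d. per base, and a
#' `duplicateRate` fraction of pairs is appended a second time verbatim.
#' Qualities are a uniform Phred 35.
#'
#' @param genome a [QuadripartiteGenome-class] or a plain DNA string.
#' @param nPairs number of (pre-duplication) read pairs; 0 gives an empty
#'   dataset.
#' @param readLength read length in bases.
#' @param insertMean,insertSd fragment-size model in bases.
#' @param errorRate per-base substitution probability.
#' @param duplicateRate fraction of pairs emitted twice.
#' @param seed integer RNG seed.
#' @param datasetId dataset label.
#' @param circular whether a plain-string genome is circular (ignored for
#'   `QuadripartiteGenome` input, which carries its own flag).
#' @return A [ReadDataset-class]; `meta(x)$origin` records each fragment's
#'   start and length for truth-based tests.
#' @export
simulateReads <- function(genome, nPairs, readLength = 100L,
                          insertMean = 300, insertSd = 30, errorRate = 0.01,
                          duplicateRate = 0.001, seed = NULL,
                          datasetId = NULL, circular = TRUE) {
  seq <- genomeSeq(genome)
  if (is(genome, "QuadripartiteGenome")) circular <- genome@circular
  L <- nchar(seq)
  if (readLength > insertMean)
    stop("readLength must not exceed insertMean")
  if (is.null(datasetId))
    datasetId <- if (is(genome, "QuadripartiteGenome"))
      paste0(genomeName(genome), ".reads") else "reads"
  if (nPairs == 0L)
    return(ReadDataset(character(0), character(0), datasetId = datasetId,
                       readLength = readLength, insertMean = insertMean,
                       insertSd = insertSd, errorRate = errorRate,
                       duplicateRate = duplicateRate))
  withSeed(seed, {
    fragLen <- pmax(readLength, pmin(L, round(rnorm(nPairs, insertMean,
                                                    insertSd))))
    start <- if (circular) sample.int(L, nPairs, replace = TRUE)
             else sample.int(max(L - max(fragLen) + 1L, 1L), nPairs,
                             replace = TRUE)
    doubled <- if (circular) paste0(seq, substr(seq, 1L, min(L, insertMean +
                                                             5 * insertSd)))
               else seq
    frags <- substring(doubled, start, start + fragLen - 1L)
    r1 <- substr(frags, 1L, readLength)
    r2 <- revComp(substring(frags, fragLen - readLength + 1L, fragLen))
    if (errorRate > 0) {
      r1 <- .addSubstitutions(r1, errorRate)
      r2 <- .addSubstitutions(r2, errorRate)
    }
    ndup <- round(nPairs * duplicateRate)
    dupIdx <- if (ndup > 0L) sample.int(nPairs, ndup) else integer(0)
    origin <- data.frame(start = c(start, start[dupIdx]),
                         fragLen = c(fragLen, fragLen[dupIdx]),
                         duplicate = rep(c(FALSE, TRUE),
                                         c(nPairs, length(dupIdx))))
    ReadDataset(c(r1, r1[dupIdx]), c(r2, r2[dupIdx]),
                pairId = c(paste0(datasetId, ".", seq_len(nPairs)),
                           if (ndup) paste0(datasetId, ".", dupIdx, ".dup")),
                datasetId = datasetId, readLength = readLength,
                insertMean = insertMean, insertSd = insertSd,
                errorRate = errorRate, duplicateRate = duplicateRate,
                meta = list(origin = origin))
  })
}

## i.i.d. per-base substitutions over a vector of equal-length reads
.addSubstitutions <- function(reads, rate) {
  rl <- nchar(reads)
  nerr <- rbinom(length(reads), rl, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(rl[i], nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  reads
}

#' Deterministic split-read fragments of a genome
#'
#' Splits a sequence into all `window`-bp fragments with a `step`-bp sliding
#' window (the split-read method used for mappability screening). Linear
#' mode yields `length - window + 1` fragments; circular mode yields
#' `length` fragments (wrapping the origin). Fragments are error-free
#' substrings.
#'
#' @param genome a [QuadripartiteGenome-class] or plain DNA string.
#' @param window fragment size in bases (default 100).
#' @param step window step in bases (default 1).
#' @param circular whether to wrap the origin; defaults to the genome's
#'   circularity flag (plain strings default linear).
#' @return character vector of fragments, named by 1-based start position.
#' @export
splitReads <- function(genome, window = 100L, step = 1L, circular = NULL) {
  seq <- genomeSeq(genome)
  if (is.null(circular))
    circular <- if (is(genome, "QuadripartiteGenome")) genome@circular else FALSE
  L <- nchar(seq)
  if (window > L) stop("window must not exceed the genome length")
  starts <- seq.int(1L, if (circular) L else L - window + 1L, by = step)
  src <- if (circular) paste0(seq, substr(seq, 1L, window - 1L)) else seq
  setNames(substring(src, starts, starts + window - 1L), starts)
}
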