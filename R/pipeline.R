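## End-to-end convenience wrappers over the module functions.

#' Construct a chloroplast genome from reads (assemble, merge, complete)
#'
#' The four-step construction strategy in one call: assemble the dataset(s)
#' with the de Bruijn unitig assembler, merge the unitigs into super
#' contigs against the reference guide, and complete the IRb region from
#' the assembled IRa. Unitigs overlap by `k - 1` bases, so that is the
#' merge overlap used here.
#'
#' @param datasets a [ReadDataset-class] or list of them (all from one
#'   clone).
#' @param reference the guide [QuadripartiteGenome-class].
#' @param k odd assembly k-mer size (default 41).
#' @param minCount minimum k-mer multiplicity (default 2).
#' @param minContigLength minimum unitig length (default 200).
#' @param minOverlap merge overlap (default 20: unitigs from a k-mer
#'   assembler abut with overlaps of about `k - 1` bases, occasionally a
#'   few bases less where a junction extends into the repeat).
#' @param name name of the constructed genome.
#' @return A circular [QuadripartiteGenome-class] (see [completeIrb()]);
#'   the attribute `superContigs` holds the pre-completion merged
#'   assembly.
#' @export
constructGenome <- function(datasets, reference, k = 41L, minCount = 2L,
                            minContigLength = 200L, minOverlap = 20L,
                            name = "constructed") {
  if (is(datasets, "ReadDataset")) datasets <- list(datasets)
  assemblies <- lapply(datasets, assembleReads, k = k, minCount = minCount,
                       minContigLength = minContigLength)
  merged <- mergeContigs(assemblies, reference, minOverlap = minOverlap)
  if (length(merged) == 0L)
    stop("no contigs could be merged against the reference")
  ## take the super contig anchored at the start of the reference LSC
  starts <- vapply(contigs(merged), function(s) {
    ch <- anchorContig(s, genomeSeq(reference))
    if (is.null(ch)) NA_real_ else ch$refStart
  }, numeric(1))
  super <- contigs(merged)[[which.min(starts)]]
  g <- completeIrb(super, reference, name = name)
  attr(g, "superContigs") <- merged
  g
}

#' Run the dual-strategy variant pipeline for a trio of clones
#'
#' For each clone: compare its constructed genome against the reference
#' (comparison strategy), pileup-call each of its read datasets against
#' the reference (mapping strategy), filter problematic mapping calls, and
#' integrate everything into one unified variant table with per-clone
#' genotypes.
#'
#' @param genomes named list (clone -> constructed
#'   [QuadripartiteGenome-class]).
#' @param datasets named list (clone -> list of [ReadDataset-class]); may
#'   be empty to use the comparison strategy alone.
#' @param reference the reference [QuadripartiteGenome-class].
#' @param minDepth,minAltFraction pileup thresholds (see [pileupCall()]).
#' @param repeatabilityMin see [flagProblematic()].
#' @param seedK,minIdentity mapper parameters (see [mapReads()]).
#' @return list with `variants` (unified annotated table), `comparison`,
#'   `mapping` (per-clone cleaned call sets) and `problematic` (per-clone).
#' @export
trioVariantPipeline <- function(genomes, datasets = list(), reference,
                                minDepth = 10L, minAltFraction = 0.8,
                                repeatabilityMin = 0.9, seedK = 21L,
                                minIdentity = 0.95) {
  comparison <- lapply(genomes, compareGenomes, reference = reference)
  mapping <- list()
  problematic <- list()
  if (length(datasets)) {
    idx <- seedIndex(reference, seedK = seedK)
    for (cl in names(datasets)) {
      callSets <- lapply(datasets[[cl]], function(d) {
        aln <- mapDataset(d, idx, minIdentity = minIdentity)
        pileupCall(aln, reference, minDepth = minDepth,
                   minAltFraction = minAltFraction)$calls
      })
      fl <- flagProblematic(callSets, comparison[[cl]], reference,
                            repeatabilityMin = repeatabilityMin)
      mapping[[cl]] <- fl$clean
      problematic[[cl]] <- fl$problematic
    }
  }
  unified <- integrateVariants(comparison, mapping)
  unified <- annotateVariants(unified, reference)
  list(variants = unified, comparison = comparison, mapping = mapping,
       problematic = problematic)
}

#' Precision and recall of a called variant set against a truth table
#'
#' Loci are matched on (position, ref allele, alt allele).
#'
#' @param called data.frame with `pos`, `ref`, `alt`.
#' @param truth data.frame with `pos`, `ref`, `alt`.
#' @return named numeric: `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
variantAccuracy <- function(called, truth) {
  k <- function(d) unique(paste(d$pos, d$ref, d$alt))
  ck <- k(called); tk <- k(truth)
  tp <- length(intersect(ck, tk))
  fp <- length(setdiff(ck, tk))
  fn <- length(setdiff(tk, ck))
  c(precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
    tp = tp, fp = fp, fn = fn)
}
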