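## Region and coding-effect annotation of variant loci.

#' Read a GFF-like gene model into the annotation data.frame
#'
#' Accepts a data.frame (columns `gene`, `type` in {gene, CDS}, `start`,
#' `end`, `strand`, optional `phase`) or a path to a GFF3 file (read with
#' rtracklayer when available).
#'
#' @param x data.frame or GFF3 file path.
#' @return validated gene-model data.frame.
#' @export
readGeneModel <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 files requires the rtracklayer package")
    g <- as.data.frame(rtracklayer::import(x))
    x <- data.frame(gene = if (!is.null(g$gene)) g$gene else
                      if (!is.null(g$Name)) g$Name else g$ID,
                    type = as.character(g$type), start = g$start,
                    end = g$end, strand = as.character(g$strand),
                    phase = if (!is.null(g$phase)) as.integer(g$phase) else 0L)
    x <- x[x$type %in% c("gene", "CDS"), ]
  }
  stopifnot(is.data.frame(x),
            all(c("gene", "type", "start", "end", "strand") %in% names(x)))
  if (is.null(x$phase)) x$phase <- 0L
  x$phase[is.na(x$phase)] <- 0L
  x
}

#' Annotate variants with region and coding effect
#'
#' Assigns each locus its quadripartite region and, given a gene model,
#' its coding effect: CDS SNPs are translated with the plastid/bacterial
#' genetic code (translation table 11) into `synonymous`, `missense` or
#' `nonsense`; CDS InDels become `frameshift` (length difference not a
#' multiple of 3) or `inframe`; loci inside a gene but outside its CDS are
#' `intron`; other loci are `upstream` or `downstream` of the nearest gene
#' relative to its strand.
#'
#' @param variants variant data.frame (`pos`, `ref`, `alt`, `type`).
#' @param genome the reference [QuadripartiteGenome-class] (for regions and
#'   codon lookup).
#' @param geneModel gene model (see [readGeneModel()]), or NULL to annotate
#'   regions only.
#' @return `variants` with `region` and (given a gene model) `gene` and
#'   `effect` columns.
#' @export
annotateVariants <- function(variants, genome, geneModel = NULL) {
  variants$region <- regionOf(genome, variants$pos)
  if (is.null(geneModel)) return(variants)
  gm <- readGeneModel(geneModel)
  if (any(gm$start < 1L | gm$end > length(genome)))
    stop("gene model interval outside the reference")
  refseq <- genomeSeq(genome)
  genes <- gm[gm$type == "gene", ]
  cdss <- gm[gm$type == "CDS", ]
  code <- Biostrings::getGeneticCode("11")
  effOf <- function(pos, refA, altA, vtype) {
    ci <- which(cdss$start <= pos & pos <= cdss$end)
    if (length(ci)) {
      cds <- cdss[ci[1L], ]
      if (vtype != "SNP") {
        d <- abs(nchar(refA) - nchar(altA))
        return(c(cds$gene, if (d %% 3L == 0L) "inframe" else "frameshift"))
      }
      ## codon holding pos (single-interval CDS; phase honoured)
      off <- if (cds$strand == "+") pos - cds$start - cds$phase
             else cds$end - cds$phase - pos
      if (off < 0L) return(c(cds$gene, "intron"))
      codonIdx <- off %/% 3L
      within <- off %% 3L
      if (cds$strand == "+") {
        c0 <- cds$start + cds$phase + 3L * codonIdx
        refCodon <- substr(refseq, c0, c0 + 2L)
        altCodon <- refCodon
        substr(altCodon, within + 1L, within + 1L) <- altA
      } else {
        c0 <- cds$end - cds$phase - 3L * codonIdx
        refCodon <- revComp(substr(refseq, c0 - 2L, c0))
        altCodon <- refCodon
        substr(altCodon, within + 1L, within + 1L) <- revComp(altA)
      }
      aaR <- code[[refCodon]]; aaA <- code[[altCodon]]
      eff <- if (aaR == aaA) "synonymous"
             else if (aaA == "*") "nonsense" else "missense"
      return(c(cds$gene, eff))
    }
    gi <- which(genes$start <= pos & pos <= genes$end)
    if (length(gi)) return(c(genes$gene[gi[1L]], "intron"))
    if (nrow(genes) == 0L) return(c(NA_character_, "intergenic"))
    d <- pmin(abs(genes$start - pos), abs(genes$end - pos))
    g <- genes[which.min(d), ]
    before <- pos < g$start
    eff <- if ((before && g$strand == "+") || (!before && g$strand == "-"))
      "upstream" else "downstream"
    c(g$gene, eff)
  }
  ann <- t(vapply(seq_len(nrow(variants)), function(i)
    effOf(variants$pos[i], variants$ref[i], variants$alt[i],
          variants$type[i]), character(2)))
  variants$gene <- ann[, 1L]
  variants$effect <- ann[, 2L]
  variants
}
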