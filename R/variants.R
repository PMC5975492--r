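## Dual-strategy variant discovery: whole-genome comparison and read-pileup
## calling, problematic-variant filtering, and integration into a unified
## per-clone variant table.

#' Call variants by whole-genome comparison
#'
#' Anchors the query genome to the reference with maximal exact matches,
#' chains them collinearly (longest consistent chain; leftmost on ties),
#' aligns the inter-anchor gaps globally (match +1, mismatch -1, gap open
#' -2, gap extend -1) and emits mismatch columns as SNPs, query-only runs
#' as insertions and reference-only runs as deletions, all left-normalized.
#'
#' @param query,reference near-identical genomes
#'   ([QuadripartiteGenome-class] or DNA string).
#' @param minAnchor minimum exact-match anchor (default 20).
#' @param minChainCover minimum fraction of the reference the chain must
#'   span (default 0.5); below it the comparison fails.
#' @return data.frame of variants: `pos` (1-based on the reference),
#'   anchored `ref`/`alt` alleles, `type`, `source = "comparison"`.
#' @export
compareGenomes <- function(query, reference, minAnchor = 20L,
                           minChainCover = 0.5) {
  q <- genomeSeq(query); ref <- genomeSeq(reference)
  ch <- chainAnchors(findAnchors(q, ref, minLen = minAnchor))
  if (is.null(ch)) stop("comparison failed: no anchors between genomes")
  if (ch$strand == "-") {
    q <- revComp(q)
    ch <- chainAnchors(findAnchors(q, ref, minLen = minAnchor))
  }
  span <- max(ch$anchors$rend) - min(ch$anchors$rstart) + 1L
  if (span < minChainCover * nchar(ref))
    stop("comparison failed: anchor chain covers less than ",
         round(100 * minChainCover), "% of the reference")
  v <- .chainVariants(q, ref, ch)
  if (nrow(v) == 0L) return(emptyVariantTable())
  v$source <- "comparison"
  rownames(v) <- NULL
  v
}

#' Call variants from read pileups (haploid organelle model)
#'
#' Builds per-column base and indel counts from the CIGARs of mapped reads
#' and calls a variant where depth is at least `minDepth` and the
#' alternate-allele fraction is at least `minAltFraction`. Columns whose
#' strongest alternate allele sits between `suspectFraction` and
#' `minAltFraction` are flagged heteroplasmy-suspect instead of called.
#'
#' @param alignments data.frame from [mapDataset()]/[mapReads()] (needs
#'   `oseq`); unmapped rows are ignored.
#' @param reference the [QuadripartiteGenome-class] (or DNA string) the
#'   reads were mapped against.
#' @param minDepth minimum column depth (default 10).
#' @param minAltFraction minimum alternate fraction to call (default 0.8).
#' @param suspectFraction lower bound of the heteroplasmy-suspect band
#'   (default 0.2).
#' @return list with `calls` (variant data.frame: `pos`, `ref`, `alt`,
#'   `type`, `source = "mapping"`, `depth`, `altFraction`) and `suspects`
#'   (same columns, uncalled heteroplasmy-like loci).
#' @export
pileupCall <- function(alignments, reference, minDepth = 10L,
                       minAltFraction = 0.8, suspectFraction = 0.2) {
  ref <- genomeSeq(reference)
  circular <- !is(reference, "QuadripartiteGenome") || reference@circular
  L <- nchar(ref)
  aln <- alignments[alignments$mapped %in% TRUE, , drop = FALSE]
  emptyCalls <- data.frame(pos = integer(0), ref = character(0),
                           alt = character(0), type = character(0),
                           source = character(0), depth = integer(0),
                           altFraction = numeric(0))
  if (nrow(aln) == 0L) return(list(calls = emptyCalls, suspects = emptyCalls))
  wrapPos <- function(p) if (circular) ((p - 1L) %% L) + 1L else p
  simple <- grepl("^[0-9]+M$", aln$cigar)
  posL <- list(); baseL <- list()
  insL <- list(); delL <- list()
  if (any(simple)) {
    s <- aln[simple, ]
    rl <- nchar(s$oseq)
    posL[[1L]] <- wrapPos(rep(s$refStart, rl) +
                            (sequence(rl) - 1L))
    baseL[[1L]] <- unlist(strsplit(s$oseq, "", fixed = TRUE))
  }
  for (i in which(!simple)) {
    p <- .cigarParse(aln$cigar[i])[[1L]]
    rpos <- aln$refStart[i]; qpos <- 1L
    seqChars <- strsplit(aln$oseq[i], "", fixed = TRUE)[[1L]]
    for (t in seq_along(p$op)) {
      len <- p$len[t]
      switch(p$op[t],
        M = {
          posL[[length(posL) + 1L]] <- wrapPos(rpos + 0:(len - 1L))
          baseL[[length(baseL) + 1L]] <- seqChars[qpos + 0:(len - 1L)]
          rpos <- rpos + len; qpos <- qpos + len
        },
        I = {
          anchor <- wrapPos(rpos - 1L)
          insL[[length(insL) + 1L]] <-
            data.frame(pos = anchor,
                       ins = paste(seqChars[qpos + 0:(len - 1L)],
                                   collapse = ""))
          qpos <- qpos + len
        },
        D = {
          anchor <- wrapPos(rpos - 1L)
          delL[[length(delL) + 1L]] <-
            data.frame(pos = anchor, dlen = len)
          rpos <- rpos + len
        },
        S = { qpos <- qpos + len })
    }
  }
  piles <- data.table::data.table(pos = unlist(posL), base = unlist(baseL))
  depth <- piles[, list(depth = .N), by = "pos"]
  counts <- piles[, list(n = .N), by = c("pos", "base")]
  counts <- depth[counts, on = "pos"]
  refBase <- substring(ref, counts$pos, counts$pos)
  altRows <- counts[counts$base != refBase]
  data.table::setorderv(altRows, c("pos", "n"), order = c(1L, -1L))
  altRows <- altRows[!duplicated(altRows$pos)] # strongest alt per column
  altRows[, "frac" := altRows$n / altRows$depth]
  snp <- data.frame(pos = altRows$pos,
                    ref = substring(ref, altRows$pos, altRows$pos),
                    alt = altRows$base, type = "SNP",
                    depth = altRows$depth, altFraction = altRows$frac)
  indelCalls <- list()
  addIndel <- function(df, what) {
    if (length(df) == 0L) return(NULL)
    dt <- data.table::rbindlist(df)
    key <- if (what == "insertion") c("pos", "ins") else c("pos", "dlen")
    dt <- dt[, list(n = .N), by = key]
    dt <- depth[dt, on = "pos"]
    dt <- dt[!is.na(dt$depth)]
    if (nrow(dt) == 0L) return(NULL)
    if (what == "insertion") {
      data.frame(pos = dt$pos,
                 ref = substring(ref, dt$pos, dt$pos),
                 alt = paste0(substring(ref, dt$pos, dt$pos), dt$ins),
                 type = "insertion", depth = dt$depth,
                 altFraction = dt$n / dt$depth)
    } else {
      data.frame(pos = dt$pos,
                 ref = substring(ref, dt$pos, dt$pos + dt$dlen),
                 alt = substring(ref, dt$pos, dt$pos),
                 type = "deletion", depth = dt$depth,
                 altFraction = dt$n / dt$depth)
    }
  }
  all <- rbind(snp, addIndel(insL, "insertion"), addIndel(delL, "deletion"))
  if (nrow(all) == 0L) return(list(calls = emptyCalls, suspects = emptyCalls))
  ## normalize indels so both strategies share one representation
  for (i in which(all$type != "SNP")) {
    nv <- leftNormalize(all$pos[i], all$ref[i], all$alt[i], ref)
    all$pos[i] <- nv$pos; all$ref[i] <- nv$ref; all$alt[i] <- nv$alt
  }
  all$source <- "mapping"
  all <- all[, c("pos", "ref", "alt", "type", "source", "depth",
                 "altFraction")]
  deep <- all$depth >= minDepth
  called <- deep & all$altFraction >= minAltFraction
  suspect <- deep & !called & all$altFraction >= suspectFraction
  calls <- all[called, , drop = FALSE]
  ## haploid deletion shadow: the bases inside a called deletion do not
  ## exist in this genome, so any other call within its reference span is
  ## a misaligned-read-tail artifact and is dropped
  del <- calls[calls$type == "deletion", , drop = FALSE]
  if (nrow(del)) {
    shadowed <- vapply(calls$pos, function(p)
      any(p > del$pos & p <= del$pos + (nchar(del$ref) - nchar(del$alt))),
      logical(1))
    calls <- calls[!shadowed, , drop = FALSE]
  }
  calls <- calls[order(calls$pos), ]
  rownames(calls) <- NULL
  suspects <- all[suspect, , drop = FALSE]
  rownames(suspects) <- NULL
  list(calls = calls, suspects = suspects)
}

#' Context flags of variant loci (homopolymer, low complexity, large indel)
#'
#' @param variants variant data.frame (`pos`, `ref`, `alt`).
#' @param reference reference genome or string.
#' @param window low-complexity window size (default 20).
#' @param entropyMin minimum dinucleotide entropy in bits (default 1.0).
#' @return character vector, comma-separated flags per variant ("" if none).
#' @export
contextFlags <- function(variants, reference, window = 20L,
                         entropyMin = 1.0) {
  ref <- genomeSeq(reference)
  vapply(seq_len(nrow(variants)), function(i) {
    p <- variants$pos[i]
    span <- max(nchar(variants$ref[i]), 1L)
    flags <- character(0)
    if (maxHomopolymerAt(ref, p, p + span - 1L) >= 5L)
      flags <- c(flags, "homopolymer")
    a <- max(1L, p - window %/% 2L)
    if (dinucEntropy(substr(ref, a, min(nchar(ref), a + window - 1L))) <
        entropyMin)
      flags <- c(flags, "low_complexity")
    if (abs(nchar(variants$ref[i]) - nchar(variants$alt[i])) > 5L)
      flags <- c(flags, "large_indel")
    paste(flags, collapse = ",")
  }, character(1))
}

#' Flag problematic mapping-derived variants for one clone
#'
#' A mapping locus is poor-repeatability when called in fewer than
#' `repeatabilityMin` of the clone's datasets; loci where the asserted
#' reference allele contradicts the reference sequence are inconsistent;
#' loci in homopolymers (>= 5 bp), low-complexity windows (dinucleotide
#' entropy < 1 bit over 20 bp) or with InDels > 5 bp are context-flagged
#' and kept only when the genome-comparison strategy confirms them (the
#' comparison strategy corrects mapping artifacts).
#'
#' @param callSets list of per-dataset variant data.frames (from
#'   [pileupCall()]`$calls`) for one clone; fewer than 2 datasets leaves
#'   repeatability undefined (warning).
#' @param comparisonSet comparison-strategy variants for the same clone.
#' @param reference reference genome or string.
#' @param repeatabilityMin minimum fraction of datasets calling a locus
#'   (default 0.9).
#' @return list with `clean` (variant data.frame with `repeatability` and
#'   `flags` columns) and `problematic` (same, plus `reason`).
#' @export
flagProblematic <- function(callSets, comparisonSet, reference,
                            repeatabilityMin = 0.9) {
  nSets <- length(callSets)
  if (nSets < 2L)
    warning("fewer than 2 datasets: repeatability undefined, only context/",
            "consistency filters applied")
  ref <- genomeSeq(reference)
  all <- data.table::rbindlist(lapply(callSets, function(d)
    d[, c("pos", "ref", "alt", "type"), drop = FALSE]))
  if (nrow(all) == 0L) {
    empty <- cbind(emptyVariantTable()[, 1:4], repeatability = numeric(0),
                   flags = character(0))
    return(list(clean = empty, problematic = cbind(empty,
                                                   reason = character(0))))
  }
  uni <- all[, list(nCalled = .N), by = c("pos", "ref", "alt", "type")]
  uni <- as.data.frame(uni)
  uni$repeatability <- if (nSets >= 2L) uni$nCalled / nSets else NA_real_
  uni$flags <- contextFlags(uni, ref)
  refAsserted <- substring(ref, uni$pos, uni$pos + nchar(uni$ref) - 1L)
  inconsistent <- refAsserted != uni$ref
  poorRep <- if (nSets >= 2L) uni$repeatability < repeatabilityMin
             else rep(FALSE, nrow(uni))
  key <- function(d) paste(d$pos, d$ref, d$alt)
  confirmed <- key(uni) %in% key(comparisonSet)
  contextBad <- uni$flags != "" & !confirmed
  reason <- ifelse(poorRep, "poor_repeatability",
            ifelse(inconsistent, "reference_inconsistent",
            ifelse(contextBad, "context_unconfirmed", "")))
  bad <- reason != ""
  uni$source <- "mapping"
  cols <- c("pos", "ref", "alt", "type", "source", "repeatability", "flags")
  problematic <- cbind(uni[bad, cols, drop = FALSE],
                       reason = reason[bad])
  clean <- uni[!bad, cols, drop = FALSE]
  clean <- clean[order(clean$pos), ]
  rownames(clean) <- rownames(problematic) <- NULL
  list(clean = clean, problematic = problematic)
}

#' Integrate comparison- and mapping-derived variants into a unified table
#'
#' Loci are merged by (position, ref allele, alt allele) after left
#' normalization. The `source` field records which strategies found each
#' locus; per-clone genotypes come from the comparison strategy (which
#' covers the whole genome: a clone carries the alternate allele iff its
#' comparison set contains the locus), with mapping filling in clones that
#' have no comparison set. Mapping-vs-comparison genotype conflicts keep
#' the comparison call and are flagged `strategy_conflict`.
#'
#' @param comparisonSets named list (clone -> comparison variant
#'   data.frame).
#' @param mappingSets named list (clone -> cleaned mapping variant
#'   data.frame, see [flagProblematic()]).
#' @return unified variant data.frame sorted by position: `pos`, `ref`,
#'   `alt`, `type`, `source`, `flags`, one `gt_<clone>` column per clone
#'   (allele strings).
#' @export
integrateVariants <- function(comparisonSets, mappingSets = list()) {
  clones <- union(names(comparisonSets), names(mappingSets))
  key <- function(d) if (nrow(d)) paste(d$pos, d$ref, d$alt) else character(0)
  pool <- list()
  for (cl in names(comparisonSets)) {
    d <- comparisonSets[[cl]]
    if (nrow(d)) pool[[length(pool) + 1L]] <-
        data.frame(pos = d$pos, ref = d$ref, alt = d$alt, type = d$type,
                   strategy = "comparison", clone = cl)
  }
  for (cl in names(mappingSets)) {
    d <- mappingSets[[cl]]
    if (nrow(d)) pool[[length(pool) + 1L]] <-
        data.frame(pos = d$pos, ref = d$ref, alt = d$alt, type = d$type,
                   strategy = "mapping", clone = cl)
  }
  if (length(pool) == 0L) {
    out <- emptyVariantTable()
    for (cl in clones) out[[paste0("gt_", cl)]] <- character(0)
    out$flags <- character(0)
    return(out)
  }
  pool <- do.call(rbind, pool)
  uni <- unique(pool[, c("pos", "ref", "alt", "type")])
  uni <- uni[order(uni$pos, uni$ref, uni$alt), ]
  rownames(uni) <- NULL
  k <- paste(uni$pos, uni$ref, uni$alt)
  bySrc <- split(paste(pool$pos, pool$ref, pool$alt), pool$strategy)
  uni$source <- vapply(k, function(kk)
    paste(sort(names(bySrc)[vapply(bySrc, function(s) kk %in% s,
                                   logical(1))]), collapse = ","),
    character(1))
  uni$flags <- ""
  ## different alleles asserted by the two strategies at one position stay
  ## as separate records, both flagged for review
  dupPos <- unique(uni$pos[duplicated(uni$pos)])
  for (p in dupPos) {
    rows <- which(uni$pos == p)
    if (length(unique(uni$source[rows])) > 1L)
      uni$flags[rows] <- "position_conflict"
  }
  for (cl in clones) {
    comp <- comparisonSets[[cl]]
    mapd <- mappingSets[[cl]]
    inComp <- if (!is.null(comp)) k %in% key(comp) else NULL
    inMap <- if (!is.null(mapd)) k %in% key(mapd) else NULL
    gt <- if (!is.null(inComp)) ifelse(inComp, uni$alt, uni$ref)
          else if (!is.null(inMap)) ifelse(inMap, uni$alt, uni$ref)
          else rep(NA_character_, nrow(uni))
    if (!is.null(inComp) && !is.null(inMap)) {
      conflict <- inMap & !inComp
      uni$flags[conflict] <- vapply(uni$flags[conflict], function(f)
        paste(c(f[nzchar(f)], "strategy_conflict"), collapse = ","),
        character(1))
    }
    uni[[paste0("gt_", cl)]] <- gt
  }
  uni
}

#' Classify trio genotypes and call the inheritance mode
#'
#' Groups every locus by pairwise genotype equality into `identical`, the
#' three two-vs-one classes (labelled with the actual clone names, e.g.
#' `"I45=I69"`) and `all_distinct`, and calls the genome-wide inheritance
#' verdict: `maternal` iff at every locus where the parents differ (and the
#' offspring matches a parent) the offspring equals the mother; `paternal`
#' for the reverse; `inconsistent` when informative loci disagree. De novo
#' offspring loci (offspring unlike both parents) are listed separately and
#' do not break the verdict. Loci with a missing genotype are excluded and
#' counted.
#'
#' @param variants unified variant table from [integrateVariants()] (or
#'   any data.frame with `pos` and `gt_<clone>` columns).
#' @param mother,father,offspring clone names matching the `gt_` columns.
#' @return A `TrioClassification` list: `table` (per-locus class),
#'   `counts`, `verdict`, `nInformative`, `deNovo` (data.frame),
#'   `nExcluded`.
#' @export
classifyTrio <- function(variants, mother, father, offspring) {
  cols <- paste0("gt_", c(mother, father, offspring))
  if (!all(cols %in% names(variants)))
    stop("clone ids not found in the variant table: ",
         paste(setdiff(cols, names(variants)), collapse = ", "))
  gm <- variants[[cols[1L]]]
  gf <- variants[[cols[2L]]]
  go <- variants[[cols[3L]]]
  complete <- !(is.na(gm) | is.na(gf) | is.na(go))
  lab <- function(a, b) paste(sort(c(a, b)), collapse = "=")
  cls <- rep(NA_character_, length(gm))
  cls[complete & gm == gf & gf == go] <- "identical"
  cls[complete & gm == gf & gf != go] <- lab(mother, father)
  cls[complete & gm == go & gm != gf] <- lab(mother, offspring)
  cls[complete & gf == go & gm != gf] <- lab(father, offspring)
  cls[complete & gm != gf & gf != go & gm != go] <- "all_distinct"
  tab <- data.frame(pos = variants$pos, class = cls)[complete, ]
  counts <- table(tab$class)
  informative <- complete & gm != gf & (go == gm | go == gf)
  nMat <- sum(informative & go == gm)
  nPat <- sum(informative & go == gf)
  verdict <- if (nMat > 0L && nPat == 0L) "maternal"
             else if (nPat > 0L && nMat == 0L) "paternal"
             else "inconsistent"
  deNovoIdx <- complete & go != gm & go != gf
  structure(list(table = tab,
                 counts = as.list(counts),
                 verdict = verdict,
                 nInformative = sum(informative),
                 nMaternal = nMat, nPaternal = nPat,
                 deNovo = variants[deNovoIdx, , drop = FALSE],
                 nExcluded = sum(!complete),
                 clones = c(mother = mother, father = father,
                            offspring = offspring)),
            class = "TrioClassification")
}

#' @export
print.TrioClassification <- function(x, ...) {
  cat(sprintf("TrioClassification (%s x %s -> %s)\n", x$clones[["mother"]],
              x$clones[["father"]], x$clones[["offspring"]]))
  for (nm in names(x$counts))
    cat(sprintf("  %-14s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  informative loci: %d (%d maternal, %d paternal)\n",
              x$nInformative, x$nMaternal, x$nPaternal))
  cat(sprintf("  de novo offspring loci: %d\n", nrow(x$deNovo)))
  cat(sprintf("  inheritance verdict: %s\n", x$verdict))
  invisible(x)
}
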