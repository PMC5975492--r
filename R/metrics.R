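## QUAST-style assembly metrics, reference-based evaluation, screening and
## optimum-assembly selection.

#' Alignment-free assembly metrics (num, totalSum, Nx/Lx family)
#'
#' Nx is the length of the contig at which the cumulative length of contigs
#' sorted longest-first first exceeds x% of the total assembly bases; Lx is
#' the number of contigs in that prefix. (At an exact x% boundary the next
#' contig is required, i.e. the strict-excess convention.)
#'
#' @param assembly an [Assembly-class] (non-empty) or a numeric vector of
#'   contig lengths.
#' @return one-row data.frame: `num`, `totalSum`, `mean`, `max`, `N80`,
#'   `L80`, `N50`, `L50`, `N20`, `L20`.
#' @export
basicMetrics <- function(assembly) {
  len <- if (is(assembly, "Assembly")) nchar(contigs(assembly))
         else as.numeric(assembly)
  if (length(len) == 0L) stop("empty assembly")
  len <- sort(len, decreasing = TRUE)
  total <- sum(len)
  cum <- cumsum(len)
  nx <- function(x) {
    i <- which(cum > x / 100 * total)[1L]
    if (is.na(i)) i <- length(len)
    c(N = len[i], L = i)
  }
  n80 <- nx(80); n50 <- nx(50); n20 <- nx(20)
  data.frame(num = length(len), totalSum = total, mean = mean(len),
             max = max(len), N80 = n80[["N"]], L80 = n80[["L"]],
             N50 = n50[["N"]], L50 = n50[["L"]], N20 = n20[["N"]],
             L20 = n20[["L"]])
}

#' Reference-based assembly metrics
#'
#' Anchors every contig to the reference, computes the genome fraction
#' (CoverRatio: reference bases covered by at least one aligned contig
#' block), the mismatch + small-indel rate per 100 kb of aligned bases, and
#' flags misassembled contigs. A contig is misassembled when its anchors
#' cannot be explained by one collinear chain: the best chain covers less
#' than `minChainFrac` of its anchored bases, or the chain itself jumps
#' more than `misassemblyDist` bases on the reference. Contigs that merely
#' have a second (inverted-repeat) placement are not flagged.
#'
#' @param assembly an [Assembly-class].
#' @param reference a [QuadripartiteGenome-class] or DNA string.
#' @param minAnchor minimum exact-match anchor (default 20).
#' @param misassemblyDist relocation distance threshold in bases
#'   (default 1000, the extensive-misassembly convention).
#' @param minChainFrac minimum fraction of anchored contig bases the best
#'   chain must explain (default 0.9).
#' @return one-row data.frame: `CoverRatio`, `mismatchesPer100kb`,
#'   `alignedBases`, `nMisassembled`, plus attribute `misassembled`
#'   (indices of flagged contigs) and `blocks` (aligned reference
#'   intervals).
#' @export
referenceMetrics <- function(assembly, reference, minAnchor = 20L,
                             misassemblyDist = 1000L, minChainFrac = 0.9) {
  ref <- genomeSeq(reference)
  ctg <- contigs(assembly)
  blocks <- list()
  mis <- integer(0)
  nDiff <- 0L
  aligned <- 0L
  for (i in seq_along(ctg)) {
    ch <- anchorContig(ctg[i], ref, minAnchor = minAnchor)
    if (is.null(ch)) next
    a <- ch$anchors
    jumps <- if (nrow(a) > 1L)
      abs(a$rstart[-1L] - a$rend[-nrow(a)]) else 0L
    relQ <- if (nrow(a) > 1L)
      abs(a$qstart[-1L] - a$qend[-nrow(a)]) else 0L
    if (ch$qAligned < minChainFrac * nchar(ctg[i]) ||
        any(jumps - relQ > misassemblyDist)) {
      mis <- c(mis, i)
      next
    }
    blocks[[length(blocks) + 1L]] <-
      IRanges::IRanges(min(a$rstart), max(a$rend))
    aligned <- aligned + ch$qAligned
    ## orient for gap alignment, then count per-column differences
    oc <- if (ch$strand == "+") ctg[i] else revComp(ctg[i])
    och <- if (ch$strand == "+") ch else
      anchorContig(oc, ref, minAnchor = minAnchor)
    if (!is.null(och) && och$strand == "+") {
      v <- .chainVariants(oc, ref, och)
      nDiff <- nDiff + nrow(v)
    }
  }
  cov <- if (length(blocks)) {
    u <- IRanges::reduce(do.call(c, blocks))
    sum(IRanges::width(IRanges::restrict(u, start = 1L,
                                         end = nchar(ref)))) / nchar(ref)
  } else 0
  out <- data.frame(CoverRatio = cov,
                    mismatchesPer100kb =
                      if (aligned > 0) nDiff / aligned * 1e5 else NA_real_,
                    alignedBases = aligned, nMisassembled = length(mis))
  attr(out, "misassembled") <- mis
  attr(out, "blocks") <- if (length(blocks))
    as.data.frame(IRanges::reduce(do.call(c, blocks)))[, c("start", "end")]
    else data.frame(start = integer(0), end = integer(0))
  out
}

#' Combined basic + reference metrics for a list of assemblies
#'
#' @param assemblies list of [Assembly-class].
#' @param reference optional reference for [referenceMetrics()] columns.
#' @param ... passed to [referenceMetrics()].
#' @return data.frame, one row per assembly (row names from run ids).
#' @export
assemblyMetricsTable <- function(assemblies, reference = NULL, ...) {
  rows <- lapply(assemblies, function(a) {
    bm <- basicMetrics(a)
    if (!is.null(reference)) cbind(bm, referenceMetrics(a, reference, ...))
    else bm
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(assemblies, runId, character(1))
  out
}

#' Screen assemblies on total bases and contig count
#'
#' Keeps assemblies with `totalSum > minTotalFrac * refLength` and
#' `num < maxContigs`; order preserved. The defaults scale the full-size
#' screening rule (> 126 kbp total bases, < 100 contigs against a 157-kbp
#' reference, i.e. roughly 80%) to any reference.
#'
#' @param assemblies list of [Assembly-class].
#' @param refLength reference length in bases.
#' @param minTotalFrac minimum total bases as a fraction of `refLength`
#'   (default 0.80).
#' @param maxContigs maximum contig count, exclusive (default 100).
#' @return the passing subset of `assemblies`.
#' @export
screenAssemblies <- function(assemblies, refLength, minTotalFrac = 0.80,
                             maxContigs = 100L) {
  keep <- vapply(assemblies, function(a) {
    len <- nchar(contigs(a))
    sum(len) > minTotalFrac * refLength && length(len) < maxContigs
  }, logical(1))
  assemblies[keep]
}

#' Select the optimum assembly from one tool's runs on one dataset
#'
#' Default rule: the assembly with the greatest N50; ties break toward
#' higher CoverRatio, then fewer contigs, then first seen. The
#' coverage-sensitive rule (used for assemblers whose genome fraction
#' varies strongly with the parameter) restricts to candidates with
#' CoverRatio > `coverMin` whenever any candidate exceeds it, and otherwise
#' falls back to the plain argmax-N50 rule.
#'
#' @param metrics data.frame with at least `N50`, and `CoverRatio`/`num`
#'   for tie-breaking (one row per candidate assembly).
#' @param toolClass `"default"` or `"coverage-sensitive"`.
#' @param coverMin CoverRatio threshold for the coverage-sensitive branch
#'   (default 0.85).
#' @return the selected row index into `metrics`.
#' @export
selectOptimum <- function(metrics, toolClass = c("default",
                                                 "coverage-sensitive"),
                          coverMin = 0.85) {
  toolClass <- match.arg(toolClass)
  if (nrow(metrics) == 0L) stop("no candidate assemblies")
  cand <- seq_len(nrow(metrics))
  if (toolClass == "coverage-sensitive" && !is.null(metrics$CoverRatio) &&
      any(metrics$CoverRatio > coverMin)) {
    cand <- which(metrics$CoverRatio > coverMin)
  }
  cover <- if (is.null(metrics$CoverRatio)) rep(0, nrow(metrics))
           else metrics$CoverRatio
  num <- if (is.null(metrics$num)) rep(0, nrow(metrics)) else metrics$num
  ord <- order(-metrics$N50[cand], -cover[cand], num[cand], cand)
  cand[ord[1L]]
}
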