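## Minimal de Bruijn unitig assembler with a multi-k sweep.

#' Build a strand-canonical de Bruijn graph from reads
#'
#' Nodes are canonical k-mers with multiplicities; k-mers seen fewer than
#' `minCount` times are removed (error filtering). An edge -- a (k-1)-base
#' overlap between two oriented k-mers -- exists only when the reads
#' contain the corresponding (k+1)-mer, so spurious overlaps between
#' unrelated k-mers never join a path.
#'
#' @param dataset a [ReadDataset-class] or character vector of sequences.
#' @param k odd k-mer size, at most the read length minus one (edges need
#'   (k+1)-mers).
#' @param minCount minimum k-mer and edge multiplicity retained (default 2).
#' @return A `DeBruijnGraph` list: `k`, `minCount`, `kmers` and `edges`
#'   (data.tables of canonical k-mer / (k+1)-mer and count).
#' @export
buildGraph <- function(dataset, k, minCount = 2L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  seqs <- if (is(dataset, "ReadDataset")) {
    if (length(dataset) && k + 1L > dataset@readLength)
      stop("k must not exceed the read length minus one")
    c(dataset@read1, dataset@read2)
  } else as.character(dataset)
  counts <- countCanonicalKmers(seqs, k)
  counts <- counts[counts$count >= minCount]
  edges <- countCanonicalKmers(seqs, k + 1L)
  edges <- edges[edges$count >= minCount]
  structure(list(k = k, minCount = as.integer(minCount), kmers = counts,
                 edges = edges),
            class = "DeBruijnGraph")
}

#' @export
print.DeBruijnGraph <- function(x, ...) {
  cat(sprintf("DeBruijnGraph: k=%d, %d canonical k-mers (minCount %d)\n",
              x$k, nrow(x$kmers), x$minCount))
  invisible(x)
}

#' Extract unitigs (maximal non-branching paths) from a de Bruijn graph
#'
#' Each unitig is emitted once per canonical orientation, contigs are
#' ordered longest first then lexicographically, and contigs shorter than
#' `minContigLength` are dropped. Extension stops at branch nodes and when
#' a path closes on itself (a circular genome yields one linear contig with
#' an arbitrary breakpoint).
#'
#' @param graph a [buildGraph()] result.
#' @param minContigLength minimum emitted contig length (default 200).
#' @param runId label for the resulting [Assembly-class].
#' @return An [Assembly-class].
#' @export
extractUnitigs <- function(graph, minContigLength = 200L,
                           runId = "unitigs") {
  stopifnot(inherits(graph, "DeBruijnGraph"))
  k <- graph$k
  kmers <- sort(graph$kmers$kmer)
  prov <- list(k = k, minCount = graph$minCount,
               minContigLength = minContigLength)
  if (length(kmers) == 0L)
    return(Assembly(character(0), runId = runId, provenance = prov))
  rcs <- revComp(kmers)
  ## canon: oriented k-mer -> canonical form (both orientations keyed)
  canonEnv <- new.env(hash = TRUE, size = 2L * length(kmers))
  for (i in seq_along(kmers)) {
    assign(kmers[i], kmers[i], envir = canonEnv)
    assign(rcs[i], kmers[i], envir = canonEnv)
  }
  ## read-supported edges, keyed by both (k+1)-mer orientations
  edgeEnv <- new.env(hash = TRUE, size = 2L * nrow(graph$edges) + 1L)
  if (nrow(graph$edges)) {
    ekm <- graph$edges$kmer
    erc <- revComp(ekm)
    for (i in seq_along(ekm)) {
      assign(ekm[i], TRUE, envir = edgeEnv)
      assign(erc[i], TRUE, envir = edgeEnv)
    }
  }
  bases <- c("A", "C", "G", "T")
  canonOf <- function(x) get(x, envir = canonEnv, inherits = FALSE)
  ## neighbours of an oriented k-mer: the node must exist, the joining
  ## (k+1)-mer must be read-supported, and a node's own reverse complement
  ## (hairpin) or itself (homopolymer loop) never counts as a neighbour
  nbr <- function(x, dir) {
    self <- canonOf(x)
    out <- character(0)
    for (b in bases) {
      if (dir == "succ") { y <- paste0(substr(x, 2L, k), b); e <- paste0(x, b) }
      else { y <- paste0(b, substr(x, 1L, k - 1L)); e <- paste0(b, x) }
      if (exists(e, envir = edgeEnv, inherits = FALSE) &&
          exists(y, envir = canonEnv, inherits = FALSE) &&
          !identical(canonOf(y), self))
        out <- c(out, y)
    }
    out
  }
  succs <- function(x) nbr(x, "succ")
  preds <- function(x) nbr(x, "pred")
  visited <- new.env(hash = TRUE, size = length(kmers))
  unitigs <- character(0)
  for (seed in kmers) {
    if (exists(seed, envir = visited, inherits = FALSE)) next
    assign(seed, TRUE, envir = visited)
    walk <- function(x) { # bases appended right of x's orientation
      acc <- character(0)
      inPath <- new.env(hash = TRUE)
      assign(get(x, envir = canonEnv), TRUE, envir = inPath)
      repeat {
        s <- succs(x)
        if (length(s) != 1L) break
        y <- s[[1L]]
        if (length(preds(y)) != 1L) break
        cy <- get(y, envir = canonEnv)
        if (exists(cy, envir = inPath, inherits = FALSE)) break # cycle
        if (exists(cy, envir = visited, inherits = FALSE)) break
        acc <- c(acc, substr(y, k, k))
        assign(cy, TRUE, envir = visited)
        assign(cy, TRUE, envir = inPath)
        x <- y
      }
      acc
    }
    right <- walk(seed)
    left <- walk(rcScalar(seed)) # rightward from rc == leftward from seed
    seqStr <- paste0(rcScalar(paste(left, collapse = "")), seed,
                     paste(right, collapse = ""))
    unitigs <- c(unitigs, seqStr)
  }
  unitigs <- unitigs[nchar(unitigs) >= minContigLength]
  unitigs <- unitigs[order(-nchar(unitigs), unitigs)]
  Assembly(unitigs, runId = runId, provenance = prov)
}

#' Assemble a read dataset at one k (graph + unitigs)
#'
#' @param dataset a [ReadDataset-class] or character vector.
#' @param k odd k-mer size.
#' @param minCount minimum k-mer multiplicity (default 2).
#' @param minContigLength minimum contig length (default 200).
#' @return An [Assembly-class].
#' @export
assembleReads <- function(dataset, k, minCount = 2L,
                          minContigLength = 200L) {
  id <- if (is(dataset, "ReadDataset")) dataset@datasetId else "seqs"
  asm <- extractUnitigs(buildGraph(dataset, k, minCount = minCount),
                        minContigLength = minContigLength,
                        runId = sprintf("%s.k%d", id, k))
  asm@provenance$datasetId <- id
  asm
}

#' Assemble one dataset across a sweep of k values
#'
#' One assembly per k; failures of individual k values (for example k
#' larger than the read length) are recorded, not fatal. All k failing is
#' an error.
#'
#' @param dataset a [ReadDataset-class].
#' @param kValues vector of odd k-mer sizes (e.g. `seq(19, 63, 2)`).
#' @param minCount,minContigLength see [assembleReads()].
#' @return list of [Assembly-class] objects named `k<value>`, with an
#'   attribute `failures` (named character vector of error messages).
#' @export
multiKSweep <- function(dataset, kValues, minCount = 2L,
                        minContigLength = 200L) {
  if (length(kValues) == 0L) stop("kValues must be non-empty")
  out <- list()
  failures <- character(0)
  for (k in kValues) {
    res <- tryCatch(assembleReads(dataset, k, minCount = minCount,
                                  minContigLength = minContigLength),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) failures[[paste0("k", k)]] <- res
    else out[[paste0("k", k)]] <- res
  }
  if (length(out) == 0L)
    stop("all k values failed: ", paste(failures, collapse = "; "))
  attr(out, "failures") <- failures
  out
}
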