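test_that("seed index agrees with a brute-force scan oracle", {
  s <- "ACGTACGT"
  idx <- seedIndex(s, seedK = 4, circular = FALSE)
  ## oracle: scan every position for the query and its reverse complement
  oracleHits <- function(q, ref) {
    hits <- integer(0)
    for (i in 1:(nchar(ref) - nchar(q) + 1))
      if (substr(ref, i, i + nchar(q) - 1) == q) hits <- c(hits, i)
    hits
  }
  q <- "ACGT" # palindromic seed: canonical form is itself
  expect_setequal(idx$seeds$pos[idx$seeds$kmer == q], oracleHits(q, s))
  expect_setequal(idx$seeds$pos[idx$seeds$kmer == q], c(1L, 5L))
  expect_error(seedIndex("ACGT", seedK = 10), "seedK")
})

test_that("every seed of the reference is found at its own position", {
  idx <- toyIndex()
  s <- genomeSeq(toyRef())
  set.seed(1)
  for (p in sample(1:(nchar(s) - 21L), 25)) {
    km <- substr(s, p, p + 20L)
    can <- min(km, oracleRevComp(km))
    expect_true(p %in% idx$seeds$pos[idx$seeds$kmer == can])
  }
})

test_that("exact substrings map back to their source at zero mismatches", {
  s <- genomeSeq(toyRef())
  idx <- toyIndex()
  a <- mapRead(substr(s, 2001, 2100), idx)
  expect_true(a$mapped)
  expect_equal(a$refStart, 2001L)
  expect_equal(a$strand, "+")
  expect_equal(a$cigar, "100M")
  expect_equal(a$nMismatch, 0L)
  ## reverse-complement reads map on the minus strand at the same locus
  b <- mapRead(oracleRevComp(substr(s, 2001, 2100)), idx)
  expect_true(b$mapped)
  expect_equal(b$refStart, 2001L)
  expect_equal(b$strand, "-")
})

test_that("all split-read fragments of the reference self-map", {
  g <- smallGenome()
  fr <- splitReads(g, window = 100, step = 1, circular = TRUE)
  idx <- seedIndex(g)
  aln <- mapReads(unname(fr), idx)
  expect_true(all(aln$mapped))
  expect_true(all(aln$identity >= 0.95))
  src <- as.integer(names(fr))
  ## fragments fully inside a single-copy region place exactly at their
  ## source with no mismatches
  lscOnly <- src + 99L <= lscEnd(g)
  expect_true(all(aln$refStart[lscOnly] == src[lscOnly]))
  expect_true(all(aln$nMismatch[lscOnly] == 0L))
  ## fragments fully inside IRb collapse onto the leftmost (IRa) copy,
  ## mirrored and mismatch-free: the documented deterministic IR collapse
  irbOnly <- src > sscEnd(g) & src + 99L <= length(g)
  mirror <- sscEnd(g) + (iraEnd(g) - (src + 99L)) + 1L
  expect_true(all(aln$refStart[irbOnly] == mirror[irbOnly]))
  expect_true(all(aln$strand[irbOnly] == "-"))
  expect_true(all(aln$nMismatch[irbOnly] == 0L))
})

test_that("reads without seed support and diverged reads stay unmapped", {
  idx <- toyIndex()
  s <- genomeSeq(toyRef())
  ## generate random reads until one shares no 21-mer with the reference
  ## (verified by scan), then demand it is unmapped
  set.seed(99)
  repeat {
    r <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
    shared <- any(vapply(1:(100 - 21 + 1), function(i) {
      km <- substr(r, i, i + 20)
      grepl(km, s, fixed = TRUE) || grepl(oracleRevComp(km), s, fixed = TRUE)
    }, logical(1)))
    if (!shared) break
  }
  expect_false(mapRead(r, idx)$mapped)
  ## a read below the identity threshold is unmapped
  bad <- substr(s, 3001, 3100)
  for (p in seq(5, 95, by = 10)) {
    old <- substr(bad, p, p)
    substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_false(mapRead(bad, idx)$mapped)
})

test_that("reads spanning small indels map through the gapped path", {
  s <- genomeSeq(toyRef())
  idx <- toyIndex()
  ## 4-base deletion relative to the reference
  rd <- paste0(substr(s, 5001, 5050), substr(s, 5055, 5104))
  a <- mapRead(rd, idx)
  expect_true(a$mapped)
  expect_equal(a$refStart, 5001L)
  expect_match(a$cigar, "4D")
  ## 4-base insertion relative to the reference
  ri <- paste0(substr(s, 5001, 5050), "ACAC", substr(s, 5051, 5096))
  b <- mapRead(ri, idx)
  expect_true(b$mapped)
  expect_match(b$cigar, "4I")
})

test_that("origin-spanning reads map on the circular reference", {
  s <- genomeSeq(smallGenome())
  idx <- seedIndex(smallGenome())
  r <- paste0(substr(s, 1751, 1800), substr(s, 1, 50))
  a <- mapRead(r, idx)
  expect_true(a$mapped)
  expect_equal(a$refStart, 1751L)
  expect_equal(a$nMismatch, 0L)
})

test_that("cpDNA extraction recovers the planted chloroplast fraction", {
  set.seed(5)
  decoy <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
                 collapse = "")
  dn <- simulateReads(decoy, 950, 100, 300, 30, errorRate = 0,
                      duplicateRate = 0, seed = 4, circular = TRUE)
  dc <- simulateReads(toyRef(), 50, 100, 300, 30, errorRate = 0,
                      duplicateRate = 0, seed = 5)
  mixed <- ReadDataset(c(readSeqs(dn, 1), readSeqs(dc, 1)),
                       c(readSeqs(dn, 2), readSeqs(dc, 2)),
                       datasetId = "mix")
  truth <- rep(c(FALSE, TRUE), c(950, 50))
  ex <- extractCpReads(mixed, toyIndex())
  expect_identical(ex$keep, truth)
  expect_equal(ex$ratio, 0.05)
  ## a pure chloroplast dataset is retained in full
  pure <- extractCpReads(dc, toyIndex())
  expect_equal(pure$ratio, 1)
  ## empty input reports ratio 0 with a warning
  expect_warning(e0 <- extractCpReads(simulateReads(toyRef(), 0, 100, 300, 30),
                                      toyIndex()), "empty")
  expect_equal(e0$ratio, 0)
})

test_that("depth profiles follow interval arithmetic and conserve mass", {
  aln <- data.frame(refStart = c(1L, 41L), cigar = c("50M", "40M"),
                    mapped = TRUE)
  dp <- depthProfile(aln, 100, circular = FALSE)
  expect_equal(max(dp$depth), 2L)
  expect_true(all(dp$depth[41:50] == 2L))
  expect_true(all(dp$depth[81:100] == 0L))
  expect_equal(dp$zeroIntervals, data.frame(start = 81L, end = 100L))
  ## no alignments: one zero-coverage interval over the whole reference
  none <- depthProfile(data.frame(refStart = integer(0),
                                  cigar = character(0), mapped = logical(0)),
                       100, circular = FALSE)
  expect_equal(none$zeroIntervals, data.frame(start = 1L, end = 100L))
  ## beyond-end alignments are rejected on linear references
  expect_error(depthProfile(data.frame(refStart = 90L, cigar = "50M",
                                       mapped = TRUE), 100,
                            circular = FALSE), "beyond")
  ## conservation: total depth equals total aligned reference span
  d <- toyReads()[1:300]
  a <- mapDataset(d, toyIndex())
  dp2 <- depthProfile(a, length(toyRef()))
  spans <- vapply(strsplit(gsub("([MDIS])", "\\1 ", a$cigar[a$mapped]), " "),
                  function(ops) {
                    lens <- as.integer(gsub("[A-Z]", "", ops))
                    sum(lens[grepl("[MD]", ops)])
                  }, numeric(1))
  expect_equal(sum(dp2$depth), sum(spans))
})

test_that("SAM emission round-trips the mandatory columns", {
  d <- toyReads()[1:5]
  a <- mapDataset(d, toyIndex())
  tmp <- tempfile(fileext = ".sam")
  writeSam(a, "toy", length(toyRef()), tmp)
  lines <- readLines(tmp)
  expect_match(lines[2], "@SQ\tSN:toy\tLN:18000")
  body <- strsplit(lines[-(1:2)], "\t")
  expect_true(all(vapply(body, length, integer(1)) >= 11L))
  expect_equal(as.integer(body[[1]][4]), a$refStart[1])
})
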