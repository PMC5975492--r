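test_that("genome comparison finds nothing between identical sequences", {
  expect_equal(nrow(compareGenomes(toyRef(), toyRef())), 0L)
})

test_that("genome comparison recovers a hand-planted SNP and indels", {
  set.seed(8)
  ref <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  q <- ref
  old <- substr(q, 60, 60)
  alt <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(q, 60, 60) <- alt
  v <- compareGenomes(q, ref, minAnchor = 10)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 60L)
  expect_identical(v$ref, old)
  expect_identical(v$alt, alt)
  expect_identical(v$type, "SNP")
  ## deletion of 5 bases
  qd <- paste0(substr(ref, 1, 59), substr(ref, 65, 120))
  vd <- compareGenomes(qd, ref, minAnchor = 10)
  expect_equal(nrow(vd), 1L)
  expect_identical(vd$type, "deletion")
  expect_equal(nchar(vd$ref) - nchar(vd$alt), 5L)
  ## insertion of 4 bases
  qi <- paste0(substr(ref, 1, 59), "TTAG", substr(ref, 60, 120))
  vi <- compareGenomes(qi, ref, minAnchor = 10)
  expect_equal(nrow(vi), 1L)
  expect_identical(vi$type, "insertion")
  expect_equal(nchar(vi$alt) - nchar(vi$ref), 4L)
  ## dissimilar sequences fail the comparison contract
  set.seed(9)
  junk <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  expect_error(compareGenomes(junk, ref, minAnchor = 10), "comparison failed")
})

test_that("genome comparison of a trio clone equals the simulator truth", {
  tr <- toyTrio()
  v <- compareGenomes(tr$mother, toyRef())
  truthM <- tr$truth[grepl("I69", tr$truth$carriers), ]
  acc <- variantAccuracy(v, truthM)
  expect_equal(unname(acc["precision"]), 1)
  expect_equal(unname(acc["recall"]), 1)
})

test_that("pileup calling follows the haploid thresholds", {
  s <- genomeSeq(toyRef())
  win <- substr(s, 1001, 1030)
  altRead <- win
  old <- substr(altRead, 15, 15)
  alt <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(altRead, 15, 15) <- alt
  mkAln <- function(seqs) data.frame(refStart = 1001L,
                                     cigar = paste0(nchar(seqs), "M"),
                                     mapped = TRUE, oseq = seqs)
  ## 20 alternate reads over a reference column: a clean SNP call
  r <- pileupCall(mkAln(rep(altRead, 20)), toyRef())
  expect_equal(nrow(r$calls), 1L)
  expect_equal(r$calls$pos, 1015L)
  expect_identical(r$calls$alt, alt)
  expect_identical(r$calls$ref, old)
  ## a 10/10 split is heteroplasmy-suspect, not a call
  r2 <- pileupCall(mkAln(c(rep(altRead, 10), rep(win, 10))), toyRef())
  expect_equal(nrow(r2$calls), 0L)
  expect_equal(nrow(r2$suspects), 1L)
  expect_equal(r2$suspects$pos, 1015L)
  expect_equal(r2$suspects$altFraction, 0.5)
  ## below minimum depth: no call
  r3 <- pileupCall(mkAln(rep(altRead, 5)), toyRef())
  expect_equal(nrow(r3$calls), 0L)
})

test_that("calls inside a called deletion's span are suppressed", {
  s <- genomeSeq(toyRef())
  ## a locus where the post-deletion base differs from the deleted base
  p <- 3000L
  while (substr(s, p + 1L, p + 1L) == substr(s, p + 5L, p + 5L)) p <- p + 1L
  ## 40 reads span the 4-bp deletion properly (30M4D30M); 10 reads end just
  ## past it and carry the shifted tail as plain matches -- the misaligned
  ## tails that motivate the deletion-shadow rule
  spanning <- paste0(substr(s, p - 29L, p), substr(s, p + 5L, p + 34L))
  tail10 <- paste0(substr(s, p - 22L, p), substr(s, p + 5L, p + 11L))
  aln <- rbind(data.frame(refStart = p - 29L, cigar = "30M4D30M",
                          mapped = TRUE, oseq = spanning)[rep(1, 40), ],
               data.frame(refStart = p - 22L, cigar = "30M",
                          mapped = TRUE, oseq = tail10)[rep(1, 10), ])
  r <- pileupCall(aln, toyRef())
  expect_true(any(r$calls$type == "deletion" & r$calls$pos <= p))
  inShadow <- r$calls$pos > p & r$calls$pos <= p + 4L
  expect_false(any(inShadow & r$calls$type == "SNP"))
})

test_that("pileup calling recovers planted truth from error-free reads", {
  tr <- toyTrio()
  d <- trioDatasets()[["I69"]][[1]]
  aln <- mapDataset(d, toyIndex())
  calls <- pileupCall(aln, toyRef())$calls
  truthM <- tr$truth[grepl("I69", tr$truth$carriers), ]
  ## every call is a planted variant (IR variants surface at the leftmost
  ## copy, which the truth table also carries)
  k <- function(x) paste(x$pos, x$ref, x$alt)
  expect_true(all(k(calls) %in% k(truthM)))
  ## all single-copy truth is recovered
  sc <- truthM[truthM$region %in% c("LSC", "SSC"), ]
  expect_true(all(k(sc) %in% k(calls)))
})

test_that("problematic-variant filtering separates the three failure classes", {
  set.seed(10)
  ref <- paste0(paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                      collapse = ""),
                "AAAAAAA",
                paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                      collapse = ""))
  mk <- function(pos, refA, altA)
    data.frame(pos = pos, ref = refA, alt = altA,
               type = ifelse(nchar(refA) == nchar(altA), "SNP",
                             ifelse(nchar(altA) > nchar(refA),
                                    "insertion", "deletion")),
               source = "mapping")
  goodPos <- 100L; rarePos <- 300L
  goodRef <- substr(ref, goodPos, goodPos)
  rareRef <- substr(ref, rarePos, rarePos)
  good <- mk(goodPos, goodRef, setdiff(c("A","C","G","T"), goodRef)[1])
  rare <- mk(rarePos, rareRef, setdiff(c("A","C","G","T"), rareRef)[1])
  ## 16 datasets: "good" called in 15 (0.94 >= 0.9), "rare" in 3
  sets <- lapply(1:16, function(i)
    rbind(if (i <= 15) good, if (i <= 3) rare))
  fl <- flagProblematic(sets, emptyComparison <- good[0, ], ref)
  expect_true(goodPos %in% fl$clean$pos)
  expect_true(rarePos %in% fl$problematic$pos)
  expect_identical(fl$problematic$reason[fl$problematic$pos == rarePos],
                   "poor_repeatability")
  ## a repeatable homopolymer call unconfirmed by comparison is discarded
  polyPos <- 503L
  poly <- mk(polyPos, substr(ref, polyPos, polyPos), "G")
  sets2 <- lapply(1:16, function(i) rbind(good, poly))
  fl2 <- flagProblematic(sets2, good[0, ], ref)
  expect_identical(fl2$problematic$reason[fl2$problematic$pos == polyPos],
                   "context_unconfirmed")
  ## the same call confirmed by the comparison strategy is kept
  fl3 <- flagProblematic(sets2, poly, ref)
  expect_true(polyPos %in% fl3$clean$pos)
  ## an asserted reference allele contradicting the reference is flagged
  wrongRef <- mk(200L, setdiff(c("A","C","G","T"),
                               substr(ref, 200, 200))[1], "A")
  sets3 <- lapply(1:16, function(i) rbind(good, wrongRef))
  fl4 <- flagProblematic(sets3, good[0, ], ref)
  expect_identical(fl4$problematic$reason[fl4$problematic$pos == 200L],
                   "reference_inconsistent")
  ## fewer than 2 datasets: repeatability undefined, warning raised
  expect_warning(flagProblematic(sets[1], good[0, ], ref), "fewer than 2")
})

test_that("integration merges strategies and fills genotypes by precedence", {
  refseq <- genomeSeq(toyRef())
  at <- function(p) substr(refseq, p, p)
  altOf <- function(p) setdiff(c("A", "C", "G", "T"), at(p))[1]
  shared <- data.frame(pos = 500L, ref = at(500), alt = altOf(500),
                       type = "SNP")
  compOnly <- data.frame(pos = 800L, ref = at(800),
                         alt = paste0(at(800), "TT"), type = "insertion")
  mapOnly <- data.frame(pos = 1200L, ref = at(1200), alt = altOf(1200),
                        type = "SNP")
  u <- integrateVariants(list(A = rbind(shared, compOnly), B = shared[0, ]),
                         list(A = rbind(shared, mapOnly)))
  expect_equal(u$pos, c(500L, 800L, 1200L))
  expect_identical(u$source, c("comparison,mapping", "comparison", "mapping"))
  ## clone A: comparison wins; the mapping-only locus conflicts with the
  ## comparison reference call and is flagged
  expect_identical(u$gt_A, c(shared$alt, compOnly$alt, at(1200)))
  expect_match(u$flags[3], "strategy_conflict")
  ## clone B carries the reference allele everywhere
  expect_identical(u$gt_B, c(at(500), at(800), at(1200)))
  expect_true(all(u$pos == sort(u$pos)))
})

test_that("full dual-strategy pipeline recovers the planted trio exactly", {
  tr <- toyTrio()
  pip <- trioPipeline(0)
  acc <- variantAccuracy(pip$variants, tr$truth)
  expect_equal(unname(acc["precision"]), 1)
  expect_equal(unname(acc["recall"]), 1)
  ## genotypes match the carrier sets
  v <- pip$variants
  truth <- tr$truth
  k <- paste(v$pos, v$ref, v$alt)
  tk <- paste(truth$pos, truth$ref, truth$alt)
  m <- match(k, tk)
  for (cl in c("I69", "I45", "NL895")) {
    carried <- grepl(cl, truth$carriers[m])
    expect_identical(v[[paste0("gt_", cl)]] == v$alt, carried)
  }
})

test_that("no genotype-differing locus is reported inside the IR", {
  pip <- trioPipeline(0)
  tc <- classifyTrio(pip$variants, "I69", "I45", "NL895")
  v <- pip$variants
  differing <- v$pos[v$pos %in% tc$table$pos[tc$table$class != "identical"]]
  if (length(differing))
    expect_true(all(regionOf(toyRef(), differing) %in% c("LSC", "SSC")))
})

test_that("trio classification labels classes and calls the verdict", {
  mkv <- function(gm, gf, go)
    data.frame(pos = seq_along(gm), ref = "A", alt = "T",
               gt_M = gm, gt_F = gf, gt_O = go)
  ## mother A / father G / offspring A: the mother=offspring class
  v <- mkv(c("A", "T", "A", "C", NA),
           c("G", "T", "A", "A", "A"),
           c("A", "T", "T", "G", "A"))
  tc <- classifyTrio(v, "M", "F", "O")
  expect_identical(tc$table$class,
                   c("M=O", "identical", "F=M", "all_distinct"))
  expect_equal(tc$nExcluded, 1L)
  ## maternal verdict with a de novo locus that does not break it
  v2 <- mkv(c("A", "A", "A"), c("T", "T", "A"), c("A", "A", "G"))
  tc2 <- classifyTrio(v2, "M", "F", "O")
  expect_identical(tc2$verdict, "maternal")
  expect_equal(nrow(tc2$deNovo), 1L)
  ## reversed: paternal
  v3 <- mkv(c("A", "A"), c("T", "T"), c("T", "T"))
  expect_identical(classifyTrio(v3, "M", "F", "O")$verdict, "paternal")
  ## mixed informative loci: inconsistent
  v4 <- mkv(c("A", "A"), c("T", "T"), c("A", "T"))
  expect_identical(classifyTrio(v4, "M", "F", "O")$verdict, "inconsistent")
  expect_error(classifyTrio(v2, "M", "F", "X"), "not found")
})

test_that("variant annotation translates coding effects with code table 11", {
  set.seed(33)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  lsc <- paste0("ATGGCTTGCTAA", rand(937),
                oracleRevComp("ATGGCTTGCTAA"), rand(39))
  stopifnot(nchar(lsc) == 1000)
  ira <- rand(300); ssc <- rand(200)
  g <- QuadripartiteGenome(paste0(lsc, ira, ssc, oracleRevComp(ira)),
                           1000, 1300, 1500, name = "annToy")
  gm <- data.frame(gene = c("g1", "g1", "g2", "g2", "g3", "g3"),
                   type = rep(c("gene", "CDS"), 3),
                   start = c(1, 1, 800, 830, 950, 950),
                   end = c(12, 12, 920, 880, 961, 961),
                   strand = c("+", "+", "+", "+", "-", "-"),
                   phase = 0L)
  mkv <- function(pos, refA, altA, type = "SNP")
    data.frame(pos = pos, ref = refA, alt = altA, type = type)
  v <- rbind(mkv(6, "T", "C"),     # GCT -> GCC, synonymous
             mkv(4, "G", "C"),     # GCT -> CCT (Ala -> Pro), missense
             mkv(9, "C", "A"),     # TGC -> TGA, stop gained
             mkv(5, "C", "CTT", "insertion"),  # +2 in CDS: frameshift
             mkv(5, "C", "CTTA", "insertion"), # +3 in CDS: inframe
             mkv(840, substr(lsc, 840, 840),
                 setdiff(c("A","C","G","T"), substr(lsc, 840, 840))[1]),
             mkv(810, substr(lsc, 810, 810),
                 setdiff(c("A","C","G","T"), substr(lsc, 810, 810))[1]),
             mkv(700, substr(lsc, 700, 700),
                 setdiff(c("A","C","G","T"), substr(lsc, 700, 700))[1]),
             mkv(30, substr(lsc, 30, 30),
                 setdiff(c("A","C","G","T"), substr(lsc, 30, 30))[1]),
             mkv(956, "A", "G"))   # minus-strand CDS, third codon position
  a <- annotateVariants(v, g, gm)
  expect_identical(a$effect[1:5], c("synonymous", "missense", "nonsense",
                                    "frameshift", "inframe"))
  expect_true(all(a$region[1:5] == "LSC"))
  expect_true(a$effect[6] %in% c("synonymous", "missense", "nonsense"))
  expect_identical(a$gene[6], "g2")          # inside the g2 CDS
  expect_identical(a$effect[7], "intron")    # in g2, outside its CDS
  expect_identical(a$effect[8], "upstream")  # before g2 on the plus strand
  expect_identical(a$effect[9], "downstream")# after g1 on the plus strand
  expect_identical(a$effect[10], "synonymous") # GCT -> GCC via minus strand
  expect_identical(a$gene[10], "g3")
  ## region labels alone when no gene model is given
  a2 <- annotateVariants(mkv(1100, "A", "T"), g)
  expect_identical(a2$region, "IRa")
  expect_error(annotateVariants(v, g, rbind(gm, data.frame(
    gene = "bad", type = "gene", start = 1, end = 99999, strand = "+",
    phase = 0L))), "outside")
})

test_that("trio variant tables export to VCF and TSV", {
  pip <- trioPipeline(0)
  v <- annotateVariants(pip$variants, toyRef())
  vcf <- tempfile(fileext = ".vcf")
  writeVariantsVcf(v, "toyRef", vcf)
  lines <- readLines(vcf)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  header <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  expect_identical(header[10:12], c("I69", "I45", "NL895"))
  body <- strsplit(grep("^[^#]", lines, value = TRUE), "\t")
  expect_length(body, nrow(v))
  expect_match(body[[1]][8], "SRC=")
  tsv <- tempfile(fileext = ".tsv")
  writeVariantsTsv(v, tsv)
  tab <- read.delim(tsv)
  expect_identical(names(tab)[1:4],
                   c("position", "reference", "alternative", "type"))
  expect_true(all(tab$type %in% c("Replace", "Insert", "Delete")))
})
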