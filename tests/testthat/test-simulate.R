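test_that("buildGenome constructs the quadripartite layout deterministically", {
  g <- smallGenome()
  expect_equal(length(g), 1800L)
  expect_equal(lscEnd(g), 1000L)
  expect_equal(iraEnd(g), 1300L)
  expect_equal(sscEnd(g), 1500L)
  s <- genomeSeq(g)
  ira <- substr(s, 1001, 1300)
  irb <- substr(s, 1501, 1800)
  expect_identical(irb, oracleRevComp(ira))
  expect_false(grepl("[^ACGT]", s))
  ## same seed, byte-identical sequence
  expect_identical(genomeSeq(buildGenome(1000, 300, 200, seed = 7)), s)
  ## different seed, different sequence
  expect_false(identical(genomeSeq(buildGenome(1000, 300, 200, seed = 8)), s))
})

test_that("buildGenome honours per-region GC content", {
  g <- toyRef()
  gc <- function(x) mean(strsplit(x, "")[[1]] %in% c("G", "C"))
  s <- genomeSeq(g)
  expect_equal(gc(substr(s, 1, 10000)), 0.3447, tolerance = 0.05)
  expect_equal(gc(substr(s, 10001, 13000)), 0.4197, tolerance = 0.05)
  expect_equal(gc(substr(s, 13001, 15000)), 0.3054, tolerance = 0.05)
})

test_that("buildGenome rejects bad inputs and warns on tiny IRs", {
  expect_error(buildGenome(0, 300, 200), "positive")
  expect_error(buildGenome(1000, 300, 200, gcByRegion = c(LSC = 0, IR = .4, SSC = .3)),
               "GC")
  expect_warning(buildGenome(1000, 50, 200, seed = 1), "IR")
})

test_that("makeTrio with no de novo edits leaves offspring equal to mother", {
  tr <- makeTrio(toyRef(), trioSpec(nShared = 3, nMotherPrivate = 2,
                                    nFatherPrivate = 2,
                                    nDeNovoOffspring = 0, seed = 5))
  expect_identical(genomeSeq(tr$offspring), genomeSeq(tr$mother))
})

test_that("makeTrio plants the requested variant classes with correct carriers", {
  ## single-copy-only placement so the truth table has exactly 14 rows
  tr <- makeTrio(toyRef(), trioSpec(nShared = 5, nMotherPrivate = 3,
                                    nFatherPrivate = 4, nDeNovoOffspring = 2,
                                    regionWeights = c(LSC = 3, SSC = 1, IR = 0),
                                    seed = 21))
  expect_equal(nrow(tr$truth), 14L)
  expect_true(all(tr$truth$region %in% c("LSC", "SSC")))
  ## offspring carries mother-private and de novo alleles, none of father's
  cls <- tr$truth$class
  off <- vapply(strsplit(tr$truth$carriers, ","), function(x)
    "offspring" %in% x, logical(1))
  expect_true(all(off[cls %in% c("shared", "mother_private", "de_novo")]))
  expect_false(any(off[cls == "father_private"]))
  ## planted positions never overlap (>= 20 bp apart)
  expect_true(min(diff(sort(tr$truth$pos))) >= 20L)
  ## ref alleles match the reference sequence
  refseq <- genomeSeq(toyRef())
  expect_identical(substring(refseq, tr$truth$pos,
                             tr$truth$pos + nchar(tr$truth$ref) - 1L),
                   tr$truth$ref)
})

test_that("IR-planted SNPs are mirrored and preserve IR symmetry", {
  tr <- makeTrio(toyRef(), trioSpec(nShared = 1, nMotherPrivate = 0,
                                    nFatherPrivate = 0, nDeNovoOffspring = 0,
                                    snpIndelRatio = 1,
                                    regionWeights = c(LSC = 0, SSC = 0, IR = 1),
                                    seed = 2))
  expect_equal(nrow(tr$truth), 2L)
  expect_setequal(tr$truth$region, c("IRa", "IRb"))
  ira <- tr$truth[tr$truth$region == "IRa", ]
  irb <- tr$truth[tr$truth$region == "IRb", ]
  expect_equal(irb$pos, sscEnd(toyRef()) + (iraEnd(toyRef()) - ira$pos) + 1L)
  expect_identical(irb$alt, oracleRevComp(ira$alt))
  for (g in list(tr$mother, tr$father, tr$offspring))
    expect_equal(irIdentity(g), 1)
})

test_that("makeTrio rejects variant counts that cannot be placed", {
  tiny <- buildGenome(300, 80, 150, seed = 3)
  expect_error(suppressWarnings(
    makeTrio(tiny, trioSpec(nShared = 500, seed = 1))), "exceeds")
})

test_that("error-free simulated reads are exact substrings of the circle", {
  d <- simulateReads(smallGenome(), 300, 100, 300, 30, errorRate = 0,
                     duplicateRate = 0, seed = 4)
  s <- genomeSeq(smallGenome())
  doubled <- paste0(s, s)
  rcDoubled <- oracleRevComp(doubled)
  ok1 <- vapply(readSeqs(d, 1), function(r) grepl(r, doubled, fixed = TRUE),
                logical(1))
  ok2 <- vapply(readSeqs(d, 2), function(r)
    grepl(r, rcDoubled, fixed = TRUE), logical(1))
  expect_true(all(ok1))
  expect_true(all(ok2))
  expect_true(all(nchar(readSeqs(d, 1)) == 100L))
  expect_true(all(nchar(readQuals(d, 1)) == 100L))
})

test_that("substitution errors occur at the configured binomial rate", {
  rate <- 0.01
  d <- simulateReads(toyRef(), 5000, 100, 300, 30, errorRate = rate,
                     duplicateRate = 0, seed = 9)
  clean <- simulateReads(toyRef(), 5000, 100, 300, 30, errorRate = 0,
                         duplicateRate = 0, seed = 9)
  mm <- sum(mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                   readSeqs(d, 1), readSeqs(clean, 1)))
  n <- 5000 * 100
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(mm / n - rate), 3 * se)
})

test_that("duplicate pairs follow the d/(1+d) post-dedup expectation", {
  d <- 0.2
  ds <- simulateReads(toyRef(), 2000, 100, 300, 30, errorRate = 0,
                      duplicateRate = d, seed = 13)
  expect_equal(nPairs(ds), 2000L + round(2000 * d))
  r <- dedupPairs(ds)
  expect_equal(r$duplicateFraction, d / (1 + d), tolerance = 0.02)
})

test_that("read simulation is a pure function of inputs and seed", {
  a <- simulateReads(smallGenome(), 100, 80, 250, 20, 0.01, 0.01, seed = 5)
  b <- simulateReads(smallGenome(), 100, 80, 250, 20, 0.01, 0.01, seed = 5)
  expect_identical(readSeqs(a, 1), readSeqs(b, 1))
  expect_identical(readSeqs(a, 2), readSeqs(b, 2))
})

test_that("simulateReads validates arguments and handles the empty case", {
  expect_error(simulateReads(smallGenome(), 10, readLength = 400,
                             insertMean = 300), "insertMean")
  d <- simulateReads(smallGenome(), 0, 100, 300, 30)
  expect_equal(nPairs(d), 0L)
})

test_that("splitReads yields the exact sliding-window fragment count", {
  g <- smallGenome()
  fr <- splitReads(g, window = 100, step = 1, circular = FALSE)
  expect_length(fr, 1800L - 100L + 1L)
  expect_identical(unname(fr[1]), substr(genomeSeq(g), 1, 100))
  frc <- splitReads(g, window = 100, step = 1, circular = TRUE)
  expect_length(frc, 1800L)
  ## boundary: window equal to the sequence length
  s <- substr(genomeSeq(g), 1, 100)
  expect_identical(unname(splitReads(s, window = 100)), s)
  expect_error(splitReads(s, window = 101), "window")
})
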