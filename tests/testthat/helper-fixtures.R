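## Shared fixtures, built once per test run and cached across test files.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache, inherits = FALSE))
    assign(name, expr, envir = .fixtureCache)
  get(name, envir = .fixtureCache, inherits = FALSE)
}

## small genome for cheap structural tests
smallGenome <- function() fixture("smallGenome",
  buildGenome(1000, 300, 200, seed = 7))

## the toy quadripartite genome of the pipeline-scale tests:
## LSC 10 kb, IR 3 kb, SSC 2 kb (total 18 kb, collapsed size 15 kb)
toyRef <- function() fixture("toyRef", buildGenome(10000, 3000, 2000, seed = 11))

toyIndex <- function() fixture("toyIndex", seedIndex(toyRef()))

## 50x error-free reads of the toy reference (4500 pairs of 2 x 100 bp)
toyReads <- function() fixture("toyReads",
  simulateReads(toyRef(), 4500, 100, 300, 30, errorRate = 0,
                duplicateRate = 0, seed = 6))

toyAssembly <- function() fixture("toyAssembly", assembleReads(toyReads(), 41))

## maternal trio with clone names matching the poplar study design
toyTrio <- function() fixture("toyTrio",
  makeTrio(toyRef(),
           trioSpec(nShared = 6, nMotherPrivate = 4, nFatherPrivate = 4,
                    nDeNovoOffspring = 2, seed = 3),
           cloneNames = c(mother = "I69", father = "I45",
                          offspring = "NL895")))

trioGenomes <- function() {
  tr <- toyTrio()
  list(I69 = tr$mother, I45 = tr$father, NL895 = tr$offspring)
}

## two read datasets per clone (the minimum for repeatability filtering)
trioDatasets <- function(errorRate = 0, baseSeed = 100) {
  fixture(sprintf("trioDatasets_%g_%d", errorRate, baseSeed), {
    gens <- trioGenomes()
    lapply(gens, function(g) lapply(1:2, function(i)
      simulateReads(g, 4500, 100, 300, 30, errorRate = errorRate,
                    duplicateRate = 0.001,
                    seed = baseSeed + i + nchar(genomeSeq(g)),
                    datasetId = paste0(genomeName(g), ".Set", i))))
  })
}

## full dual-strategy pipeline results (cached: ~25 s each)
trioPipeline <- function(errorRate = 0) {
  fixture(sprintf("trioPipeline_%g", errorRate),
          trioVariantPipeline(trioGenomes(),
                              trioDatasets(errorRate = errorRate,
                                           baseSeed = if (errorRate > 0) 200
                                                      else 100),
                              toyRef()))
}

## independent brute-force Nx/Lx oracle (cumulative scan, no shared code);
## strict-excess boundary convention: the prefix must exceed x% of the total
oracleNxLx <- function(lengths, x) {
  lengths <- sort(lengths, decreasing = TRUE)
  target <- x / 100 * sum(lengths)
  acc <- 0
  for (i in seq_along(lengths)) {
    acc <- acc + lengths[i]
    if (acc > target) return(c(N = lengths[i], L = i))
  }
  c(N = lengths[length(lengths)], L = length(lengths))
}

## independent reverse complement (no package code)
oracleRevComp <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

## rotation-insensitive sequence equality for circular molecules
rotationEqual <- function(a, b)
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
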