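---
title: "Constructing chloroplast genomes and tracing trio variant transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing chloroplast genomes and tracing trio variant transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Land-plant chloroplast genomes (cpDNA) are circular molecules of roughly
120-160 kbp with a conserved quadripartite layout: a large single-copy
region (LSC, ~84-85 kbp in *Populus*), a small single-copy region (SSC,
~16 kbp) and two inverted repeats (IRa, IRb, ~27 kbp each) in which IRb is
the reverse complement of IRa at or near 100% identity. Because the
organelle is inherited maternally in most angiosperms, comparing the cpDNA
of an offspring with both of its parents at single-base resolution tells
you which parent transmitted the plastome and which variants arose de
novo -- information directly useful for parental selection in tree
breeding.

Two properties make this analysis awkward with short reads. First, cpDNA
reads are a small fraction (a few percent) of whole-genome shotgun data
and must be fished out by mapping against a related reference. Second, the
two IRs are long and (near-)identical, so k-mer based size estimators and
de Bruijn assemblers *collapse* them: assemblies and size estimates come
out at LSC+IR+SSC, about 82-83% of the true circle, and the second IR copy
has to be restored afterwards.

`chlorotrace` implements the full construction strategy --
Simulation, Assembly, Merging, Correction -- and the downstream
dual-strategy variant analysis, together with a synthetic-data generator
so that every stage is testable end to end without any external data or
tools.

## The pipeline

1. **Simulation** (`buildGenome`, `makeTrio`, `simulateReads`,
   `splitReads`). A quadripartite genome with per-region GC content; a
   mother/father/offspring trio derived from it by planting variants with
   known carriers; wgsim-style paired-end reads with uniform circular
   sampling, i.i.d. substitution errors and verbatim duplicate pairs; and
   the deterministic "split-read" datasets (every 100-bp window at 1-bp
   steps) used for mappability screening.
2. **Read preparation** (`trimLowQualityEnds`, `dedupPairs`,
   `kmerHistogram`, `estimateGenomeSize`). FASTX-style 3' end trimming,
   FastUniq-style exact duplicate-pair removal, canonical k-mer spectra
   and spectrum-based genome-size estimation.
3. **Mapping** (`seedIndex`, `mapReads`, `extractCpReads`,
   `depthProfile`). A k-mer seed-and-extend mapper with voting, an
   ungapped fast path and gapped extension (Biostrings pairwise alignment)
   for reads spanning indels; used for cpDNA read extraction, per-base
   depth and pileup input.
4. **Assembly** (`buildGraph`, `extractUnitigs`, `multiKSweep`). A
   strand-canonical de Bruijn graph whose edges require read support by a
   (k+1)-mer; unitigs are maximal non-branching paths. The multi-k sweep
   emulates the parameter diversity of running several assemblers.
5. **Evaluation** (`basicMetrics`, `referenceMetrics`,
   `screenAssemblies`, `selectOptimum`). QUAST-style Nx/Lx statistics,
   genome fraction (CoverRatio), misassembly flagging, screening and the
   two-branch optimum-assembly selection rule.
6. **Merging and correction** (`mergeContigs`, `detectQuadripartite`,
   `collectIrbContigs`, `completeIrb`). Reference-guided ordering,
   orientation and overlap merging of contigs into super contigs;
   detection of the quadripartite structure from inverted self-matches;
   and completion of the missing IRb stretch from the reverse complement
   of the assembled IRa.
7. **Variants** (`compareGenomes`, `pileupCall`, `flagProblematic`,
   `integrateVariants`, `annotateVariants`, `classifyTrio`). Whole-genome
   comparison (anchor chaining plus gap alignment) and per-dataset pileup
   calling; filtering of poorly repeatable, reference-inconsistent and
   context-compromised mapping calls; integration into one genotyped
   table; region/effect annotation; and the trio inheritance verdict.

`constructGenome()` and `trioVariantPipeline()` wrap steps 4-7.

## What the generator emulates, and what it does not

The simulator's defaults encode the study conditions the package is
validated under:

* **Genome.** Regions at the canonical proportions (default GC 34.47% /
  41.97% / 30.54% for LSC / IR / SSC), IRb exactly the reverse complement
  of IRa. The test genome uses LSC 10 kb, IR 3 kb, SSC 2 kb (18 kb total,
  15 kb collapsed) -- the real proportions at roughly 1/9 scale, chosen so
  the whole pipeline runs in seconds per invocation while keeping every
  structural phenomenon (IR collapse, junction unitigs, mirrored IR
  variants) intact.
* **Trio.** Offspring cpDNA = transmitting parent's cpDNA + de novo
  edits; carriers are recorded as ground truth. Planted variants are 60%
  SNPs and 40% InDels of 1-10 bp, at least 20 bp apart, left-aligned, and
  InDels avoid homopolymers of 5+ bp so truth is unambiguous. Only
  variants shared by all three clones are placed in the IR (mirrored into
  both copies); genotype-differing variants stay in single-copy regions,
  reflecting the IR's conservatism. A flag reverses transmission
  (paternal control) or opens the IR to de novo edits for negative
  controls.
* **Reads.** 2 x 100 bp pairs, insert 300 +/- 30 bp, uniform circular
  fragment starts, i.i.d. substitutions at a configurable rate (0 and 1%
  in the tests), uniform Phred 35 qualities, and a configurable fraction
  of verbatim duplicate pairs (0.1% by default, matching the "< 0.1% PCR
  duplicates" regime). Coverage in the tests is 50x with two independent
  datasets per clone -- a deliberate scale-down of multi-pass
  ultra-deep sequencing that still exercises repeatability filtering.

Not modelled: positional quality decay, GC-coverage bias, optical
duplicates, adapter read-through, and IR copies below 100% identity are
only reachable through an explicit divergence parameter. Passing tests
therefore demonstrate the correctness of the algorithms under an
idealized error model, not performance on real HiSeq data.

## Numerical and design choices

* **Nx/Lx boundary.** `Nx` is the contig length at which the
  longest-first cumulative sum first *strictly exceeds* x% of the total;
  at an exact x% boundary the next contig is required. The convention is
  stated explicitly because the two conventions differ only on exact
  boundaries; the strict form is the one our worked example
  (`{5,4,3,2,1}` giving N80 = 2, L80 = 4) pins down, and the property
  tests compare against a brute-force oracle under the same rule.
* **Canonical k-mers.** All k-mer machinery is strand-collapsed
  (lexicographic minimum of a k-mer and its reverse complement). This is
  required for the IR collapse to reproduce: IRb k-mers only merge with
  IRa k-mers under canonicalization.
* **Genome-size estimate.** The spectrum's error mode is separated at the
  first local minimum (ties toward lower multiplicity), the coverage peak
  is the mode above it, and the size estimate is the *number of distinct
  canonical k-mers above the valley*. A totals/peak ratio would count
  two-copy IR k-mers twice and recover the full circle; the
  distinct-k-mer count is what converges to the collapsed LSC+IRa+SSC
  size that spectrum-based estimators report on plastomes, which is the
  behaviour this package is built to reproduce.
* **Mapper.** Seeds are canonical 21-mers every 5 bases; the best-voted
  (offset, strand) wins with ties to the leftmost position, then the +
  strand. A read maps iff identity over aligned bases is >= 0.95 across
  >= 90% of the read. One best alignment per read: reads (and contigs)
  from the IR place deterministically on the leftmost copy, the same
  collapse real short-read mappers exhibit, so IR pileup calls surface on
  IRa only and are interpreted accordingly.
* **Chaining tolerance.** When two anchor chains for one sequence score
  within 30 bases of each other (the IR ambiguity: junction extensions
  can make one copy score a handful of bases higher), the leftmost
  reference placement wins. 30 bases is well above the chance extension
  length at a junction (geometric with mean ~1/3) and far below any
  genuine placement difference.
* **Merging.** Contigs are ordered and oriented by their reference anchor
  chain, placed against the growing consensus by contig-vs-consensus
  anchors (exact even when the target genome carries indels relative to
  the guide), and merged when the overlap is >= `minOverlap` at >= 99%
  identity. Disagreements resolve by per-column majority with ties going
  to the reference base. Unitigs from a k-assembler overlap by about k-1
  bases, so the end-to-end wrapper uses a 20-bp merge overlap;
  the 100-bp default documents the intent for longer, independently
  assembled contigs. Unanchored contig overhangs (the wrap-around tail a
  unitig of a circular genome carries past the origin) are clipped before
  placement.
* **IRb completion.** Reference boundaries are projected onto the partial
  assembly through its anchor chain; any assembled IRb prefix must agree
  with the reverse complement of the assembled IRa at >= 99.5% identity,
  otherwise completion refuses. Assembled bases are kept; only the
  missing stretch is inferred, and the completion report records which
  interval was inferred rather than assembled.
* **Variant calling.** Haploid organelle model: a pileup call needs depth
  >= 10 and alternate fraction >= 0.8; columns between 0.2 and 0.8 are
  flagged heteroplasmy-suspect and not genotyped. Calls falling inside the
  reference span of an accepted deletion call are suppressed (the
  "deletion shadow"): in a haploid genome those bases do not exist, and
  the only reads placing bases there are ones whose ends crossed the
  deletion by too few bases for the aligner to open a gap. Mapping loci
  called in
  fewer than 90% of a clone's datasets are discarded as poorly
  repeatable; loci in homopolymers >= 5 bp, low-complexity windows
  (dinucleotide entropy < 1 bit over 20 bp) or with InDels > 5 bp are
  kept only when the genome-comparison strategy confirms them. On
  integration, comparison genotypes take precedence over mapping
  genotypes -- the comparison strategy is the corrector, not the
  corrected. No multiple-testing control is applied: calls are rule-based
  thresholds, not hypothesis tests.
* **Trio verdict.** A locus is informative when the parents differ and
  the offspring matches one of them; the verdict is maternal iff every
  informative locus matches the mother (paternal for the reverse,
  inconsistent when they disagree). De novo offspring loci are listed
  separately and never break the verdict.

## Known limitations

* The assembler has no bubble popping or tip clipping beyond
  multiplicity-2 k-mer and edge filtering; it is adequate and auditable
  at organelle scale, not a general-purpose assembler.
* The mapper reports one best alignment, no pair rescue and no
  quality-aware scoring; SAM output is minimal plain text.
* `detectQuadripartite` leaves the SSC in its assembled orientation
  (flip-isomers are equivalent for comparison purposes) and, on circular
  input, canonicalizes only the rotation.
* Annotation assumes single-interval CDSs with a phase; it classifies
  SNPs via the plastid/bacterial genetic code (table 11) and InDels as
  frameshift/inframe, and does not handle splice-junction effects.
* The repeatability filter needs at least two datasets per clone; below
  that only the context and consistency filters act (with a warning).

## Problem sizes used by the tests and the acceptance script

All validation runs use the 18-kb toy genome described above: 50x
error-free and 1%-error datasets of 4500 read pairs, two datasets per
clone, 14-16 planted variants per trio, and assembly at k = 41 (with
k = 19..63 sweeps exercised on subsamples). These sizes keep a full
pipeline invocation in the tens of seconds on one core while leaving
every algorithmic branch -- IR collapse and completion, junction unitigs,
repeatability filtering, heteroplasmy flagging, mirrored IR variants --
active at the same relative scales as a real plastome.
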