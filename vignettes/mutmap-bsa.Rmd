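---
title: "Mapping recessive EMS mutations by bulked-segregant SNP-index analysis"
author: "MutMapBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive EMS mutations by bulked-segregant SNP-index analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MutMapBSA)
```

## The design and its model

MutMap-style bulked-segregant analysis locates a recessive causal mutation
with three sequencing samples: the wild-type parent line, the EMS mutant
derived from it, and a pool of recessive-phenotype F2 plants from the
mutant x wild-type cross.  Because the mutant is near-isogenic to its
parent, essentially every segregating SNP is an EMS artefact, and the only
locus under selection in the recessive pool is the causal one.

The per-site statistic is the **SNP index**: the fraction of pooled reads
carrying the mutant allele, where "mutant allele" means the allele the
mutant parent is homozygous for (not the VCF alt — this makes the index
invariant to reference polarity).  Each chromosome in the pool is an F1
gamete that carried the causal allele, so at a marker with recombination
fraction $r$ to the causal locus the chance it still carries the mutant
allele is $1 - r$:

$$E[\text{index}] = 1 - r, \qquad r = \tfrac{1}{2}\,(1 - e^{-2d})$$

with $d$ the Haldane map distance in Morgans (`haldaneR()`,
`expectedIndexAtLinkedMarker()`).  At the causal site the index is exactly
1 before sequencing error; on unlinked chromosomes it fluctuates around
0.5.  The assumptions are standard: single recessive nuclear locus,
error-free phenotyping of the pooled plants, no segregation distortion, and
crossovers without interference.

## The filtration cascade

`filterVariants()` applies six rules in order, attributing each removed
site to its first failing rule so the report is a partition
(`input = kept + sum(removed)`):

| rule | removes | default |
|------|---------|---------|
| i    | parent depth outside bounds, bulk depth outside bounds | [3, 100], [5, 150] |
| ii   | genotype quality below threshold in any sample | 20 |
| iii  | heterozygous / missing wild-type parent | — |
| iv   | bulk covered only by alleles carried by neither parent | — |
| v    | parents not homozygous-divergent | — |
| vi   | wild-type → mutant substitution not C>T / G>A | on |

Numerical conventions worth stating:

* **Strict inequalities.** The published bounds are written as "<3 or
  >100", so a depth exactly at a bound passes.  The boundary grid is
  enumerated in the tests.
* **Depth is summed AD, not DP.**  The SNP index consumes allele depths;
  using the same quantity in the filter keeps the two stages consistent
  (DP can disagree with AD after caller-side read filtering).
* **Missing GQ defaults to 99.**  Absence of an annotation should not
  silently delete data; the choice is visible in `readVariantVcf()`.
* **Rule iv on biallelic records.**  "Both bulk alleles foreign to the
  cross" can only happen, after biallelic decomposition, when both parents
  are homozygous for one allele and every bulk read carries the other.
  Such a site also fails rule v, but is attributed to iv because iv is
  tested first.  The predicate is kept explicit so decomposed multiallelic
  input exercises it.
* **Missing bulk/parent genotypes** are kept as `missing` and handled by
  the genotype rules (a missing wild-type parent fails rule iii, since its
  allele cannot be established) rather than dropped at read time.

## The sliding-window scan

`slidingWindowTrack()` averages raw indices in windows of `windowBp`
(default 2 Mb) centred every `stepBp` (default 10 kb); windows with fewer
than `minSnps` (default 3) SNPs are masked.  The source analysis states
the sliding-window method but not its parameters; these defaults are common
MutMap practice, resolve comfortably at the scale of a ~10-Mb candidate
region, and are all exposed in `ScanParam()`.  The window statistic is the
arithmetic mean, the convention for SNP-index plots; the smoothed value
always lies within the range of its contributing raw indices (tested as an
invariant).

`callCandidateRegions()` takes maximal runs of consecutive unmasked windows
at or above the threshold (default 0.80, the fixed threshold of the
design) and snaps each run to the first and last raw SNP inside its span;
`length_mb` is `(end - start)/1e6` rounded to two decimals.  Whether the
original threshold was applied to raw or smoothed indices is not stated;
we threshold the smoothed track — matching the way the threshold line is
drawn over a smoothed index plot — and expose `smoothed = FALSE` to
threshold raw points instead.  Region calling is monotone: raising the
threshold never enlarges a region (tested).

## Segregation statistics

`chiSquareGof()` implements the 1-df goodness-of-fit statistic with the
Yates continuity correction and a floor at zero,
$\chi^2 = \sum_i \max(|O_i - E_i| - 0.5,\, 0)^2 / E_i$.
The correction is on by default because it is demonstrably what the
original analysis used: 321:89 vs 3:1 gives 2.198 corrected but 2.371
uncorrected, and 18:20 vs 1:1 gives 0.026 corrected but 0.105 uncorrected —
only the corrected values match the published table.  For the allelism-test
counts 77:23 vs 3:1 the corrected statistic is 0.12; the source labels that
number a *P* value, but 0.12 is the statistic itself (the p-value is
~0.73), a conflation we note rather than resolve.  Only two-class ratios
(df = 1) are supported; the uncorrected branch is cross-checked against
`stats::chisq.test` in the tests.

`checkRecessiveCosegregation()` encodes the KASP validation logic for a
recessive mutation: consistency requires every mutant-phenotype plant
homozygous mutant and every wild-type-phenotype plant heterozygous or
homozygous wild type; discordant plant ids are listed.

## Consequence annotation

`classifyEffect()` reproduces the reasoning that connects a splice-site
transition to a truncated protein.  A SNP within 2 nt of either intron end
(the GT/AG dinucleotides) is taken to abolish splicing of **that intron
only**; the retained intron is left in the transcript and translation is
re-run from the start codon through the full downstream sequence, so a
frameshifted read-through finds its new premature stop wherever it falls.
`frameshift` is true when the retained length is not divisible by 3; an
in-frame, stop-free retention preserves the downstream protein (tested).
Exonic substitutions re-translate the mutated CDS and classify as
stop_gained / missense / synonymous / start_lost.  Two classes extend the
obvious set: `noncoding_exonic` (exonic but outside the CDS) and
`stop_lost` (the terminal stop destroyed), because forcing those cases into
neighbouring classes would break the length invariants.  Single-intron
retention is the only splicing failure modelled — EMS produces point
transitions and the motivating observation was retention of one intron;
exon skipping and cryptic splice sites are out of scope.  Classification is
deterministic and strand-symmetric (a mirrored gene on the opposite strand
yields identical calls; tested on mirrored fixtures).

## What the simulator emulates — and what it does not

`simulateBulkSegregant()` draws EMS sites as a Poisson process (default
5 mutations/Mb over 2 chromosomes x 10 Mb, ~100 sites — an
order-of-magnitude convention, exposed in `SimParam()`), all G>A or C>T on
the reference strand, with a causal G>A mid-chromosome.  F2 plants are two
independent F1 gametes; gametes recombine by Poisson crossovers under the
Haldane map at 3 cM/Mb (a typical plant genome density); plants enter the
pool only if homozygous mutant at the causal site, until the 30-plant bulk
is filled.  Read sampling is Poisson depth (bulk 50x, parents 30x,
roughly the coverage of the motivating experiment) with binomial allele
counts at error-perturbed frequencies $f(1-e) + (1-f)e$, default
$e = 0.001$.  Genotypes are called by majority with a het call at >= 20%
minor reads, and GQ is synthesised as `min(99, 4 x depth)` — both simulator
conventions, not claims about any particular variant caller.

The simulator deliberately omits: alignment and mapping artefacts,
reference bias, indels, depth heterogeneity along the genome, linked
selection other than at the causal locus, and phenotyping error.  Passing
tests therefore show the *statistical* machinery is correct under the
stated genetic model; they do not certify behaviour on real alignments, and
the field-scale counts of the motivating study (millions of raw SNPs,
hundreds surviving filtration) are not reproducible without re-processing
raw reads, which is outside desk scale by design.

## Problem sizes and determinism

The shipped tests and the acceptance script use: exhaustive enumeration for
all rule truth tables; 400–1000 randomised records against the per-record
filter oracle; 1000 pooled chromosomes per recombination fraction for the
$1 - r$ law (3-SE bands); and 100 seeded end-to-end simulations at the
default scale for causal-locus recovery — sizes chosen so a full run
completes in a few minutes while keeping Monte-Carlo bands tight.  All
randomness funnels through explicit seeds (`SimParam@seed`,
`withr::with_seed`), so a fixed seed reproduces every output byte for byte.

## Known limitations

Single-gene, single-mRNA gene models only; two-class segregation ratios
only; no confidence bands on the SNP index under the null (the design uses
a fixed 0.80 threshold); biallelic SNPs only, with multiallelic sites
dropped at read time; no BAM/FASTQ handling — the pipeline starts from a
VCF.
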