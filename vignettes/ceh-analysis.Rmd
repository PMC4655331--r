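---
title: "Characterizing conserved extended MHC haplotypes with cehkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing conserved extended MHC haplotypes with cehkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cehkit)
```

## The problem

Conserved extended haplotypes (CEHs) are stretches of the human MHC,
often several megabases long, in which a particular combination of HLA
alleles travels with an essentially fixed chromosomal background.
Unrelated individuals homozygous for the same CEH are nearly identical at
the sequence level across the region, which makes the haplotype easy to
recognize but hard to dissect: the extreme linkage disequilibrium means
association signals cannot be localized within it. The leverage comes
from the *intra*-CEH variants — the few dozen positions at which
chromosomes carrying the same CEH differ. `cehkit` implements the full
desk workflow for finding and exploiting them: locating the conserved
region, cataloguing variation within and between haplotypes, quantifying
diversity and haplotype age, screening variants against expression
phenotypes through LD structure, placing haplotypes on a tree, and typing
the RCCX copy-number module.

This vignette explains the models and rules each stage implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was open.

## Coordinates and data model

All internal coordinates are 0-based half-open; conversion to and from
1-based happens only at the VCF boundary. A sample's data is a
`DiploidCallset`: a sorted table of site calls (two allele tokens,
a 3-level confidence of `high`/`low`/`nocall`, a phased flag) plus
no-call tract intervals. Positions not listed and not inside a tract are
homozygous-reference at high confidence — the convention of variant
files. Indels are reduced to a minimal left-trimmed representation on
read and carried as `ins:<seq>` / `del:<len>` tokens so that intra- and
inter-haplotype catalogues compare events stably. Confidence is an enum
rather than a score because the upstream assemblers' thresholds are not
re-derived here: the VCF `FILTER` column is taken at face value.

## Homozygosity mapping

`window_zygosity_profile()` tiles the region with 5-kb windows anchored
at the region start (the anchoring is configurable; results are
insensitive to it at the stretch scale) and counts homozygous and
heterozygous variant calls. The segmentation statistic is the zygosity
SNV ratio `n_hom / (n_hom + n_het)`. Two choices matter:

* **Empty windows pass.** The ratio is undefined with no variant calls,
  and a maximally conserved region is exactly one with no variants, so
  absence of data is treated as evidence of conservation rather than
  failure.
* **Indels are excluded from the ratio by default** (`include_indels`
  flips this); the statistic is defined on SNVs.

`call_conserved_stretches()` then reports maximal window runs containing
no more than 4 consecutive failing windows (ratio defined and < 0.95),
trimmed so both boundaries are passing windows — trimming gives
conservative bounds where the convention is otherwise unstated.

`roh_scan()` is a from-scratch runs-of-homozygosity scan honoring four
parameters in bp terms: 50-kb sliding windows, ≤3 heterozygous calls per
window, ≤50-kb gaps between informative sites, ≥1-Mb segments. (Common
ROH tools mix SNP-count windows with kb windows; here everything is in
bp, which is the form in which the parameters are usually reported.) A
segment is valid iff no four heterozygous calls inside it span less than
the window width; the implementation is a two-pointer sweep whose output
is tested for equality against exhaustive interval enumeration. The scan
expects dense, array-like callsets that include homozygous-reference
sites — sparse variant-only callsets carry no information about
inter-site homozygosity.

## Consensus and variant catalogues

Each diploid genome contributes two haploid chromosomes
(`split_haploids()`): phased heterozygous sites split by phase; unphased
ones split by the deterministic convention *first listed allele →
chromosome 0* and are flagged. Within a CEH the heterozygous sites are
isolated singletons (~5–9 per 100 kb), so the arbitrary phase of a
flagged site does not affect any statistic computed downstream — no two
flagged sites need to be phased relative to each other.

`build_consensus()` applies two distinct rules, kept deliberately
separate:

* a position where **two or more** haploids are ambiguous or
  low-confidence is no-called (`N`) in the consensus;
* an alternate allele carried by **two or more** haploids is recorded as
  a called consensus-level variant against the reference.

A 3–3 tie among six haploids is no-called and flagged ambiguous — the
conservative reading of a majority rule. The intra-CEH catalogue
(`intra_ceh_catalog()`) uses a weaker criterion on purpose: *any*
position where more than one distinct allele occurs among fully
high-confidence haploids is a record, because intra-CEH variants are
overwhelmingly singleton-heterozygous and would vanish under a ≥2 rule.
The comparable length *L* excludes every position that is no-called or
low-confidence in any compared sequence, and all masked-tract width.

`shared_segment_scan()` reports every maximal run of SNP indices with at
most `max_mismatch` disagreements between a query allele profile and one
or two reference profiles; maximality is two-sided and the output equals
brute-force enumeration on small inputs.

## Diversity, feature classes and haplotype age

The headline diversity statistic is defined as **π = S / L**: segregating
SNV count over comparable length. This is the per-base density of
segregating sites (for two sequences it coincides with canonical π; for
cohorts it is a segregating-site density, and the canonical
average-pairwise statistic is available separately as
`pairwise_nucleotide_diversity()`). The definition is kept because it is
the arithmetic that reproduces the published intra-CEH values
(238/2,720,646 = 8.75×10⁻⁵; 293/4,135,945 = 7.08×10⁻⁵). Note the A33
cohort's published SNV count appears both as 290 and 293 in different
places in the source material; π reproduces exactly with 293, and both
numbers are simply carried as-is.

Feature annotation translates coding SNVs on the coding strand
(synonymous / missense / nonsense; indels frameshift iff length mod 3 ≠
0) and otherwise classifies by interval precedence **coding > UTR5 >
UTR3 > ncRNA-exonic > intronic > promoter > intergenic**, taking the
highest-precedence class across overlapping genes — the convention of
standard annotators. The promoter is a strand-aware 1-kb window upstream
of the TSS by default; the size is configurable since published analyses
rarely state it.

Haplotype age uses a star genealogy: *n* haploid chromosomes descending
independently from the founder for *T* generations carry
*E[S] = n·μ·T·L* mutations, so

> *T* = ⌊ *S* / (*n·μ·L*) ⌋,  age = *g·T* years

with defaults μ = 1.1×10⁻⁸ /site/generation, *g* = 20 years, *n* = 6.
The floor on the generation count (rather than rounding) is part of the
estimator's definition here: it is the only inversion consistent with
the published age values this package reproduces
(238 → T = 1325 → 26,500 y; 293 → T = 1073 → 21,460 y), and is
documented as reverse-engineered. Under the same star model the
parameter-recovery test plants mutations at rate *n·μ·T* and checks the
estimate falls in the Poisson band of *S*.

## LD blocks and regulatory screening

`pairwise_r2()` computes *D = p~AB~ − p~A~p~B~* and
*r² = D²/(p~A~q~A~p~B~q~B~)* from pairwise-complete rows of a phased 0/1
matrix; monomorphic sites have undefined r² and are flagged. An **LD
block** is a maximal contiguous run in which *every* pairwise r² strictly
exceeds 0.8 — the all-pairs definition, not the confidence-interval
method of GUI tools; strict inequality at the threshold, so an exact 0.8
breaks a block. The greedy left-to-right search (leftmost maximal run
wins, scanning resumes after it) is deterministic and tested against
exhaustive enumeration for ≤25 sites. Block/haplotype operations require
phased input; a two-locus EM estimator (`em_haplotype_freqs()`) is
provided as a utility for unphased r² but is intentionally not used by
the block caller, which avoids re-implementing full phasing.

`cosegregation_screen()` returns the sites whose alleles partition two
phenotype classes perfectly — no overlap and no missing data. With small
cell-line panels this is a deterministic filter, not a statistical test;
candidates still require functional follow-up. `delta_ct_expression()`
implements 2^−ΔCt quantification with a 35-cycle detection limit by
default (configurable; the limit is an assay property, not a constant of
nature).

## Phylogeny

SNP alignments encode homozygous calls as their allele symbol and
heterozygous, low-confidence and no-call sites as missing data. K2P
distances separate transition (*P*) and transversion (*Q*) proportions
over pairwise-complete sites:
*d = −½ ln((1−2P−Q)·√(1−2Q))*, flagged saturated when a log argument is
non-positive. Trees are neighbor-joining on those distances — a
deliberate substitution for likelihood tree search: for the near-clonal
haplotypes this package targets, distance and likelihood methods give
the same groupings, and topology claims are only ever tested on
synthetic data with planted truth. Negative NJ branch lengths are
clamped to zero and flagged. Bootstrapping resamples columns with
replacement (missing data travels with its column); replicates whose
resampled distance matrix is non-finite are skipped and excluded from
the support denominator, and the number of evaluated replicates is
reported.

## RCCX copy number

Relative quantification assumes 100% amplification efficiency
(configurable): copies = 2·2^−ΔCt against the single-copy-per-chromosome
RP1 anchor. A single shared linear calibration `true = a·measured + b`
is fitted across reference samples by least squares — fitted in the
prediction direction, since its purpose is assignment — correcting the
intrinsic underestimation of the relative step. Integers are assigned by
nearest-integer rounding (ties at .5 up, floored at zero) and validated
against the identity **C4A+C4B = C4L+C4S = TNXA+2**.

A note on noise: with triplicate wells at replicate sd σ cycles, the
mean ΔCt has sd σ√(2/3) and a *c*-copy gene is mis-rounded when the ΔCt
error exceeds log₂((c+0.5)/c) ≈ 0.72/*c*. At σ = 0.15 a 4-copy gene sits
only ~1.4σ from its rounding boundary and is mis-assigned ~14% of the
time — no assignment rule can avoid this. The recovery tests therefore
run at σ = 0.05, typical of careful SYBR triplicates, where all copy
numbers up to 4 are ≥4σ from their boundaries.

## The synthetic generators

`simulate_ceh_cohort()` plants structure directly rather than simulating
genealogies: one founder haplotype shared by all individuals (differing
from the reference at 2.2×10⁻³ homozygous sites per bp, the observed
scale of between-haplotype divergence in the MHC), Poisson-placed
singleton variants at 8.6 SNVs/100 kb with an indel:SNV ratio of 52:290,
99% of them heterozygous within a single carrier, an optional
hyper-variable cluster window holding 72% of the variants in 120 kb,
per-individual heterozygous flanks (100 hets/100 kb) delimiting the
conserved core, no-call tracts, and per-site genotyping error. These
defaults are the study conditions the package's tests run under; indel
lengths are uniform 1–10 bp (the distribution is rarely reported and is
exposed as a parameter). A single seed fans out to per-component child
seeds so adding a generator never perturbs existing streams.

`simulate_population_haplotypes()` draws each chromosome's haplotype per
block from the block's frequency table, coupling adjacent blocks through
a per-chromosome uniform draw (inverse-CDF coupling) redrawn with
probability `recomb_between` at each boundary. This is a *planted*,
single-generation panel: crossover probability *r* leaves residual
inter-block correlation (1−*r*), so fully independent blocks require
*r* = 1 rather than 0.5 — unlike a population at recombination–drift
equilibrium, where any recurrent recombination eventually decouples
blocks. The tests assert the planted-panel arithmetic (r² ≈ (1−r)²
between complementary-haplotype blocks).

What the generators do **not** emulate: coalescent genealogies and
recombination graphs, sequencing-depth-dependent error, reference
alignment artefacts, structural variation beyond short indels, and
population stratification. Passing recovery tests therefore demonstrate
that the estimators invert the generative model they assume — not that
real cohort data meet those assumptions.

## Numerical choices and degenerate inputs

* Zygosity ratio in an empty window: `NA`, window passes.
* Consensus ties: no-call plus an ambiguous flag.
* Monomorphic sites: r² undefined and flagged; undefined never exceeds a
  block threshold.
* K2P saturation: `d = Inf`, flagged; `nj_tree()` refuses non-finite
  matrices.
* Copy assignment: ties at .5 round up; negatives floor at 0.
* π with `L = 0` and ages with invalid parameters are errors, not NaNs.
* All simulators are byte-reproducible under a fixed seed.

## Problem sizes in the test suite

The recovery tests run on 1.5–4-Mb simulated regions with three
individuals, 10,000-chromosome LD panels over ≤25 SNPs, 1,000 annotated
CDS variants, 1,000 simulated qPCR samples and ≤12-taxon trees; the full
suite completes in well under two minutes on one core. These sizes were
chosen so that every stochastic check sits inside a 95–99% band of its
planted parameter with comfortable margin, and the one place a fixed
seed initially produced a legitimate 0.5%-tail Poisson draw, the test
pools four independent cohorts instead of re-rolling the seed.

## Known limitations

* Intra-CEH catalogues assume the cohort shares one founder; mixtures of
  sub-haplotypes inflate the catalogue (by design — that is the signal
  the hyper-variable cluster analysis looks for).
* The co-segregation screen requires perfect partitions and is sensitive
  to single genotyping errors at small sample sizes.
* The star-genealogy age ignores purifying selection, gene conversion
  and the variance of the founder's own age; its confidence is bounded
  below by Poisson noise in *S*.
* The block caller requires phased panels; unphased data can be screened
  pairwise with the EM utility but not segmented into blocks.
* Long/short module phase within a chromosome (which chromosome carries
  which C4 form) is not determinable from counts alone.
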