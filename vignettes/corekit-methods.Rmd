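---
title: "Methods: germplasm core selection, diversity statistics and breeding fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germplasm core selection, diversity statistics and breeding fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corekit)
```

corekit implements the computational chain used when a large crop germplasm
panel (here modelled on a lettuce collection of eight horticultural types)
is reduced to a core collection, characterized genetically and
phenotypically, scanned for marker–trait associations, and finally used for
genomic-design breeding with a parental-origin fingerprint of the derived
line. This vignette explains each model, the tunable parameters, and the
design choices made where conventions differ between tools.

## Genotype container and variant filters

Genotypes are diploid biallelic SNPs stored as alternate-allele dosages 0/1/2
with `NA` for missing, sorted by (chromosome, position). VCF 4.x input is
parsed with vcfR; multiallelic records are skipped with a count. The writer
emits a minimal GT-only VCF 4.2 with `##contig` lengths so a write/read
round-trip is exact. Coordinates are 1-based inclusive externally; window
arithmetic uses a half-open grid anchored at position 1 internally.

`filter_variants()` keeps a site iff MAF ≥ `maf_min` (computed from
non-missing alleles only) and missing fraction < `miss_max`. Resequencing
panels of this kind typically filter at MAF ≥ 0.05 with missingness < 0.10
for population-genetic inference and MAF > 0.1 for association scans; both
thresholds are parameters because the two stages legitimately differ.

`ld_prune()` mirrors the common `--indep-pairwise` procedure (20 kb window,
5-site step, r² > 0.2 by default). The pair member dropped is the one with
the higher missing rate, then the later position — a fixed tie-break chosen
for reproducibility. After the stepped greedy pass, a step-1 sweep repeats
to a fixed point, so the output *provably* contains no in-window pair above
the threshold regardless of step size (a guarantee the stepped heuristic
alone does not give).

## Core selection by allele-state coverage

Coverage of a subset is the fraction of (site, dosage-state) pairs of the
full panel also observed in the subset — marker-state coverage computable
from dosages alone, matching the semantics of coverage-based core-selection
tools. `greedy_core_select()` seeds breeding-priority accessions first, then
repeatedly adds the accession with the largest coverage gain (ties by
accession id), stopping at the coverage target, when the marginal gain drops
below `delta_min` (0.0001 reproduces a "0.01 % minimum gain" rule), or on
exhaustion.

Greedy maximum-coverage is the field's standard because exhaustive subset
search is exponential; on panels small enough to enumerate it usually — but
provably not always — finds the minimum-cardinality subset for a 95 %
target. Tests therefore verify the greedy contract (monotone coverage,
target reached, never better than the exhaustive optimum, within one
accession of it on small panels) rather than pretending the heuristic is
exact. On simulated structured panels a minority of accessions reaches 99 %
coverage, the qualitative behaviour that motivates core collections.

## Population-genetic statistics

*Nucleotide diversity.* Per-site π is the expected pairwise difference among
the 2n called alleles, x(2n−x)/C(2n,2); window values divide the summed site
π by the window span in bp (invariant sites contribute zero), on a sliding
grid with 100-kb windows and 10-kb steps by default — both are parameters
since published scans use either 100-kb/10-kb or plain 10-kb windows. The
last partial window is normalized by its true span.

*F_ST.* Weir & Cockerham (1984) per-site components with ratio-of-sums
aggregation Σa/Σ(a+b+c) per window and genome-wide, the estimator of the
common VCF toolkits; negative windows are reported as computed. The
estimator is validated to 10⁻¹⁰ against a scalar, term-by-term test-only
implementation, and recovers the Balding–Nichols drift parameter of the
simulator within ±0.02.

*LD decay.* r² is the squared Pearson correlation of dosage vectors
(composite LD; the data are unphased). The decay curve bins all
intra-chromosomal pairs by distance; the half-decay distance is the first
point where mean r² falls to half the observed maximum, linearly
interpolated. Because the maximum is measured at the first bin midpoint m0,
the analytic truth for the copying-process simulator (r²(d) = exp(−2d/τ))
is m0 + (τ/2)·ln 2, which the estimator matches within sampling error.

*Relatedness.* The GRM is VanRaden-standardized with per-site mean
imputation of missing calls; PCA takes the top eigenpairs of the GRM (these
PCs are also the stratification covariates of the association scan). The
IBS distance is 1 − mean((2 − |d_j − d_k|)/2). Neighbour joining uses
Saitou–Nei agglomeration via ape, with negative branch lengths clamped to
zero and the deficit moved to the sibling edge.

## Ordinal trait statistics

Traits are ordinal class codes 1..10 recorded per accession × year ×
replicate. Replicates are aggregated to the per-accession modal class with
ties resolved to the lower code (descriptor conventions do not state an
aggregation; the modal rule is deterministic and robust to single
mis-scores). Class codes are treated as numeric for correlations, Euclidean
distances and PCA — exactly how published trait matrices of this kind are
analysed — and traits are z-scored before distances because class ranges
differ (2–10).

The Shannon–Wiener index uses the natural logarithm,
H′ = −Σ p ln p over non-zero classes with percentages renormalized to 1.
The ln convention is validated against the published worked rows: a
two-class row at 50.79/49.21 % gives 0.69 nats only under ln. Recomputing
H′ for all 32 published trait-year rows reproduces the printed column at
2 dp in every row, and the printed 0.40–2.15 range is the min/max of the
recomputation.

Broad-sense heritability fits class ~ (1|accession) + (1|year) +
(1|accession:year) by REML (lme4, the engine used for such trait tables)
and reports the accession-mean-basis ratio
H² = V_g / (V_g + V_gy/y + V_e/(ry)). Multi-year BLUPs come from
class ~ year + (1|accession); they are mean-zero shrinkage estimates used
as the multi-environment phenotype for association scans.

## Association scan, thresholds, inflation, clumping

The scan is a deliberately transparent per-marker OLS of phenotype on
intercept + dosage + leading GRM PCs, with a two-sided t-test on the dosage
coefficient, computed on the accessions called at that site; monomorphic
sites get p = 1 so indices stay aligned. It is a documented stand-in for
mixed-model scans: kinship-corrected solvers at millions of sites are out of
scope, and the PC adjustment reproduces the property that matters for the
synthetic end-to-end tests (stratification-driven inflation drops when PCs
are included). Null calibration is verified: permuted phenotypes give
uniform p-values and λ within [0.9, 1.1].

Significance thresholds follow the two closed forms used for dense scans:
−log10(1/N) ("permutation-style") and −log10(α/N) (Bonferroni); at
N = 3 842 327 and α = 0.05 these are 6.585 and 7.886. The genomic inflation
factor is the median implied χ²₁ statistic over its null median 0.45494.

QTL clumping merges significant SNPs (−log10 p ≥ 7 by default) on a
chromosome while consecutive gaps are ≤ 200 kb, reports regions with ≥ 3
significant SNPs, and takes the most significant SNP (ties to the smaller
position) as the lead. Published descriptions of this rule are sometimes
worded as "clustered if proximity > 200 kb"; the implementation splits at
gaps > 200 kb — the reading consistent with reported interval widths — and
both the gap and the density minimum are configurable ("more than three"
may be read as ≥ 3 or ≥ 4). The clumping is validated exactly against an
exhaustive gap-partition oracle.

## Fingerprint (bin) maps of biparental progeny

Informative sites are those where both parents are homozygous, called, and
divergent. Progeny calls at those sites decode to parent-1, parent-2 or
heterozygous origin; anything else is missing (impossible dosages are
counted). Sites are grouped in non-overlapping 1-Mb bins anchored at
position 1 (chromosome lengths from the VCF contig header, else the maximum
observed position); the majority class wins the bin, empty bins are
MISSING, exact ties AMBIGUOUS (the vote rule is silent on ties; AMBIGUOUS
keeps them visible instead of inventing a winner, and downstream breakpoint
logic skips them). Breakpoints are emitted between consecutive differing
called bins, with skipped MISSING/AMBIGUOUS spans annotated.

A majority-vote bin map cannot depict a parental segment shorter than about
one bin — the vote swallows it. Recovery tests against the simulator's
truth therefore demand ≥ 95 % correct bin calls and exact matching (within
one bin) of every crossover whose flanking true segments both span ≥ 2 Mb;
shorter-range junctions are below the method's resolution by construction.

## Synthetic data: what it emulates and what it does not

`simulate_structured_population()` draws founder allele frequencies from
Uniform(0.05, 0.5) — the post-filter MAF regime of a resequenced panel —
and drifts each subpopulation with a Balding–Nichols reparameterization so
the drift parameter is the expected F_ST; genotypes are Hardy–Weinberg
draws and missingness is uniform at random (no published missingness
mechanism to copy). Subpopulations are labelled with horticultural types,
wild last, so type-specific diversity gradients (wild > looseleaf >
stem/oilseed) are emulated by giving derived types stronger drift.

`simulate_traits()` builds a normal liability genotype value + year effect
+ genotype-by-year + residual, rescales the genotype value to V_g and
solves V_e from the accession-mean H² identity for the configured design
(y years × r replicates), then cuts the liability at the quantiles of the
configured class probabilities (equal by default; skew them to mimic
descriptor tables dominated by one class). Defaults are 5 classes (the
middle of the 2–10 range of real descriptors), 2 years × 3 replicates
(matching a two-season trial with three biological replicates). Ordinal
discretization costs a few points of recovered H², which the ±0.1 recovery
tolerance absorbs.

`simulate_biparental_cross()` makes an F1 from two inbred parents and selfs
it for `n_selfing_generations` (default 5, i.e. an F5-derived line with
expected residual heterozygosity 2⁻⁵ ≈ 3.1 % per informative site, which
the simulation reproduces), with Poisson crossovers (mean 1.5 per
chromosome per meiosis) at uniform positions and full truth segments
returned per homolog.

None of the generators model coalescent linkage structure (except the
dedicated two-ancestor copying process used for LD-decay validation),
selection, sweeps, or epistasis. Passing tests on these panels validate the
estimators and the pipeline logic; they do not certify behaviour on real
panels with complex LD, related accessions, or informative missingness.

## Problem sizes, numerical choices, limitations

Test and demo problem sizes are desk-scale by design: a few hundred
accessions and 10² –10⁴ sites, where every estimator can be checked against
brute-force enumeration (π, F_ST, clumping), closed forms (thresholds,
selfing series, LD half-decay) or parameter-recovery simulations
(heritability, F_ST drift, planted QTLs). The headline numbers of real
panels of this type (millions of SNPs, 200-kb LD decay, specific QTL
tables) require the unreleased raw data and are out of desk-scale reach;
what is reproduced exactly are the published worked values: the Shannon
index rows, their 0.40–2.15 range, and the two significance thresholds.

Numerical conventions worth knowing: REML fits are lme4 defaults with
convergence chatter silenced (variance components are still returned);
H² is clamped implicitly to [0, 1] by the nonnegative variance components;
eigenvalues of the GRM may be tiny negatives (−10⁻⁸ tolerated as PSD);
p-values of 0 are floored at the smallest positive double before the
−log10 transform; all simulators route randomness through one integer seed
and restore the caller's RNG state.
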