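---
title: "Detecting heterozygosity-rich regions, autozygosity and balancing selection with hetscan"
author: "hetscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting heterozygosity-rich regions, autozygosity and balancing selection with hetscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetscan)
```

## Overview

`hetscan` implements a population-genomic workflow for dense SNP-array
genotypes from structured populations (its defaults are tuned to dog
breeds: 38 autosomes, roughly 15 kb marker spacing, 20 animals per
breed). The workflow asks whether stretches of unusually *high*
heterozygosity — heterozygosity-rich regions, HRRs — recur at the same
genomic positions across many individuals and breeds, and whether those
positions coincide with signatures of balancing selection measured by
windowed Tajima's D. Runs of homozygosity (ROH), the mirror image of
HRRs, are called with a model-based homozygous-by-descent (HBD) hidden
Markov model so that islands of homozygosity in one breed can be
compared with islands of heterozygosity in another.

The pipeline stages are:

1. **QC** — two tiers. Tier 1 removes markers and then samples with more
   than 10% missing calls and optionally subsamples each breed to 20
   animals by greedy kinship pruning; it feeds run detection and island
   calling. Tier 2 additionally removes markers with minor allele
   frequency below 0.01 and feeds Tajima's D and F~ST~. Run-based
   statistics never see the MAF filter, because removing rare variants
   would bias heterozygosity downward inside runs; frequency-spectrum
   statistics always do.
2. **HRR detection** (`detect_runs`) — consecutive-runs scanning.
3. **HBD model** (`hbd_segments`) — model-based ROH.
4. **Islands** (`islands_by_breed`) — breed-level HRRI/ROHI calling.
5. **Selection scan** (`window_stats_by_breed`, `threshold_signals`).
6. **Cross-breed accounting** (`hot_spots`, `count_overlaps`,
   `breed_factor_anova`, `pairwise_fst`).

`run_pipeline()` orchestrates all stages from one configuration and
writes every table as TSV plus a provenance record.

## The consecutive-runs scanner

For one individual and chromosome, an interval of consecutive markers
`[i..j]` is a *feasible* HRR when six clauses hold: (a) markers `i` and
`j` are heterozygous and called; (b) at most `max_opposite` homozygous
calls lie inside; (c) at most `max_missing` missing calls lie inside;
(d) no adjacent-marker gap inside exceeds `max_gap_bp`; (e) the interval
has at least `min_snp` markers; and (f) spans at least `min_length_bp`
(measured as `bp(j) − bp(i)`). The defaults — 20 SNPs, 50 kb, 50 kb gap,
3 homozygous, 1 missing — are the standard settings for array data of
this density: the SNP minimum protects against false positives in short
windows, and allowing three opposite calls accepts regions that are
*predominantly*, not perfectly, heterozygous.

`detect_runs` emits **all inclusion-maximal feasible intervals**. This
definition is exactly testable: a brute-force enumerator that checks
every `O(m²)` interval and keeps the maximal ones must agree exactly,
and the test suite asserts set equality on hundreds of random instances.
Maximal intervals may overlap (two windows can spend their
opposite-call budgets differently); the per-SNP coverage that all
downstream statistics consume is their union, and `merge_runs()`
consolidates them per individual when the run itself is the unit of
interest, e.g. for recovery scoring against planted tracts. Run
boundaries must be called, target-state markers — standard trimming, so
a run never starts or ends on evidence-free positions.

The same scanner runs in ROH mode (`run_params("ROH")`, defaults 1
heterozygous / 2 missing allowed) as a utility; the pipeline's ROH calls
come from the HBD model below.

## The HBD hidden Markov model

Autozygous segments are modelled with hidden states
`k = 1..K` (HBD classes with rates `R = 2, 4, 8, 16, 32, 64`) plus one
non-HBD class (`R = 128`). Between adjacent markers at genetic distance
`d` Morgans (physical distance times 1 cM/Mb, the conventional scale
when no genetic map is supplied) the chain either *stays* in its state
with probability `exp(−R_k d)` or *re-draws* a state from the mixing
distribution π. Higher rates mean shorter segments, so the class grid
spans recent to ancient inbreeding; rates are fixed and only π is
estimated, per individual.

Emissions at a marker with population (breed) alternate-allele frequency
`p`: HBD classes emit a homozygote for an allele drawn at frequency `p`,
contaminated toward Hardy–Weinberg proportions with error probability
`ε = 0.001` (so `P(het | HBD) = ε·2p(1−p)`); the non-HBD class emits
Hardy–Weinberg genotypes; missing genotypes emit 1 in every state.
Breed frequencies used inside the model are shrunk by a half count,
`(x + 0.5)/(2n + 1)`, so markers monomorphic within a breed keep
emissions strictly positive.

The scaled forward–backward pass exploits the stay/re-draw structure for
`O(states)` updates per marker and is implemented in C++; an
exhaustive-path oracle (summing all `K^T` paths on tiny instances)
pins its exactness to `1e−8` in log-likelihood.

**EM update.** Because π parameterises the transitions as well as the
initial state, the textbook "occupancy" update
`π_k ∝ Σ_t γ_t(k)` is not an EM step for this model and can decrease
the likelihood. `fit_mixing_em` therefore uses the exact closed form on
the augmented representation: `π_k` is proportional to the expected
number of *draws from π* that land in state `k` (the first marker plus
every re-draw transition), computed from the forward–backward
quantities. This is provably monotone, and the tests assert a
non-decreasing log-likelihood trace on every fitted individual. Note
the fitted `π_HBD` is a per-draw weight, not the autozygous genome
fraction: one long HBD segment competes with many short non-HBD draws,
so the genome fraction is read from the mean posterior HBD probability
instead (the tests recover a planted 20% autozygous genome to within
one percentage point).

Markers with summed HBD posterior at or above 0.5 form ROH segments
(`call_hbd_segments`); 0.5 is the conventional posterior decision
threshold and the calls are insensitive to it when posteriors are
confident, as they are on planted tracts (mean in-tract posterior
≥ 0.93 in the seeded tests).

## Islands

For each breed, `snp_share_frequency` computes per marker the fraction
of individuals whose runs cover it (each individual counts once). The
island threshold is the 99.9th percentile — "top 0.1%" — of the breed's
genome-wide per-SNP sharing frequencies, with linear interpolation
between order statistics (R's default quantile type 7, fixed for
determinism). Islands are maximal stretches of consecutive markers
within a chromosome at or above the threshold (and strictly above
zero), with at least 2 member SNPs. The percentile is taken over *all*
markers, zero-sharing markers included; a guard refuses to call islands
when the threshold itself is zero, since an all-zero profile would
otherwise flag the entire genome.

A consequence worth knowing: when tracts are shared by a fixed carrier
fraction (say 0.8 of a breed), the genome-wide percentile lands exactly
on that plateau, so an island ends wherever a single carrier's run
fragments (two missing calls in a row are enough to split a run, and
sub-minimum fragments are discarded). Island calls are therefore
conservative *cores* of shared tracts — in the seeded validation every
planted tract yields exactly one island and no island appears outside a
tract, but island boundaries sit inside the tract boundaries.

## Windowed Tajima's D

Per breed, sites are binned into non-overlapping 250 kb windows anchored
at position 0. With `n_s` called chromosomes and alternate count `x` at
a site, the site contributes `2x(n_s − x)/(n_s(n_s − 1))` to window π
(the unbiased per-site heterozygosity, equal to the average pairwise
difference among sampled chromosomes) and counts toward `S` when
`0 < x < n_s`; sites with fewer than 4 called chromosomes are ignored.
Then

`D = (π − S/a1) / sqrt(e1·S + e2·S(S−1))`

with the standard constants at `n` = the rounded median of `n_s` over
the window's segregating sites — a documented approximation for
missing-data windows; with complete data it is exact and the tests
check π and D against an explicit all-pairs difference oracle at
`1e−10`. Windows with `S = 0` have undefined D and are excluded from
thresholds. Balancing-selection signals are, per breed, windows in the
top 0.1% of the genome-wide distribution of defined D values, with an
explicit positivity guard: the target is an excess of
intermediate-frequency variants, so non-positive D never qualifies no
matter how degenerate the breed's distribution is. Ties at the
threshold are all kept.

## Cross-breed statistics

**Hot spots.** Islands (or signal windows) from all breeds are swept
into maximal regions with a constant set of supporting breeds; each
region's breed count `k` is standardised over the region set
(`z = (k − mean k)/sd k`) and regions with `z ≥ 1.645` (one-sided
p < 0.05) are significant, adjacent significant regions being merged
with their breed sets unioned. With the study-scale breed counts this
reproduces the familiar "shared by at least seven breeds" style of
cut-off; the package keeps the z rule rather than a hard count so the
cut-off adapts to the number of breeds analysed.

**Overlaps.** One record per (HRR island, signal window) pair of the
same breed on the same chromosome with at least 1 bp intersection,
inclusive coordinates. Same-breed counting matches the per-breed
presentation of such overlaps; a cross-breed mode is available behind a
flag because the aggregate wording is ambiguous in parts of the
literature.

**ANOVA.** To ask whether breed factors (geographic origin, breed
purpose, genetic cluster) shape where signals recur, each (region,
supporting breed) incidence becomes one observation with response = the
region's breed count and group = the breed's factor level, analysed by
classical one-way ANOVA (`stats` F-test) with `R² = SS_between /
SS_total`. This coding is interpretive — region/breed incidences are
not independent — so the package reports it as descriptive, records the
coding in the provenance file, and makes no causal claim.

**F~ST~.** Pairwise Weir–Cockerham (1984) estimates: per locus the
variance components `a`, `b`, `c` for two populations from sample
sizes, allele frequencies and heterozygote frequencies, then the
multi-locus ratio of sums `θ̂ = Σa / Σ(a+b+c)` over loci where both
breeds have calls and the pooled frequency is polymorphic. Negative
estimates are reported unclipped; fixed differences give exactly 1, and
splitting one sample into identical halves gives `θ̂ ≤ 0` (the
finite-sample correction is then strictly conservative) — both are
asserted in the tests.

## The synthetic-data generator

`simulate_dataset` is first-class, tested code and the validation
substrate for every stage. Ancestral alternate-allele frequencies are
drawn Uniform(0.05, 0.95) per SNP — mimicking the ascertained,
common-variant spectrum of genotyping arrays — and each breed's
frequencies diverge by a Balding–Nichols Beta draw at `F = 0.10`, a
typical between-breed differentiation for dogs. Background genotypes
are Hardy–Weinberg at the breed frequencies with a uniform 2% missing
rate; defaults are 3 breeds × 20 individuals on two 25 Mb chromosomes
at 15 kb spacing, sized for desk-scale validation while preserving the
marker density of the study design.

Three feature kinds are planted on top:

- **HRR tracts**: in a carrier fraction (default 0.8) of a breed's
  individuals, tract SNPs are heterozygous with probability 0.95,
  otherwise Hardy–Weinberg.
- **ROH tracts**: carriers receive a single allele drawn at the breed
  frequency, duplicated into a homozygote, with a 1% error rate.
- **Balancing windows**: window frequencies are redrawn
  Uniform(0.4, 0.6) for every breed and the Hardy–Weinberg heterozygote
  probability is inflated by 1.3 with renormalisation — one knob that
  raises both observed heterozygosity and Tajima's D.

Features of different kinds may not share SNPs (the generator refuses);
a fixed seed gives byte-identical output, and the generator restores
the caller's RNG state.

What the generator deliberately omits: linkage disequilibrium (sites
are independent given frequencies), recombination-rate variation, and
mutation–drift realism. None of the statistics in scope depend on LD —
runs, sharing frequencies, per-site π and WC components are all
computed marker-wise — so passing tests validate the *computations*,
not the realism of any coalescent process. Results on real data will
additionally reflect LD clumping of runs and array ascertainment
beyond what these simulations emulate; one visible consequence of the
array-like Uniform(0.05, 0.95) spectrum is that background Tajima's D
is positive on average, which is why signal thresholds are quantiles of
the realised distribution rather than absolute cut-offs.

## Problem sizes and numerical choices

The bundled demo (`demo_pipeline_config()`: 5 breeds × 20 individuals,
two 30 Mb chromosomes, ≈ 4,000 markers, planted tracts and balancing
windows) exercises every stage in about a minute and a half and
re-runs byte-identically; validation simulations for the selection scan
use 500 Mb / 2,000 windows, chosen so the top-0.1% quantile has
non-trivial resolution. EM uses tolerance `1e−6` on the log-likelihood
with a 200-iteration cap (30 in the demo, where posteriors saturate
long before); quantiles are always type 7; kinship pruning breaks ties
lexically by sample id so subsampling is deterministic. Genotype
orientation (which homozygote is code 0) is fixed by the first allele
observed in the input file and is immaterial to every statistic, all of
which are symmetric under allele relabelling — a property the tests
assert for runs, D and kinship.

## Worked example

```{r example, eval = FALSE}
library(hetscan)

cfg <- demo_pipeline_config(out_dir = "hetscan_demo", seed = 7)
res <- run_pipeline(cfg)

nrow(res$runs)        # HRR runs across 100 individuals
res$islands           # HRRIs and ROHIs per breed
res$signals           # top-0.1% Tajima's D windows per breed
res$overlaps          # same-breed HRRI x signal overlaps
res$fst               # pairwise Weir-Cockerham matrix
```

All tables are also written under `out_dir`, together with
`provenance.json` recording every parameter and interpretive decision.

## Known limitations

- No LD in simulations (see above); planted-tract recovery rates are
  upper bounds for real-data behaviour.
- Island calls are conservative cores when sharing plateaus at the
  percentile threshold (see Islands).
- The ANOVA observation coding treats (region, breed) incidences as
  exchangeable observations; its R² values are descriptive.
- The window-median chromosome count in Tajima's D is approximate under
  heavy, uneven missingness.
- Sex chromosomes, phased data, VCF and PLINK 2 formats are out of
  scope; positions are taken as given (no lift-over).
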