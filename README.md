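# hetscan

Detection of heterozygosity-rich regions, autozygosity and
balancing-selection signals in diploid SNP-array genotypes from
structured populations (dog breeds and similar).

## The problem

Runs of homozygosity (ROH) are well studied; their mirror image —
**heterozygosity-rich regions (HRRs)**, stretches of consecutive SNPs
that are predominantly heterozygous in one individual — are not. When
the same region is heterozygosity-rich in many individuals of many
breeds, one candidate explanation is **balancing selection**
(heterozygote advantage maintaining polymorphism), which leaves an
excess of intermediate-frequency variants detectable as positive
windowed **Tajima's D**. `hetscan` implements the full chain needed to
test that hypothesis on PLINK-format genotypes:

- two-tier QC (missingness 0.10 on both axes; MAF 0.01 for
  frequency-spectrum statistics only) with kinship-based subsampling to
  20 animals per breed;
- per-individual HRR detection by consecutive-runs scanning
  (defaults: ≥ 20 SNPs, ≥ 50 kb, gaps ≤ 50 kb, ≤ 3 homozygous and ≤ 1
  missing call per run), emitting all inclusion-maximal feasible
  intervals;
- model-based ROH via a homozygous-by-descent HMM with rate classes
  R = 2, 4, 8, 16, 32, 64 and a non-HBD class at R = 128, mixing
  proportions fitted per individual by a monotone EM;
- breed-level **HRR islands / ROH islands**: stretches of consecutive
  SNPs whose run-sharing frequency reaches the breed's top-0.1%
  (99.9th percentile), with ≥ 2 SNPs;
- per-breed Tajima's D in non-overlapping 250 kb windows,
  `D = (π − S/a₁) / √(e₁S + e₂S(S−1))`, with signals = the top 0.1% of
  positive-D windows;
- cross-breed **hot spots** (sweep-line regions whose supporting-breed
  count has Z ≥ 1.645), island × signal overlap records, one-way ANOVA
  of breed factors, and pairwise Weir–Cockerham F_ST;
- a seeded multi-breed simulator with planted heterozygous tracts,
  autozygous tracts and balancing windows, plus recovery scoring — the
  validation substrate for every stage.

## Worked example

```r
library(hetscan)

cfg <- demo_pipeline_config(out_dir = "hetscan_demo", seed = 7)
res <- run_pipeline(cfg)   # five breeds x 20, ~4,000 SNPs, ~90 s
```

The demo simulation plants, per breed, one 600 kb heterozygous tract
(carrier fraction 0.8), one 450 kb autozygous tract, a tract position
shared by all five breeds, and five balancing-selection windows. The
run above prints stage logs and returns the result tables, e.g.:

```
nrow(res$runs)                     # 291 HRR runs across 100 individuals
mean(res$runs$end_bp - res$runs$start_bp) / 1000   # 559 kb mean length
range(res$summaries$ho)            # observed heterozygosity 0.319-0.358

head(res$islands, 4)
#   breed island_type chrom start_bp  end_bp n_snp threshold_used
# 1   B01        HRRI     1  2085000 2430000    24            0.8
# 2   B01        HRRI     1  5010000 5565000    38            0.8
# 3   B02        HRRI     1  5145000 5565000    29            0.8
# 4   B02        HRRI     1  8070000 8595000    36            0.8

res$hot_spots$islands$hot_spots    # the tract shared by all five breeds
#   chrom start_bp  end_bp k              breeds        z significant
# 1     1  5175000 5355000 5 B01,B02,B03,B04,B05 1.831176        TRUE

head(res$overlaps, 3)              # HRRIs coinciding with D signals
#   breed chrom island_start island_end signal_start signal_end overlap_bp
# 1   B01     1      5010000    5565000      5000001    5250000     240001
# 2   B02     1      5145000    5565000      5000001    5250000     105001
# 3   B03     1     14010000   14595000     14000001   14250000     240001

round(res$fst["B01", "B02"], 3)    # 0.099, near the simulated F = 0.10
```

Each island's threshold (0.8) is the 99.9th percentile of that breed's
per-SNP sharing profile — here exactly the planted carrier fraction.
The hot spot is the one tract position planted in all five breeds, and
the overlaps show HRR islands coinciding with top-0.1% Tajima's D
windows in the same breed: the heterozygous tracts themselves carry an
intermediate-frequency spectrum, which is the association the method is
built to expose. All tables are also written to `out_dir` as TSV (and
BED for intervals) together with `provenance.json`.

A thin command-line front end over the same functions ships in
`inst/scripts/hetscan_cli.R`
(`Rscript hetscan_cli.R all --demo --out-dir out/`).

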