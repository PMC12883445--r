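# xhetkin

Sample-level quality control for sequencing studies, computed **directly
from VCF genotypes** — no alignment files required. `xhetkin` answers two
questions an analyst should settle before any downstream work: *does each
sample's X chromosome look like what its metadata claims?* and *are the
declared family relationships supported by the genotypes?*

It is aimed at groups running exome/genome cohorts (especially trios) who
want a first-pass screen for sex-label errors, sample mix-ups, duplicates
and pedigree inconsistencies, plus a way to investigate where artifactual
X heterozygosity in hemizygous samples comes from.

## The statistics

**Xhet.** On the non-pseudoautosomal portion of chromosome X
(chrX:2,781,479–153,925,834, the smallest interval excluding PAR1/PAR2
shared by GRCh37, GRCh38 and T2T), genotypes are restricted to
heterozygous (0/1) and homozygous-alternate (1/1) calls that pass
parametric filters (allele fraction > 0.25, depth > 20, optional GQ), and

```
Xhet = n_het / (n_het + n_homalt)
```

An XY sample is hemizygous on non-PAR X, so true heterozygosity is
impossible there: Xhet is near 0, and every residual het call is a
technical artifact (typically reads mis-mapped from paralogs or
pseudogenes). An XX sample shows substantially positive Xhet. A 1-D
two-means cutoff separates the clusters; samples are labeled `xx-like` /
`xy-like` / `ambiguous` (the labels describe the genotype pattern, never
reported sex).

**KING-robust kinship.** For every sample pair, over pairwise-complete
sites,

```
phi = (N_Aa,Aa − 2·N_AA,aa) / (N_Aa(i) + N_Aa(j))
```

where `N_Aa,Aa` counts sites with both samples heterozygous, `N_AA,aa`
opposite homozygotes, and `N_Aa(·)` each sample's heterozygote count.
Duplicates give phi = 0.5, parent–offspring ≈ 0.25, half-sibs ≈ 0.125,
unrelated ≈ 0; degrees are binned at the standard powers-of-two cutoffs
(0.354, 0.177, 0.0884, 0.0442).

**Pseudo-heterozygosity scan.** For hemizygous-expected samples, exonic
SNV het calls are tallied under inclusive variant-allele-fraction windows
(25–75, 33–66, 45–55 %), then aggregated per position, per gene (calls in
overlapping genes count in both) and per annotated region as calls/Mb —
the tool for locating recurrent mis-mapping sources on X.

A pedigree-aware simulator (`simulate_cohort()`) generates ground-truthed
cohorts — Hardy–Weinberg founders, sex-aware X transmission, Poisson
depth / binomial allele-depth read model, and injectors for swaps,
duplicates, contamination, X-homozygosity runs and trap-interval
pseudo-heterozygosity — and backs the entire test suite.

## Worked example

```r
library(xhetkin)

sim <- simulate_cohort(sim_config(seed = 1))   # two trios (mother/father/son)
xh  <- xhet_batch(sim$gm)                      # Xhet under AF > 0.25, DP > 20
xh
#>    sample n_het n_homalt       xhet af_min dp_min gq_min
#> 1 father1     6      496 0.01195219   0.25     20     NA
#> 2 father2    15      478 0.03042596   0.25     20     NA
#> 3 mother1   625      172 0.78419072   0.25     20     NA
#> 4 mother2   641      165 0.79528536   0.25     20     NA
#> 5    son1     5      491 0.01008065   0.25     20     NA
#> 6    son2    11      476 0.02258727   0.25     20     NA

cutoff <- unsupervised_threshold(xh$xhet)      # 0.4042
classify_sex(xh$xhet, cutoff, sample_id = xh$sample)$label
#> [1] "xy-like" "xy-like" "xx-like" "xx-like" "xy-like" "xy-like"

gmk <- missingness_filter(apply_call_filters(sim$gm), 0.2)
kin <- kinship_matrix(gmk, autosomes_only = TRUE)
subset(kin, sample_i != sample_j & degree == "first")[, c(1, 2, 8, 9)]
#>    sample_i sample_j     phi degree
#> 5   father1     son1 0.24881  first
#> 11  father2     son2 0.24752  first
#> 14  mother1     son1 0.24701  first
#> 18  mother2     son2 0.24067  first
```

The fathers and sons sit at Xhet ≈ 0.01–0.03 (hemizygous X: the residual
het calls are injected mis-mapping artifacts), the mothers at ≈ 0.79; the
two-means cutoff cleanly splits them. Kinship recovers exactly the four
declared parent–offspring pairs as first-degree (phi ≈ 0.25) with all
other pairs ≈ 0.

The composite driver runs everything at once and writes per-stage TSVs, a
sample summary with advisory flags, a JSON manifest, and
MultiQC-compatible tables (`xhet_mqc.tsv` bar graph,
`relatedness_mqc.tsv` heatmap):

```r
run_qc(sim$gm, "qc_out",
       sex_metadata = data.frame(sample = names(sim$truth$sex),
                                 sex = unname(sim$truth$sex)),
       pedigree = sim$truth$pedigree, autosomes_only = TRUE)
```

A thin CLI over the same functions lives at `inst/cli/xhetkin.R`
(subcommands `simulate`, `xhet`, `relatedness`, `sexinfer`, `hetscan`,
`qc`; every filter threshold is a flag, with YAML config support).

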