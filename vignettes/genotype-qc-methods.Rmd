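---
title: "Genotype-based sample QC: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-based sample QC: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xhetkin)
```

# The problem

Cohort sequencing studies accumulate sample-level errors — mislabeled sex,
swapped tubes, duplicated libraries, wrong pedigree records — that are
cheap to catch from genotypes alone and expensive to discover later.
`xhetkin` screens for them using only VCF genotype calls: a per-sample
X-chromosome heterozygosity statistic (Xhet) for sex-pattern clustering,
and the KING-robust kinship coefficient for relationship checks. A third
analysis turns the logic around: in a sample whose X is hemizygous, every
non-PAR heterozygous call is an artifact, so tallying them localizes
systematic mis-mapping (paralogs, pseudogenes, ampliconic repeats).

# The Xhet statistic

## Model and assumptions

Non-PAR X genotypes of an XY individual come from a single chromosome:
under error-free calling they are hemizygous (0 or 1), never heterozygous.
An XX individual is diploid there and shows ordinary heterozygosity. The
statistic

$$\mathrm{Xhet} = \frac{n_{0/1}}{n_{0/1} + n_{1/1}}$$

is computed over calls inside chrX:2,781,479–153,925,834 (both bounds
inclusive) that pass the parametric filters. Two choices deserve
justification:

* **The denominator excludes hom-ref.** The method restricts input to
  0/1 and 1/1 genotypes *before* forming the proportion, so "total number
  of variants" means het + hom-alt. This makes the statistic well defined
  for variant-only single-sample VCFs (which contain no 0/0 records at
  all) and comparable between variant-only and joint-called inputs.
* **The interval bounds are closed.** The region string convention of the
  standard VCF toolchain treats both ends as inclusive; position
  2,781,479 is in, 2,781,478 is out.

An undefined Xhet (zero qualifying calls) is reported as missing with its
counts, never as 0 — a sample with no usable X data must not silently
join the hemizygous cluster.

Expected values: for an XX sample genotyped at sites with alternate-allele
frequencies $p_i$ under Hardy–Weinberg,

$$E[\mathrm{Xhet}] \approx \frac{\sum_i 2p_i(1-p_i)}{\sum_i \left(2p_i(1-p_i) + p_i^2\right)}$$

(`expected_xhet()`), e.g. $2/3$ when all $p_i = 0.5$. The observed value
on real data depends strongly on caller ascertainment (which sites get a
record at all), so only the *separation* between clusters, not the
absolute female value, should be interpreted.

## Genotype classification rules

* Half-calls (`./1`) classify as **missing** — conservative, since a
  half-call carries no usable zygosity information.
* Multiallelic genotypes: any two distinct allele indices are **het**,
  identical non-ref indices **hom-alt**; sites are not split into
  biallelic records.
* Haploid calls map ref → hom-ref, alt → hom-alt; a haploid `1` on male X
  therefore lands in the Xhet denominator, as it should.
* Phasing separators and allele order are irrelevant.

# Parametric filters

| parameter | rule | default | rationale |
|---|---|---|---|
| `af_min` | AF strictly `>` | 0.25 | removes low-fraction artifact calls; AF is the non-reference share of AD |
| `dp_min` | DP strictly `>` | 20 | excludes shallow calls where AF is unstable |
| `gq_min` | GQ `>=`, optional | off | direction chosen as the field convention; off by default because not all callers emit GQ |
| `miss_max` | per-site missing fraction strictly `>` excludes | 0.2 | a site with exactly 20% missing is retained |
| VAF windows | inclusive both ends, percent | 25–75 / 33–66 / 45–55 | the het-scan windows; a call at exactly 25% is inside |

Inequality directions are implemented exactly as stated: the boundary
cases AF = 0.25, DP = 20 and missingness = 20% are pinned by unit tests.

Two deliberate policies:

* **Calls lacking AD/DP pass the AF/DP filters** by default (treated as
  unfiltered); `strict = TRUE` inverts this. Deeply annotated inputs are
  unaffected; sparse inputs would otherwise be silently emptied. When AD
  is absent but the caller supplies a `VAF`/`AF` FORMAT field, that value
  is used as the fraction.
* **Hom-ref calls are exempt from the AF rule** (they still face DP/GQ).
  The AF threshold judges the credibility of a *variant* call; a hom-ref
  call's allele fraction is expected to be near zero, so a low value is
  its normal state, not a defect. For variant-only caller output the
  exemption is vacuous (no 0/0 records exist). For joint-called matrices
  it is essential: blanking every hom-ref call would remove all
  opposite-homozygote sites and bias every pairwise kinship estimate
  upward toward the duplicate range.

# KING-robust kinship

For samples $i, j$ over pairwise-complete sites,

$$\hat\varphi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}},$$

the symmetric form with both heterozygote counts in the denominator (the
default output of the standard toolchain; the asymmetric per-sample
variant is intentionally not implemented). A zero denominator yields an
undefined estimate, reported as such — never coerced to 0.

Degree bins follow the powers-of-two convention, with each boundary
belonging to the lower bin: phi > 0.354 duplicate/MZ, (0.177, 0.354]
first, (0.0884, 0.177] second, (0.0442, 0.0884] third, else unrelated.

**Chromosome restriction.** By default the relatedness branch uses every
contig that survives the pre-filters; `autosomes_only = TRUE` drops
X/Y/MT. For cohorts whose male X genotypes are present as hemizygous
calls coded hom-ref/hom-alt, X sites generate spurious opposite-homozygote
counts in male-involved pairs and drag phi down (a father–son pair shares
no X), so autosome-only kinship is recommended and is what the package's
own end-to-end runs use. Variant-only inputs, where male X hom-ref sites
are simply absent, are much less affected.

**Known distortion on variant-only input.** When no sample carries 0/0
records, $N_{AA,aa} = 0$ by construction and phi is estimated only over
sites where both samples carry variants; unrelated pairs then sit well
above 0. This is a property of the data regime, not a bug; within a
uniformly processed cohort the *ranking* (duplicates > first-degree >
unrelated) remains interpretable.

# Sex-group inference

The unsupervised cutoff is 1-D 2-means on the defined Xhet values,
deterministically initialized at the minimum and maximum (no random
restarts; with exactly two values each is its own cluster), returning the
midpoint of the final cluster means. All-identical values are an error
("no separation") rather than an arbitrary split.

Classification: below the cutoff `xy-like`, at or above `xx-like`; values
within a margin (default 10% of the cutoff — conservative, exposed as a
parameter) are forced to `ambiguous`. Labels are genotype-pattern terms,
deliberately not "male"/"female": aneuploidies (XXY, X0), contamination
and extended X homozygosity all produce intermediate patterns that
deserve the ambiguous flag, not a confident sex assignment.

Supervised confirmation fits a one-feature logistic regression
(IRLS via `glm`). On cleanly separated cohorts — the expected regime —
the unpenalized MLE does not exist; the fit detects this and refits with
a small ridge penalty on the slope (default $\lambda = 10^{-2}$,
intercept unpenalized), reporting a `separated` flag and a finite
decision boundary instead of diverging coefficients. Coefficient values
under separation are regularization-dependent and should not be
interpreted beyond the boundary location and slope sign.

# The pseudo-heterozygosity scan

A call enters the scan iff its site is an SNV (ref and every alt a single
base), overlaps an exon interval, classifies het, and its AD-derived
allele fraction lies inside the window (inclusive). Inputs without AD are
rejected — a VAF window is meaningless without fractions. Two summary
notions are computed and labeled distinctly, because both are in common
use: *unique het positions* (distinct sites with at least one qualifying
call) and *het genotype calls* (sample-summed). Gene assignment counts a
call once per overlapping gene (overlapping gene pairs each receive the
shared calls); ranking ties break lexicographically. Region densities are
calls per Mb of the label's summed span; nested regions tally
independently. All annotation (exons, genes, regions) is supplied as BED
input, never fetched — the shipped `chrX_strata_synthetic.bed` is an
approximate synthetic stand-in for the X evolutionary strata, intended
for demonstrations and tests only.

# The simulator

`simulate_cohort()` emulates the data regime the method targets: trios
and small cohorts genotyped genome-wide, with a hemizygous male X.

* Sites: autosomal panel (chr1) plus X sites, a configurable fraction of
  which (default 0.1) fall in PAR1 coordinates and are diploid in
  everyone; allele frequencies Uniform(0.05, 0.5) by default.
* Founders drawn under Hardy–Weinberg; offspring by Mendelian
  transmission; on non-PAR X mothers transmit one allele, fathers pass
  their single X to XX offspring only. Male non-PAR X is emitted haploid
  (`1`) by default, or `1/1`-style with `diploid_male_x = TRUE`, because
  real callers do both; both paths are tested.
* Read model: DP ~ Poisson(40) (a typical genome run), AD ~ Binomial(DP,
  f) with f = 0.005 / 0.5 / 0.995 for hom-ref / het / hom-alt.
* Error model: each call is replaced by a uniformly drawn different class
  with probability 0.001 (typical genotype discordance order).
* Pseudo-heterozygosity: male non-PAR X calls become het with per-site
  probability 0.005 (background) or 0.35 inside labeled trap intervals,
  with VAF drawn from Normal(0.5, 0.08) truncated to (0, 1) — mass
  concentrated inside all three scan windows, mimicking the mis-mapping
  signature the scan is built to find.
* Injectors: column swaps (header unchanged), genotype-identical
  duplicates with independent depths, per-site contamination by another
  sample's calls, and contiguous X-homozygosity runs (autozygosity-like)
  covering a configured fraction of a sample's non-PAR X.

All randomness flows from a single seed; the same configuration
reproduces the emitted VCF byte-for-byte.

**What the simulator does not model** — and therefore what passing tests
do *not* establish about real data: caller ascertainment (every site gets
a record for every sample), linkage disequilibrium, population structure,
batch effects, indels/structural variants, and realistic allele-frequency
spectra. In particular the simulated XX Xhet (≈ 0.8 under the default AF
range) is higher than values typically seen on carrier-ascertained
single-sample VCFs; only the XX/XY separation, not the absolute level,
transfers.

# Study sizes used in the packaged checks

The test suite and the acceptance script run entirely on simulated
cohorts at sizes chosen to make Monte-Carlo noise small relative to the
assertions: 20,000 autosomal sites for the kinship ladder (one-pair
standard error ≈ 0.006, against tolerances of 0.02–0.03), 1,000–2,000
non-PAR X sites for sex separation (cluster gap ≈ 0.7, far beyond
sampling noise), and 4,000 X sites with two 1-Mb trap intervals for the
scan. The brute-force oracles (per-site counting loops, exhaustive
overlap checks) are kept deliberately naive and independent of the
vectorized implementations they verify.

# Known limitations

* Same-sex first-degree pairs (mother–daughter, father–son) are
  indistinguishable from each other by design: degree and inferred sex
  group are identical within the pair. The QC report states this rather
  than guessing.
* Kinship here supports relationship *screening*, not Mendelian-error
  analysis; it performs no per-site transmission checks and must not be
  used as de novo evidence.
* Aneuploidies are only surfaced as `ambiguous`; no karyotype calling is
  attempted, and no coverage-based ploidy estimation is performed (the
  tool is genotype-only by design).
* Xhet is sensitive to the calling pipeline (joint vs single-sample,
  filters); compare values only within uniformly processed datasets.
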