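---
title: "Global autozygosity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global autozygosity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(autozyg)
```

## The measures

Global autozygosity summarizes a whole genome's zygosity in one number.
`autozyg` implements the two standard measures.

**Heterozygosity ratio.** With `N_het` heterozygous and `N_HomNonRef`
homozygous non-reference SNPs in one genome,

$$HR_{NonRef} = N_{het} / N_{HomNonRef}.$$

Its theoretical anchor: for a site with derived-allele frequency $p$
(reference = ancestral), Hardy–Weinberg gives $E[\text{het}] = 2p(1-p)$ and
$E[\text{hom-derived}] = p^2$. Averaged over the neutral site-frequency
spectrum, whose density is $\propto 1/p$ on $[p_{min}, p_{max}]$,

$$\frac{\int 2p(1-p)\,p^{-1}dp}{\int p^2\,p^{-1}dp}
  = \frac{2[(p_{max}-p_{min}) - (p_{max}^2-p_{min}^2)/2]}
         {(p_{max}^2-p_{min}^2)/2} \to 2$$

for symmetric bounds $p_{min} = 1 - p_{max}$. Per-sample ratios concentrate
around this value as the SNP count grows because numerator and denominator
are sums over many independent sites. The acceptance script recomputes this
anchor at 200 samples × 100,000 SNPs.

The anchor has two fragilities that motivate the second measure. First, the
human reference allele is not the population major allele everywhere (about
8% of array sites); a common site with swapped labels contributes a
homozygous "non-reference" call for most samples, inflating the denominator
and dragging $HR_{NonRef}$ well below 2. $HR_{Minor} = N_{het}/N_{HomMinor}$
counts homozygotes of the *cohort-minor* allele instead and is invariant to
the labeling. Second, inbreeding deflates heterozygosity: with inbreeding
coefficient $F$ the genotype law is

$$P(\text{hom-ref}) = (1-p)^2 + Fp(1-p),\quad
  P(\text{het}) = 2p(1-p)(1-F),\quad
  P(\text{hom-alt}) = p^2 + Fp(1-p),$$

so mean $HR_{NonRef}$ decreases monotonically in $F$ — a property the test
suite checks over $F \in \{0, 0.05, 0.1, 0.25\}$.

**Runs of homozygosity.** `detect_roh()` is a faithful sliding-window scan:
windows of `window_snps` SNPs move one SNP at a time along a chromosome; a
window is a *hit* when it has at most `window_max_het` heterozygous and
`window_max_missing` missing calls; a SNP is eligible when at least
`hit_proportion_threshold` of the windows covering it are hits; maximal
eligible runs are split at inter-SNP gaps above `max_gap_kb`, trimmed to
start and end on non-heterozygous calls, and reported when they meet the
`min_snps`, `min_length_kb` and density filters. The defaults
(50 / 1 / 5 / 0.05 / 100 / 1000 kb / 1000 kb / 50 kb-per-SNP) mirror the
documented defaults of the standard tool for array data, since no single
published parameterization is canonical; all are exposed through
`roh_params()`. The per-sample summary carried into the regressions is the
**median segment length** (kb), with the explicit convention that a sample
with no detected segment scores 0 — it is minimally autozygous and should
stay in the regression rather than be dropped.

An exhaustive brute-force scanner (every window and every run enumerated by
loops) lives in the test helpers and must agree segment-for-segment with the
vectorized implementation over 50 random 500-SNP cohorts × 50 random
parameter draws.

## Mutational signatures

Somatic substitutions are classified into the 96 trinucleotide motifs:
6 pyrimidine-strand substitutions × 16 flank combinations, in
substitution-major order with alphabetical flanks (the layout of published
reference matrices). Purine-reference mutations are reverse-complemented, so
a mutation and its opposite-strand description land in the same class —
enumerating all 192 (ref, alt, flanks) combinations hits each of the 96
classes exactly twice.

Per-sample catalogs are refit to a reference signature matrix by
non-negative least squares,
$\min_{s \ge 0} \lVert R s - c \rVert_2$, solved with the Lawson–Hanson
active-set method. Exposures are reported in **mutation-count units**, not
renormalized proportions: the downstream linear regressions need one
consistent scale, and count units keep the per-sample mutation burden
visible. Fitting is per-sample independent with no sparsity penalty or
signature pre-selection. Recovery is verified two ways: exact
reconstruction of forward-constructed catalogs ($R s^*$, relative error
≤ 1e−6) and cosine similarity ≥ 0.99 on 50,000-draw multinomial catalogs
from 4-signature mixtures.

## Association stages

Every effect is **per standard deviation**: the covariate is standardized
(`standardize()`) on the pooled case + control vector of the analysis
stratum, and every test runs separately per stratum, never pooled.

- **Risk**: `logistic_assoc()` fits status ~ covariate by maximum
  likelihood and reports the Wald CI and p. Strata whose case count does
  not exceed `min_cases` (default 100, configurable) are *skipped*, not
  errored; (quasi-)separation is *flagged* with no coefficient. No
  multiplicity adjustment is applied to the risk tables.
- **Signatures**: `linear_assoc()` (ordinary least squares) per signature,
  with Benjamini–Hochberg FDR across the whole table and a 0.05 threshold.
- **Survival**: `cox_fit()` (partial likelihood, Breslow ties) for the
  continuous model, and `maxstat_cutpoint()` for the optimal
  dichotomization: the standardized two-sample log-rank statistic is
  evaluated at every observed covariate value between the 10th and 90th
  percentiles, and the maximizing cut is returned with its *unadjusted*
  log-rank p. Because the cut is selected to maximize the statistic this p
  is anti-conservative by construction; the package reports it alongside
  the continuous-model p and labels it descriptive.
- **Meta-analysis**: `meta_random_effects()` is the DerSimonian–Laird
  moment estimator in closed form ($Q$, $\tau^2$, random-effects weights
  $1/(se^2+\tau^2)$). DL was chosen over REML deliberately: it is
  closed-form and therefore checkable against a hand calculation
  (effects (1, 3) with SEs (1, 1) give $Q = 2$, $\tau^2 = 1$, pooled
  $2.0 \pm 1.0$), and the tests additionally cross-check against an
  independent meta-analysis library run with the DL method.
- **AUC**: `roc_auc()` is the Mann–Whitney probability with ties counted
  one half, hence invariant to monotone transforms.

## The synthetic cohort generator

The generator produces data with the statistical structure the analysis
assumes, so the pipeline is testable end to end without any genotype
download:

- frequencies from the neutral $1/p$ spectrum (inverse-CDF:
  $p = p_{min}(p_{max}/p_{min})^u$), a uniform spectrum, or a fixed list;
- Hardy–Weinberg genotypes with per-sample $F$, on synthetic 25 Mb
  chromosomes at fixed 10 kb SNP spacing — the spacing makes kb-scale ROH
  thresholds deterministic functions of SNP counts (a 120-SNP tract is
  1,190 kb, comfortably past the 100-SNP / 1 Mb defaults, while a 20-SNP
  tract can never be reported);
- injected contiguous homozygous tracts with recorded truth coordinates;
- reference-allele flips at a configurable fraction of sites (default
  0.08, matching the observed share of array variants where the reference
  is not the major allele); flips swap hom-ref with hom-nonref and leave
  het calls invariant;
- an optional X block, diploid in females and haploid in males (haploid
  calls coded as homozygotes of the present allele, the array convention)
  — this alone reproduces the qualitative sex difference in HR and its
  shrinkage when sex chromosomes are excluded;
- case-control labels from a logistic model with known per-SD log odds
  ratio (default 1.0) and baseline prevalence 0.5;
- multinomial mutation catalogs from known signature mixtures;
- exponential survival with known per-SD log hazard (default 0.7) and
  independent exponential censoring calibrated by root-finding to a target
  censored fraction (default 20%).

All randomness flows from one integer seed; sub-streams are derived
deterministically per operation, and reruns are byte-identical.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure (sites are independent given $F$, so background ROH
arises only from injection or high $F$, not from real IBD segments),
genotyping and imputation error beyond simple missingness, population
stratification or admixture, and any causal mechanism linking
autozygosity to signature exposures (none is claimed; the signature stage
is generated under the null, which is exactly what the false-discovery
check needs). Passing tests therefore demonstrate correctness of the
computations and calibration of the statistics under these idealized
conditions — not that real cohorts satisfy them.

## Numerical conventions and degenerate inputs

- Coordinates are 1-based inclusive throughout (VCF convention); the BED
  writer converts to 0-based half-open.
- Variant identity is chromosome + position + ref + alt; cohort
  intersection requires all four to match, so a site with swapped alleles
  in another cohort is excluded rather than silently harmonized.
- Multi-allelic records and indels are dropped on read (the HR definitions
  assume one alternate allele); half-missing genotypes are Missing.
- Major-allele tie at frequency exactly 0.5 resolves to the reference
  allele, which keeps `hr_minor == hr_nonref` exact at balanced sites.
- A zero denominator makes an HR undefined (`NA`), never an exception;
  such samples are excluded listwise from regressions and counted in the
  run manifest. At genome scale the denominator is effectively never zero.
- `standardize()` errors on zero variance rather than returning zeros: a
  constant predictor cannot carry a per-SD effect.
- The NNLS solve is deterministic; a zero catalog short-circuits to zero
  exposures with zero residual.

## Problem sizes

The test suite runs at desk scale by design: the HR anchor at 200 × 100,000
SNPs, oracle comparisons on 500-SNP cohorts, logistic calibration with 100
coverage and 400 null replicates of n = 4,000, Cox recovery with 50
replicates of n = 500, and pipeline runs of 150–240 samples × 2,500 SNPs.
These sizes make every distributional claim in the tests an actually
computed quantity while keeping a full run in tens of seconds.

## Known limitations

- ROH detection inherits the sliding-window method's sensitivity to SNP
  density; the package exposes the parameters but does not attempt the
  array-specific tuning a real study would do.
- Models are single-predictor and unadjusted (no age, stage or ancestry
  covariates), matching the analysis design the package implements.
- The maxstat p-value is uncorrected for cutpoint selection; treat it as
  descriptive.
- Exposure units (counts vs proportions) change the scale of the
  signature regressions; the package fixes counts and documents it rather
  than offering both silently.
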