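# autozyg

Global autozygosity — the genome-wide balance of heterozygous and homozygous
variants — is a single-number characterization of a genome that has been
linked to disease risk. `autozyg` computes the two standard measures from
cohort genotype data and carries them through a complete association
analysis, for statistical geneticists and cancer-genomics analysts who want
the whole chain (genotypes → autozygosity → risk / signature / survival /
meta-analysis) reproducible from one seed.

## What it computes

**Heterozygosity ratio.** For one genome with `N_het` heterozygous SNPs and
`N_HomNonRef` homozygous non-reference SNPs,

    HR_NonRef = N_het / N_HomNonRef

Under a neutral site-frequency spectrum (density ∝ 1/p) with the reference
allele equal to the ancestral allele, E[2p(1−p)] / E[p²] = 2, so HR_NonRef
has a theoretical cohort mean of 2 in a panmictic population. Because the
human reference allele is not the population major allele at roughly 8% of
array sites, the package also computes

    HR_Minor = N_het / N_HomMinor

where `N_HomMinor` counts sites homozygous for the *cohort-minor* allele.
Inbreeding deflates heterozygosity by (1−F), so both ratios fall as the
inbreeding coefficient F rises.

**Runs of homozygosity (ROH).** A PLINK-style sliding-window scan
(50-SNP windows, ≤1 het and ≤5 missing calls per hit window, 5% hit
proportion for SNP eligibility, segments reported at ≥100 SNPs, ≥1 Mb,
≤1 Mb gaps, ≥1 SNP/50 kb; all configurable via `roh_params()`). The
per-sample summary is the **median segment length** in kb.

**Downstream stages.**

- `logistic_assoc()` — case-control log odds ratio per standard deviation
  of HR or ROH, Wald 95% CI, with a configurable minimum-case gate.
- `build_catalogs()` / `fit_exposures()` — 96-motif trinucleotide mutation
  catalogs (pyrimidine-strand normalized) refit to reference mutational
  signatures by non-negative least squares; `linear_assoc()` + `bh_fdr()`
  for signature–autozygosity association at FDR < 0.05.
- `cox_fit()` / `maxstat_cutpoint()` — disease-specific survival on the
  continuous covariate plus the maximally selected log-rank dichotomization
  (both p-values reported; the dichotomized one is descriptive).
- `meta_random_effects()` — DerSimonian–Laird random-effects pooling with
  the Q heterogeneity test.

A seeded synthetic-cohort generator (`sample_frequencies()`,
`simulate_genotypes()`, `inject_roh()`, `flip_reference()`,
`simulate_case_control()`, `simulate_catalogs()`, `simulate_survival()`)
emulates the statistical structure of array-genotyped case-control cohorts
so every stage is testable without any external download.

## Worked example

```r
library(autozyg)

cfg <- pipeline_config(
  sim = synthetic_cohort_config(n_samples = 240, n_snps = 2500,
                                roh_tracts = 1, roh_tract_len_snps = 120,
                                seed = 42),
  n_strata = 2, min_cases = 20)
res <- run_autozygosity_pipeline(cfg)

res$profile
#> autozygosity_profile: 240 samples
#>   mean hr_nonref: 1.0051  mean hr_minor: 4.5764
#>   mean n_roh: 1.00  mean median ROH length: 1412.3 kb
```

The cohort mean HR_NonRef sits near 1 rather than 2 because 8% of sites
have their reference/major labels swapped (the generator's default,
mirroring real reference genomes): each swapped common site adds a
homozygous "non-reference" call to the denominator. HR_Minor, which is
immune to the labeling, is several-fold higher. Every sample carries one
injected ~1.2 Mb homozygous tract, which the scan recovers (mean median
ROH length 1412 kb).

```r
res$risk[res$risk$predictor == "hr_nonref",
         c("stratum", "logor", "p", "auc", "cases", "controls")]
#>   stratum     logor            p       auc cases controls
#> 1      G1 0.7841015 4.142333e-04 0.7156563    58       62
#> 3      G2 1.0607061 3.418912e-05 0.7426901    57       63
```

Case-control labels were generated with a true per-SD log odds ratio of 1;
both strata recover it (0.78 and 1.06, each CI covering 1). Pooling:

```r
with(subset(res$risk, predictor == "hr_nonref"),
     meta_random_effects(logor, stderr))
#> meta_result (DerSimonian-Laird, k = 2)
#>   pooled effect 0.9029 (SE 0.1677), p = 7.35e-08
#>   heterogeneity: Q = 0.666, tau2 = 0.0000, p = 0.414
```

Survival among cases (true log hazard 0.7 per SD, 20% censoring):

```r
res$survival[, c("stratum", "hazard_coef", "p_continuous", "p_dichotomized")]
#>   stratum hazard_coef p_continuous p_dichotomized
#> 1      G1   0.8380735 1.955537e-05   3.962987e-05
#> 2      G2   0.8097138 4.189509e-07   7.771679e-09
```

`run_autozygosity_pipeline(cfg, out_dir = "out")` writes all tables
(`profile.tsv`, `risk.tsv`, `signature_assoc.tsv`, `survival.tsv`,
`meta.tsv`, `roh.bed`) plus a JSON manifest; rerunning with the same seed
reproduces them byte for byte.

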