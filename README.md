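# iecatrc

Single-variant case-control association testing that integrates external
control samples **after regression-calibrating their genotypes**, so that
batch effects between studies — genotyping platform, calling pipeline,
stratification — do not masquerade as association signal.

## Who this is for

GWAS analysts with a modest internal case-control cohort and access to a
large externally genotyped control set. Pooling the external controls
naively inflates type-I error wherever the two studies' genotype
distributions differ; discarding them wastes power. `iecatrc` implements
the middle path: calibrate, then integrate, then test with properly
calibrated p-values.

## The method

For each variant, external-control genotypes are adjusted in three steps:

1. **Regression calibration.** External controls are processed in blocks of
   at most `n0I` (the internal control count). Within a block, K random
   pairings of external subjects with internal controls are drawn; each
   yields a least-squares fit of internal-control genotype on paired
   external genotype (plus optional principal-component terms), and the K
   coefficient vectors are averaged:

   `G*_i = b0 + b1 g_i + aI X_i^I + aE X_i^E`

   The continuous predictions `G*` are discretized by thresholds
   `a0 <= a1` chosen so the calibrated 0/1/2 frequencies match the
   internal-control frequencies.

2. **Score test.** With the covariate-only logistic null fit `mu` and
   `V = diag{mu(1-mu)}`, the adjusted genotype is
   `Gt = G - Z (Z'VZ)^-1 Z'V G`, the score is `S = Gt'(Y - mu)`,
   `Var(S) = sum Gt_i^2 mu_i (1-mu_i)`, and `T = S^2/Var(S)` is compared
   to a chi-square with 1 df.

3. **P-value calibration.** Unbalanced case-control ratios get a two-sided
   saddlepoint (Lugannani-Rice) tail from the full cumulant generating
   function of S; variants with minor allele count below 10 get an exact
   efficient-resampling p-value that enumerates the case assignments among
   the minor-allele carriers, weighted by the Poisson-binomial law of the
   carrier case count.

Three analysis strategies are provided for comparison: `rc` (calibrated
integration, the full method), `naive` (raw pooling — the negative
control), and `internal` (internal samples only). A simulation engine
reproduces the type-I-error and power study design: six models crossing
internal case:control:external ratios (5000:5000:10000, 6667:3333:10000,
500:5000:10000) with two batch mechanisms (external MAF doubled, or drawn
from Uniform(0.1q, 4q)), exome-like MAF spectra, and prevalence-anchored
phenotypes.

## Worked example

Simulate a small cohort pair with a deliberate batch effect (external MAF
doubled on every variant), then compare the three strategies:

```r
library(iecatrc)
set.seed(1)

internal <- cohort_data(
  matrix(rbinom(2000 * 3, 2, 0.15), 2000,
         dimnames = list(NULL, c("v1", "v2", "v3"))),
  phenotype = rep(0:1, 1000),
  covariates = data.frame(z1 = rnorm(2000))
)
external <- cohort_data(  # batch-shifted: MAF 0.30 instead of 0.15
  matrix(rbinom(1500 * 3, 2, 0.30), 1500,
         dimnames = list(NULL, c("v1", "v2", "v3"))),
  covariates = data.frame(z1 = rnorm(1500))
)

naive <- iecat_scan(internal, external, method = "naive")
rc    <- iecat_scan(internal, external, method = "rc", K = 10, seed = 7)

dplyr::select(naive, variant_id, n, mac, p_value, route)
#>   variant_id    n  mac      p_value route
#> 1         v1 3500 1516 5.826771e-18   SPA
#> 2         v2 3500 1523 7.281794e-15   SPA
#> 3         v3 3500 1515 1.100361e-14   SPA
dplyr::select(rc, variant_id, n, mac, p_value, route)
#>   variant_id    n  mac   p_value               route
#> 1         v1 3500 1068 0.4730735 SPA_fallback_normal
#> 2         v2 3500 1107 0.6393286 SPA_fallback_normal
#> 3         v3 3500 1074 0.6962469 SPA_fallback_normal
```

Every variant is null — the phenotype is independent of genotype — yet
naive pooling declares all three genome-wide significant (p down to
6e-18), because the external controls carry twice the allele frequency.
After calibration the same integration yields unremarkable p-values
(0.47-0.70) at the same combined sample size: `mac` drops from ~1520 to
~1080 because the calibrated external genotypes now match the
internal-control frequency. The `route` column records which tail calibration produced each
p-value (`asymptotic`, `SPA`, `SPA_fallback_normal` for scores too central
for the saddlepoint to matter, `ER` at low minor allele count).

The experiment harnesses wrap this comparison at study scale:

```r
cfg <- sim_config(model = 1, dvs = 0.03, n_variants = 200,
                  n_pheno_resamples = 100, seed = 1)
ex <- type1_error_experiment(cfg)
tidy(ex)        # rejection rates: method x alpha, pooled and stratified
autoplot(ex)    # by differential-variant stratum
```

A thin command line mirrors the R API
(`iecat-rc scan|simulate|calibrate`, installed under `exec/`):

```sh
iecat-rc scan --geno-internal int.vcf --geno-external ext.vcf \
  --pheno pheno.tsv --method rc --K 10 --seed 1 --out results.tsv
iecat-rc simulate --model 3 --variants 200 --resamples 100 --seed 1 --out sim/
```

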