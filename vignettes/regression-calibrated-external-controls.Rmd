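---
title: "Integrating external controls by regression calibration: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating external controls by regression calibration: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iecatrc)
```

## The problem

A case-control GWAS with a modest internal sample can borrow power by
pooling publicly available genotyped controls from another study. Pooled
naively, the external controls bring their batch effects with them:
platform, genotype-calling and stratification differences shift their
genotype distribution relative to the internal controls, and the score test
reads that shift as association. The resulting type-I error inflation is
not subtle — on a variant whose external-control allele frequency is twice
the internal frequency, a well-powered test rejects almost every time.

`iecatrc` implements a three-step remedy:

1. **Regression calibration** maps each external control's genotype through
   an averaged paired least-squares model and re-discretizes the result so
   the calibrated genotype frequencies match the internal-control
   frequencies.
2. A **covariate-adjusted logistic score test** is run on the combined
   sample (internal cases and controls plus calibrated external controls
   with phenotype 0). With null fit $\hat\mu$ and $V = \mathrm{diag}\{
   \hat\mu_i(1-\hat\mu_i)\}$, the adjusted genotype is
   $\tilde G = G - Z(Z^TVZ)^{-1}Z^TVG$, the score is
   $S = \tilde G^T(Y - \hat\mu)$, $\mathrm{Var}(S) = \sum_i \tilde
   G_i^2\hat\mu_i(1-\hat\mu_i)$, and $S^2/\mathrm{Var}(S) \sim \chi^2_1$
   asymptotically.
3. **P-value calibration**: a saddlepoint approximation (SPA) replaces the
   normal tail when case-control ratios are unbalanced, and an efficient
   resampling (ER) computation replaces it when the minor allele count
   (MAC) is below 10.

## Step 1: what calibration does — and what it cannot do

For each variant, external controls are processed in consecutive blocks of
at most $n_{0I}$ subjects. Within a block, $K$ random pairings of external
subjects with the internal controls are drawn; each pairing yields an OLS
fit of internal-control genotype on paired external genotype (plus optional
PC terms), and the $K$ coefficient vectors are averaged. The averaged model
predicts a continuous calibrated genotype for every block member, which is
discretized by thresholds $a_0 \le a_1$ chosen so the calibrated 0/1/2
frequencies match the internal-control frequencies.

Two structural facts shape the implementation:

* **The pairing slope is centered at zero.** Internal and external cohorts
  are disjoint individuals, so the paired regression estimates a
  cross-covariance whose true value is 0; averaging $K$ repeats shrinks its
  noise but not its center. The continuous predictions therefore order the
  external subjects by their raw genotype (up to a random overall sign),
  and the frequency-matching discretization does all the distributional
  work. In effect, calibration redraws the external genotypes
  frequency-matched to the internal controls. This is exactly what removes
  the batch effect; it also means the calibrated coding of an individual
  variant can be rank-reversed relative to its raw coding, which is
  harmless for control-only subjects (only their marginal genotype law
  enters the test).
* **Ties must be split.** Without PC terms the continuous predictions take
  at most three values, so every threshold falls inside a tied group. A
  tie rule that sends a whole group to one category would reproduce the
  external frequencies verbatim and the method would do nothing. The
  implementation assigns the lowest $\mathrm{round}(f_0 m)$ predictions to
  0, the next $\mathrm{round}(f_1 m)$ to 1 and the rest to 2, splitting
  tied groups uniformly at random (seeded). The frequency match then holds
  to $1/m$ for every input, including the fully degenerate case of
  identical predictions; discretization is monotone in the prediction, as
  an exact step function whenever predictions are distinct.

`K` defaults to 10: the slope noise shrinks like $1/\sqrt{K}$ and the gain
plateaus quickly; the value is configurable. Partial final blocks are
paired with an equal-sized random subsample of internal controls. When PC
terms are used ($p > 0$), one PCA is fitted per cohort and external
subjects receive internal-PC coordinates by projection onto the internal
loadings, keeping both PC terms defined for every subject; $p = 0$ is the
default and is appropriate for the simulation engine, whose generating
model has no ancestry structure.

## Steps 2-3: the test and its calibrated tails

The covariate-only null model is fitted once per phenotype/covariate
configuration (Newton iteration, coefficient-change tolerance $10^{-8}$,
$\hat\mu$ clipped to $[10^{-12}, 1-10^{-12}]$ to keep the cumulant
generating function finite) and reused across all variants.

The score's CGF under the null fit is
$K(t) = \sum_i \log(1-\hat\mu_i+\hat\mu_i e^{\tilde G_i t}) - t\sum_i
\tilde G_i \hat\mu_i$. The SPA p-value is two-sided: the upper
Lugannani-Rice tail at $|s|$ plus the lower tail at $-|s|$, each with its
own saddlepoint root of $K'(\hat t) = s$ (safeguarded Newton with a
bisection bracket). Numerical choices:

* $|\omega| < 10^{-4}$ (score near its mean) makes the printed formula
  divide by ~0; the normal approximation is returned instead, flagged
  `fallback_used`.
* The scan dispatch applies the saddlepoint only when the normal $|z|$
  exceeds `spa_cutoff` (default 1.2). This is the standard practice of
  saddlepoint GWAS tools, which use cutoffs near 2; the default here is
  deliberately lower so that the $\alpha = 0.05$ decision boundary
  ($|z| = 1.96$) always lies inside the saddlepoint region. `spa_pvalue()`
  itself takes `cutoff = 0`.
* A score at or beyond its attainable extreme has no finite saddlepoint and
  the Lugannani-Rice formula degenerates; that tail is computed exactly as
  the probability of the single extreme phenotype configuration.

The SPA is an asymptotic approximation. At $n \le 12$, where the exact
score distribution can be enumerated, the score support is a small lattice:
the uncorrected formula's relative error is a few percent in the typical
instance but individual lattice atoms can be off by tens of percent, and a
uniform 10% error bound is not attainable without a continuity correction
(which this package deliberately does not add — the tests pin the actual
profile: median error below 10%, never off by more than a factor of two,
exact at the boundary). In its operating regime — thousands of subjects,
unbalanced designs, tails at $\alpha \le 10^{-3}$ — Monte-Carlo calibration
checks show the SPA at or below nominal where the normal approximation is
measurably anticonservative.

At low minor allele count (MAC < 10 by default) the test statistic is
driven by a handful of carriers and ER takes over: with $m$ carriers and
$D$ the number of cases among them, the p-value decomposes over
$\Pr(D = d)$ (the Poisson-binomial of the carriers' $\hat\mu_i$, computed
by convolution), with the conditional term enumerated exactly over the
$\binom{m}{d}$ case assignments weighted by their conditional
probabilities. The statistic is the raw carrier score
$Q = \sum_{\text{carriers}} G_i(y_i - \hat\mu_i)$ (genotype-2 carriers
enter with weight 2); since $E[Q] = 0$ under the null fit, the two-sided
p-value is $\Pr(|Q| \ge |\hat Q|)$ with the observed configuration counted
in its own tail, so $p > 0$ and the test is exact (verified against
$2^m$ enumeration to $10^{-12}$). For MAC < 10 the enumeration bound
($10^5$ configurations) is never reached; a self-normalized
importance-sampling branch exists for larger conditional spaces.

Dispatch per variant: ER if MAC < `mac_threshold`; else SPA if external
controls are integrated or the internal case fraction is below 1/3 (for
balanced designs the SPA converges to the normal result, so applying it
broadly is safe); else the asymptotic $\chi^2_1$ tail. Each result row
records the route taken.

## The simulation engine

Phenotypes follow
$\mathrm{logit}\,P(Y=1) = \alpha_0 + 0.5 Z_1 + 0.5 Z_2 + \beta G +
\varepsilon$ with $Z_1 \sim N(0,1)$, $Z_2 \sim \mathrm{Bernoulli}(0.5)$,
$\varepsilon \sim N(0,1)$ kept as a latent logistic-normal term exactly as
the design states, $G \sim \mathrm{Bin}(2, q)$, and $\alpha_0$ solved by
Monte-Carlo root-finding (common random numbers, $10^6$ draws) so the
population prevalence is 0.05. Internal cases and controls are accrued by
rejection sampling with a generous draw budget; external controls are
population controls under the external MAF.

**MAF spectrum.** Per-variant MAFs default to a folded site-frequency
spectrum emulating an exome discovery panel of 697 diploids:
$\Pr(\mathrm{MAC} = k) \propto k^{-1.5}$ for $k = 1..697$, $q = k/1394$.
This gives ~38% singletons ($q \approx 7\times10^{-4}$) and a strong rare
excess, the hallmark of exome panels of this size; an empirical MAF list
can be supplied instead (`maf_source`). The batch-effect magnitudes below
are sensitive to this spectrum: common variants reject near-certainly
under a doubled external MAF, singletons only occasionally, so the
spectrum's rare mass sets the averages.

**Batch effect.** A fraction `dvs` of variants (the differential variant
size) gets a perturbed external MAF: doubled (`2q`, capped at 0.5) or
drawn from $U(0.1q, 4q)$ (capped at 0.5). Six standard models pair the
internal case:control:external ratios 5000:5000:10000, 6667:3333:10000 and
500:5000:10000 with the two mechanisms.

**Type-I harness.** Genotypes are generated once per variant set and the
internal phenotypes are resampled (default 100 times), keeping the other
data fixed. Two choices deserve explanation:

* *Resampling law.* Covariates stay fixed and $\varepsilon$ is redrawn,
  but the intercept is re-solved each resample so the expected internal
  case count equals $n_{1I}$. Redrawing at the population intercept would
  collapse the ascertained 1:1 (or 1:10) design to ~5% cases and change
  what the models measure; case-control ascertainment shifts only the
  logistic intercept, so this is the retrospective null law of the design.
* *Calibration is fixed data.* The external genotypes are calibrated once
  per variant set, against the ascertained control labels, and held fixed
  across resamples. Conditionally on all genotype data the score test is
  then exactly calibrated. Recalibrating inside the resampling loop would
  tie the calibrated genotypes to the current phenotype vector — frequency
  matching would clone each resample's internal-control frequency into all
  external controls, the modeled $\mathrm{Var}(S)$ would understate the
  truth, and the calibrated method would appear inflated for a purely
  procedural reason. (We verified this effect empirically before fixing
  the calibration outside the loop.)

All variants share one subject panel per experiment, since under
$\beta = 0$ the null model is genotype-free and one fit serves every
variant of a resample; with 200 variant sets and 100 resamples a full
model runs in a few minutes on one CPU. Rates are reported pooled and
stratified by the differential flag, with binomial Monte-Carlo standard
errors and per-method route counts.

**Interpreting pooled versus stratified rates.** Naive integration's
inflation is a per-variant property of the perturbed variants: a pooled
rate at `dvs` = 0.03 is bounded by roughly $0.03 \times 1 + 0.97 \times
0.05 \approx 0.08$ no matter how severe the batch effect, while the
perturbed-stratum rate can reach 0.4-0.5 under the doubled-MAF mechanism
with the default spectrum. Headline inflation magnitudes in this package's
acceptance checks are therefore computed on perturbed variants (run with
`dvs = 1`, which estimates the same per-variant quantity with full
replicate efficiency); internal-only rates involve no external data and
are invariant to `dvs`.

**Power harness.** Independent single-causal-variant datasets per
replicate; the acceptance-scale check uses 500 replicates at
$\alpha = 10^{-3}$ and $\beta = \log 2$ and asserts that calibrated
integration does not lose power relative to the internal-only test.

## What the generator does and does not emulate

It emulates: ascertained case-control sampling at a realistic prevalence,
covariate-driven risk with latent noise, exome-like allele-frequency
spectra, and frequency-shift batch effects of tunable severity and extent.
It does not emulate: linkage disequilibrium between variants (variants are
independent), ancestry or population stratification (no PC structure in
the generating model), genotype missingness or calling error at the
read level, or covariate batch differences between cohorts. Passing the
simulation suite therefore demonstrates control of frequency-shift batch
effects under the stated phenotype model, not robustness to stratification
— the method itself requires internal and external samples of matching
ancestry, with PCs as the only adjustment knob.

## Degenerate inputs and edge policies

* Monomorphic variants (after adjustment): $p = 1$, route `monomorphic`.
* Monomorphic external blocks: the paired OLS drops the genotype column
  (slope 0) and discretization falls through to the frequency-matched
  random assignment.
* Collinear covariates: refused at null-model fitting with a clear error.
* Non-convergent null fits (separation): flagged; tests against them are
  refused rather than silently reported.
* Missing genotypes: mean-imputed per variant (after optional MAF and
  missingness filters) before anything downstream sees them.
* Scan errors are attached to the variant's result row rather than
  aborting a genome-wide run.

## Reproducibility

Every stochastic component (pairing draws, tie-breaks, simulation,
resampling, ER sampling branch) derives from explicit seeds; identical
seeds give bit-identical calibrations, scans and rejection tables. Run
metadata (seed, configuration hash, package and R versions) is written
alongside results by the CLI and `write_run_metadata()`.
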