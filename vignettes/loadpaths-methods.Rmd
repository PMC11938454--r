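---
title: "Methods: mediation and Mendelian randomization from genetic risk to LOAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mediation and Mendelian randomization from genetic risk to LOAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loadpaths)
```

## The scientific question

Common risk variants for late-onset Alzheimer's disease (LOAD) — above all
the APOE ε4 haplotype — could act on disease risk directly, or by altering
the morphology of brain structures that degenerate early in the disease
(entorhinal cortex, hippocampus, amygdala, the ventricles). `loadpaths`
implements the two inferential tools needed to separate these routes at the
level of individual participants: a variant-by-measure **causal mediation
grid** that quantifies how much of each variant's effect on LOAD is
transmitted through each regional measure, and **one-sample bidirectional
Mendelian randomization (MR)** that asks whether a mediating measure is a
cause or a consequence of the disease.

## Phenotypes

**Outcome.** Two cohort designs are supported. Case-control cohorts carry a
clinical LOAD status, modeled with logistic regression. Biobank-style
cohorts without enough clinical cases instead use a family-history proxy
score: each biological parent affected by LOAD contributes 1; an unaffected
parent of age $t$ (current, or at death) contributes
$\min\{0.32,\; \max(0, (100 - t)/100)\}$ — the age weight captures the risk
period the parent has not yet survived, and the 0.32 ceiling is the maximum
population prevalence of AD. The score therefore lives in $[0, 2]$, is
zero-inflated and right-skewed, and is analysed with linear regression;
the `type1_sim()` harness exists precisely to confirm by simulation that
the path-c test holds its nominal type-I error under this non-normal
outcome (the package's calibration runs use 5,000 replicates of n = 500).
Participants with no parental information get `NA` and drop out of
proxy-outcome models. Whether an affected parent should contribute exactly
1 regardless of age is not fully pinned down by the score's verbal
definition; the package implements 1, which keeps the score's integer part
equal to the affected-parent count. The negative weights the formula would
assign to unaffected parents older than 100 are clamped to 0.

**APOE ε4 count.** The APOE haplotype is read off rs429358 and rs7412
(ε1 = C+T, ε2 = T+T, ε3 = T+C, ε4 = C+C). `count_apoe4()` enumerates both
phasings of the unphased genotypes; the only ambiguous case is the double
heterozygote (C/T, C/T), compatible with ε2/ε4 and ε1/ε3. Because ε1 is
vanishingly rare in European-ancestry populations, it is resolved as ε2/ε4
(count 1) and flagged `ambiguous` so users can exclude those participants
in sensitivity analyses.

**Regional measures.** Hemisphere-level FreeSurfer-style values are
combined by summing (surface area, volume) or averaging (thickness). Total
surface area is the sum of the 34 cortical regional areas; global mean
thickness is the surface-area-weighted mean of the regional thicknesses.
All measures are z-scored (sample SD, $n-1$ denominator — the convention of
`stats::sd`; the choice matters only in the third decimal at cohort sizes)
within the analysis sample after exclusions.

**Genotype QC.** Variants failing 10% missingness or a 1-df chi-square
Hardy–Weinberg test at $p < 10^{-9}$ are removed before analysis. The
chi-square (rather than exact) test matches large-cohort practice; at the
n where the exact test would differ, a threshold of $10^{-9}$ is
essentially never crossed by sampling noise anyway. Monomorphic variants
admit no test; their HWE p is defined as 1 and they are flagged (they are
subsequently dropped by the association scans, which detect the
rank-deficient design).

## The mediation engine

Each grid cell fits three regressions sharing one listwise-deleted sample
(participants missing that variant's dosage, that measure, the outcome or a
covariate drop out of that model only — exclusions are model-specific,
never global):

* path a: measure ~ dosage + age + sex (+ site) + global covariate,
* paths b, c′: outcome ~ dosage + measure + the same covariates,
* path c: outcome ~ dosage + the same covariates.

The global covariate is matched to the mediator type (total surface area
for areas, global mean thickness for thicknesses, ICV for volumes), so that
regional effects are not confounded by head size. Site enters as
fixed-effect indicators whenever more than one site level is present, and
is automatically absent for single-site cohorts; estimates are invariant to
site relabeling.

**Indirect effect.** For a linear outcome the ACME is the product $a\,b$,
and the identity $c = c' + a\,b$ holds exactly for nested least-squares
fits sharing covariates — the test suite asserts it to $10^{-8}$ on every
grid cell as a structural invariant. For a logistic outcome the package
reports the ACME on the risk-difference scale by g-computation: with
fitted mediator model $\hat m_i(d)$ and outcome model, it averages
$P(Y=1 \mid d_i, \hat m_i(d_i+1), z_i) - P(Y=1 \mid d_i, \hat m_i(d_i), z_i)$
over the empirical covariate distribution, holding the direct path at the
observed dosage. The logit (not probit) link is used for binary outcomes.

**Bootstrap.** Inference on the ACME is a nonparametric bootstrap over
participants: percentile 95% interval (BCa offers little at these n and
costs jackknife passes) and two-sided p-value
$2\min\{P(\hat\theta^* \le 0),\, P(\hat\theta^* \ge 0)\}$. The production
default is 5,000 resamples; the test suite uses 200–500. Resamples whose
outcome model fails to converge are dropped; a model whose failure rate
exceeds 20% is returned as an error state, not an estimate. Within a grid,
model $i$ uses seed $\texttt{seed} + i$, so a fixed seed reproduces every
interval bit-for-bit.

One degenerate configuration deserves note: a mediator generated with
*zero* residual variance is an exact linear combination of dosage and
covariates, which makes the outcome design singular. The package raises a
named collinearity error rather than returning arbitrary coefficients.

## Multiple testing and pooling

The 93 measures are strongly correlated (and so are dosages, mildly), so
Benjamini–Hochberg over the raw count of grid cells would be
conservative. `li_ji_meff()` computes the effective number of independent
tests from the eigenvalues $\lambda_i$ of a correlation matrix:
$m_\mathrm{eff} = \sum_i \big[\mathbb{1}(\lambda_i \ge 1) + (\lambda_i -
\lfloor \lambda_i \rfloor)\big]$. For the grid, the measure-correlation and
dosage-correlation matrices are computed on the analysis sample and their
effective counts multiplied (the eigenvalues of a Kronecker product are the
pairwise products, so this is the Li–Ji count of the full
measure-by-variant test family under separability). One global
$m_\mathrm{eff}$ is applied across the whole grid rather than per variant.
Significance then uses BH step-up with $m_\mathrm{eff}$ in place of the
test count: rank-$i$ threshold $i\,q/m_\mathrm{eff}$, rejecting up to the
largest passing rank; each test's rank threshold is reported alongside its
p-value as the adjusted alpha it faced. A plain Bonferroni-over-
$m_\mathrm{eff}$ switch is available (`method = "bonferroni"`). With
$m_\mathrm{eff}$ equal to the test count the procedure reduces exactly to
BH, which the tests verify against `p.adjust`.

Two cohorts' grids are pooled per cell by fixed-effect inverse-variance
meta-analysis, with each cohort's SE recovered from its bootstrap interval
as $(\mathrm{hi}-\mathrm{lo})/(2 z_{0.975})$. Fixed effect, not random:
two cohorts give no usable heterogeneity estimate.

## The MR engine

For each candidate measure (by default the significant mediators), the
per-variant exposure and outcome associations are estimated in the same
participants with the mediation covariates (one-sample design; there is no
two-sample summary-statistic mode). With $\beta_{Xj}, \beta_{Yj}$ and
outcome SEs $\sigma_j$:

* **IVW**: $\hat\theta = \sum_j \beta_{Xj}\beta_{Yj}/\sigma_j^2 \big/
  \sum_j \beta_{Xj}^2/\sigma_j^2$, fixed-effect SE
  $(\sum_j \beta_{Xj}^2/\sigma_j^2)^{-1/2}$ — weighted regression through
  the origin; at $k=1$ it is the Wald ratio. No multiplicative
  random-effects inflation is applied; Cochran's Q is reported so users can
  judge heterogeneity themselves.
* **Weighted median**: Wald ratios sorted, inverse-variance weights
  normalized, the estimate interpolated where the standardized cumulative
  weight $s_j = \sum_{i\le j} w_i - w_j/2$ crosses one half; SE from a
  200-draw parametric bootstrap of the per-variant associations.
* **MR-Egger**: weighted regression with free intercept after orienting
  every instrument so $\beta_{Xj} \ge 0$; the slope is the causal estimate
  and the intercept tests directional pleiotropy. Constraining the
  intercept to zero reproduces IVW exactly (asserted to $10^{-10}$).
  No SIMEX dilution correction is applied; instead
  $I^2_{GX} = \max\{0, (Q_{GX} - (k-1))/Q_{GX}\}$ (computed from the
  exposure-association heterogeneity $Q_{GX}$; the $Q_{GX}$-based rather
  than mean-F-based variant) flags slopes with $I^2_{GX} < 0.80$ as
  dilution-prone.

Reverse-direction analyses use the LOAD outcome as exposure; for binary
LOAD the exposure associations are logistic coefficients, so the reverse
estimates are per log-odds of LOAD — the scale is a property of the
outcome column supplied, and either proxy or case-control outcomes are
accepted. BH correction at 5% is applied across measures within each
direction-method stratum. Leave-one-out IVW re-estimates accompany every
model; with $k=2$ each re-estimate degenerates to a Wald ratio and is
flagged.

## The synthetic-cohort generator

The generator's role is to produce data with exactly the statistical
structure the estimators assume, so that recovery of planted parameters is
a meaningful end-to-end check. It emulates: Hardy–Weinberg genotypes at
specified allele frequencies with MCAR missingness; APOE genotypes drawn as
haplotype pairs (ε1 omitted — its European frequency is far below 1% —
though the counting code still handles it); regional measures from a linear
mediator model on the standardized scale (default covariate loadings:
−0.01 SD per year of age, 0.05 SD for male sex, 0.3 SD per SD of ICV on
volumes; residual SD 1); a logistic case/control outcome; and parental
records whose affection probability is logistic in the participant's own
genetic liability attenuated by 0.5 (one meiosis transmits half the
dosage in expectation — parental genotypes are not simulated explicitly,
which is simpler and sufficient to create a nonzero total effect).
Demographics default to the two cohort styles' reference values (proxy:
age 64.4 ± 7.7, 47.7% male, 3 sites; case-control: age 76 ± 7.2, one
site); ages and parental ages are Gaussian truncated to [40, 100], parental
affection base rate 0.118 with ages N(75, 10) — chosen so the proxy score's
mean (≈ 0.65) and SD (≈ 0.36) approximate the values reported for biobank
samples (0.66, 0.41); the exact shape of the score's distribution is not
published, only its non-normality, which the generator reproduces.

It deliberately does **not** emulate: linkage disequilibrium between SNPs,
imputation noise, site effects on measures, the empirical correlation
structure of real regional measures (measures are conditionally independent
given genotype and covariates), or mediator-dependent parental outcomes
(a participant's own brain cannot affect a parent's disease, so in proxy
cohorts true path-b effects exist only in case-control simulations).
Passing tests therefore certify the estimators and the pipeline plumbing —
not robustness to LD-induced instrument correlation or to real-world
mediator covariance, which users must assess on their own data.

## Problem sizes, seeds and numerical choices

Everything is deterministic given seeds: cohorts are a function of the
config seed, grid model $i$ uses base seed + $i$, the pipeline derives
stage seeds from its master seed by fixed offsets. Point estimates are
invariant to row order and site relabeling; bootstrap draws (and hence CI
endpoints) are tied to the seed.

The test suite scales simulations to what the checks need rather than to
production sizes: parameter-recovery cohorts of n = 5,000 (path a, where
the Monte-Carlo SE of a standardized per-allele coefficient at allele
frequency 0.15 is ≈ 0.028) and n = 10,000 (bootstrap ACME, 500 resamples);
the full 11 × 93 = 1,023-cell grid at n = 300 with 200 resamples;
bootstrap-coverage calibration over 300 datasets of n = 1,000 with 200
resamples (95% ± 3 points); type-I calibration over 5,000 replicates of
n = 500. The production bootstrap default stays 5,000.

Other numerical conventions: sample SD ($n-1$) in z-scores; percentile
(not BCa) bootstrap intervals; dosage treated as numeric additive 0/1/2
(including the ε4 count); quantile type 7 (R default) for percentile
endpoints; HWE p defined as 1 for monomorphic variants; degenerate
bootstrap intervals of width 0 yield SE 0 with a warning since they break
inverse-variance weights; correlation matrices for Li–Ji use
pairwise-complete observations with non-finite entries mapped to 0.

## Known limitations

* No exposure–mediator interaction terms and no sensitivity analysis for
  sequential ignorability: the mediation estimates are causal only under
  no unmeasured confounding of all three arrows.
* One-sample MR with mediation covariates inherits winner's-curse and
  weak-instrument biases that two-sample designs partially avoid; the
  I²_GX flag is a warning, not a correction.
* Fixed-effect pooling assumes both cohorts estimate the same quantity;
  with a proxy-score outcome in one cohort and case-control log-odds in
  the other, the pooled value mixes scales and should be read as a test of
  directionally consistent mediation rather than a single effect size.
* Site is a fixed effect; no multilevel site models.
* The Li–Ji product rule assumes measure-by-variant separability of the
  test-statistic correlation; strong variant-specific measure effects would
  violate it mildly.
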