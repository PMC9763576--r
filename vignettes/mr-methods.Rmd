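---
title: "Two-sample Mendelian randomization with hcymr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with hcymr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcymr)
```

## The causal model

Two-sample Mendelian randomization (MR) estimates the causal effect of a
modifiable exposure (here: plasma homocysteine) on an outcome (binary liver
disease traits) using genetic variants as instrumental variables, with the
variant-exposure and variant-outcome associations estimated in two
non-overlapping GWAS samples. For instrument $j$ the observed summary
statistics are $\hat\beta_{Xj} \sim N(\beta_{Xj}, \sigma_{Xj}^2)$ and
$\hat\beta_{Yj} \sim N(\beta_{Yj}, \sigma_{Yj}^2)$, independent across
samples, and the working structural model is

$$\beta_{Yj} = \theta\,\beta_{Xj} + \alpha_j,$$

where $\theta$ is the causal effect (log-odds of disease per unit exposure)
and $\alpha_j$ is variant $j$'s direct (horizontally pleiotropic) effect on
the outcome. A valid instrument satisfies relevance
($\beta_{Xj} \neq 0$), independence from confounders, and the exclusion
restriction ($\alpha_j = 0$). The estimators differ in how much deviation
from $\alpha_j = 0$ they tolerate.

## Data preparation

`read_summary_table()` ingests delimited summary statistics with a
configurable column map; `harmonize()` inner-joins exposure and outcome
tables on rsid and aligns the outcome to the exposure's effect allele,
negating the outcome beta (and complementing the frequency) when the allele
pair is swapped. Allele pairs that are neither identical nor swapped are
dropped with a warning. Palindromic SNPs (A/T, C/G) cannot be
strand-resolved from summary data; the default policy keeps them but
records a flag, which is the right behaviour when both GWAS are known to
report the same strand (as in the packaged dataset, whose tables ship
pre-aligned). Harmonization is idempotent, and a double allele flip is the
identity — both properties are exercised in the test suite.

Instrument selection follows the conventional funnel:
`select_by_pvalue()` keeps genome-wide-significant associations (default
$p < 5\times10^{-8}$); `ld_prune()` greedily clumps against a user-supplied
local LD matrix, visiting SNPs by ascending p-value (rsid tie-break, making
the procedure deterministic) and accepting a SNP only if its $r^2$ with
every accepted SNP is below the threshold; `exclude_rsids()` applies
explicit exclusion lists (e.g. variants lacking outcome information or
flagged by confounder screening). The pruning default is $r^2 < 0.05$, a
strict near-independence requirement appropriate when instruments are
combined with equal standing in a meta-analysis; a threshold of 1 disables
pruning. The packaged 18-candidate demonstration reproduces the
12-instrument homocysteine panel: three candidates are removed by LD at
$r^2 \ge 0.9$ with stronger partners and three by the exclusion list. The
LD values in that fixture are synthetic (constructed, not measured), and
one candidate id (`rs0cand18`) is a synthetic placeholder: the study the
panel derives from names only 17 of its 18 candidates, listing one variant
both as information-lacking and as a retained instrument. The fixture keeps
the retained panel authoritative and routes the inconsistency into the
placeholder, flagged rather than resolved.

## Estimators

**Wald ratios.** Each instrument's ratio estimate is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order standard
error $\sigma_{Yj}/|\hat\beta_{Xj}|$ and inverse-variance weight
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$. The first-order SE ignores
exposure-side uncertainty, consistent with the weights used throughout;
`wald_ratios(second_order = TRUE)` adds the delta-method second term for
users who want it.

**IVW.** The inverse-variance-weighted estimate
$\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$ is algebraically the
weighted least-squares slope of $\hat\beta_Y$ on $\hat\beta_X$ through the
origin with weights $1/\sigma_{Yj}^2$ — the test suite verifies the two
formulations agree to $10^{-12}$. The fixed-effect standard error is
$(\sum_j w_j)^{-1/2}$; the multiplicative random-effects model scales it by
$\max\{1, \sqrt{Q/(J-1)}\}$ with Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$. Random effects is the
package default: it is the standard default in summary-data MR software, it
reduces exactly to fixed effects when the instruments are homogeneous
($Q \le J-1$), it is never anti-conservative, and it is the model under
which the packaged dataset reproduces its reference results — for the NASH
and cirrhosis outcomes, whose instruments are over-dispersed, the
fixed-effect intervals are visibly too narrow, while the NAFLD outcome
(homogeneous, $Q/(J-1) < 1$) is identical under both models.

**Weighted median.** Ratios are ordered, weights normalized, and each ratio
placed at its cumulative weight minus half its own weight (the midpoint
convention); the estimate is the linear interpolation at cumulative weight
0.5, clamped to the extreme ratios. The convention matters only at small
$J$ and midpoint is the dominant choice in the MR literature. The standard
error comes from a parametric bootstrap (default 1000 replicates):
exposure and outcome effects are redrawn from
$N(\hat\beta, \hat\sigma^2)$, ratios and weights recomputed, and the SE is
the standard deviation of the replicate estimates. A seed is mandatory; the
estimator is bit-reproducible, and its RNG use never leaks into the
caller's stream.

**MR-Egger.** After orienting every instrument to a positive exposure
effect (negating both betas where needed — a transformation all ratio
statistics are invariant to), the slope of the weighted regression of
$\hat\beta_Y$ on $\hat\beta_X$ *with a free intercept* estimates $\theta$
under the weaker InSIDE condition, and the intercept estimates the average
directional pleiotropy per SNP. Weights are $1/\sigma_{Yj}^2$; standard
errors use the unit-weight covariance scaled by
$\max\{1, \sqrt{\mathrm{RSS}/(J-2)}\}$, the same truncated multiplicative
overdispersion as IVW. The intercept's two-sided normal p-value is the
pleiotropy test. An all-equal oriented exposure vector has no leverage and
raises a singular-design error rather than returning noise.

All confidence intervals are Wald intervals with
$z = \Phi^{-1}(1-\alpha/2)$ (no t correction) and all p-values two-sided
normal; with 12 instruments this matches the reference results of the
packaged dataset and is what summary-data MR software conventionally does.
Estimates are reported on both the log-odds scale and the exponentiated
odds-ratio scale; `ci_low` and `ci_high` are exponentiated bounds.

## MR-PRESSO

The PRESSO family tests for pleiotropic outliers by residual resampling.
For each SNP the causal effect is re-estimated by fixed-effect IVW on the
other $J-1$ instruments, giving the leave-one-out prediction
$\hat\theta_{-j}\hat\beta_{Xj}$; the observed statistic is the weighted
residual sum of squares
$\mathrm{RSS} = \sum_j (\hat\beta_{Yj} - \hat\theta_{-j}\hat\beta_{Xj})^2
/ \sigma_{Yj}^2$ (the division by $\sigma_{Yj}^2$ is fixed here because
implementations differ). Its null distribution is simulated: outcome
effects are redrawn around their leave-one-out predictions at the reported
SEs and the entire leave-one-out statistic recomputed per replicate.
By default only outcome effects are redrawn; `simulate_exposure = TRUE`
also redraws exposure effects, since whether exposure uncertainty belongs
in the null is a genuine modelling choice. Empirical p-values use the
add-one convention $(\#\{\mathrm{sim} \ge \mathrm{obs}\}+1)/(n_{sim}+1)$
and therefore live in $[1/(n_{sim}+1), 1]$ — never exactly zero.

The global test compares the total RSS; the outlier test compares each
SNP's weighted squared residual to its own simulated distribution, flagging
SNPs below the Bonferroni-adjusted threshold $0.05/J$; when outliers are
flagged and at least three instruments remain, the outlier-corrected IVW
estimate is reported, and the distortion test compares the relative shift
$(\hat\theta_{corr}-\hat\theta_{all})/|\hat\theta_{all}|$ against the shift
from removing random SNP sets of the same size. Defaults are 1000
simulations and a mandatory seed. With fewer than four instruments the
residual-resampling logic is meaningless and the functions refuse to run.

## The synthetic generator

`generate_dataset()` draws summary statistics from the structural model
above so every estimator can be validated against known truth. Defaults
mirror the packaged dataset's scales, chosen once as the study conditions
for all calibration tests: exposure effect magnitudes
$|N(0.08, 0.04^2)|$ floored at 0.02 (the packaged panel spans
0.04–0.16), exposure SEs uniform on 0.007–0.013, outcome SEs uniform on
0.037–0.063 (the NAFLD column's range — binary outcomes with few cases are
represented purely through large outcome SEs, since estimators only ever
see summary statistics). Instrument signs are randomized by default, and
pleiotropic effects are expressed relative to the exposure-increasing
allele ($\beta_{Yj} = \theta\beta_{Xj} + \mathrm{sign}(\beta_{Xj})
\alpha_j$): otherwise random allele orientation would cancel directional
pleiotropy on average and no estimator could see it. Pleiotropy regimes:
`none`, `balanced` ($\alpha_j \sim N(0,\tau^2)$), `directional`
($N(\mu,\tau^2)$); `inside_rho` correlates $\alpha_j$ with instrument
strength to violate InSIDE; `outlier_spec` shifts one observed outcome
effect by a stated number of its SEs, the planted-outlier device used to
validate PRESSO. Exposure and outcome noise are independent, honouring the
two-sample design.

What the generator does *not* emulate: LD between instruments (the LD path
is tested with hand-built matrices), individual-level case-control
sampling, non-normal estimation error, winner's curse in instrument
selection, and sample overlap. Passing calibration tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness of MR itself to those violations in real data.

`recovery_experiment()` repeats generate-estimate cycles and reports bias,
empirical SD, CI coverage and null rejection per estimator. The packaged
validation uses 500 replicates for IVW type-I error and coverage (checked
against exact binomial 95% bands around 0.05 and 0.95; the fixed-effect
model is the one tested, because under the generative null its z-statistic
is exactly standard normal, whereas the random-effects truncation is
deliberately conservative) and 100 replicates at 500 simulations each for
planted-outlier detection — sizes at which the binomial bands are tight
enough to be informative while the whole suite runs in seconds.

## Numerical and design notes

* Wald intervals reproduce three-decimal reference values for the packaged
  dataset only with $z = 1.959964$, not a $t_{11}$ quantile; the package
  therefore uses normal quantiles everywhere.
* The exposure's unit is treated as opaque ("per unit homocysteine"): the
  source tables do not state whether effects are per µmol/L or per SD, and
  nothing in the estimators depends on it.
* `ivw(model = "random")` truncates the dispersion at 1 rather than letting
  under-dispersion shrink the SE below fixed-effect.
* Weighted-median interpolation clamps at the extreme ratios, so the
  estimate always lies within the ratio range.
* Empty intersections, zero exposure betas, non-positive SEs, asymmetric LD
  matrices, and too-few-instrument calls all raise early, specific errors
  naming the offending rsids or files.
* `run_analysis()` derives every stochastic stage from the single
  configured seed, so identical configurations produce byte-identical
  report files; the run log records seeds, thresholds, exclusions and
  flips.
* No multiple-testing correction is applied across outcomes: each outcome
  is reported marginally, matching the per-outcome reporting convention of
  the analyses this package is designed to support.

## Worked example

```{r example}
d <- hcy_table1()
ds <- harmonize(d$exposure, d$outcomes$NAFLD, outcome_label = "NAFLD")
mr_ivw(ds)
mr_weighted_median(ds, n_boot = 1000, seed = 1)
mr_egger(ds)
mr_presso(ds, n_sim = 1000, seed = 1)
```
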