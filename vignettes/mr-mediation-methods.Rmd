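---
title: "Methods: two-sample MR mediation with observational triangulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR mediation with observational triangulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The question the package answers

Educational attainment is associated with low back pain (LBP), but
observational associations of this kind are confounded and potentially
reverse-causal. `mrmediate` implements the full inference stack for asking,
with genome-wide association study (GWAS) summary statistics alone, (i)
whether education causally lowers LBP risk, and (ii) how much of that effect
flows through modifiable lifestyle mediators — smoking and body mass index
(BMI) being the canonical pair — with a survey-weighted observational arm to
triangulate the genetic answer against a designed population sample.

The package is tidyverse-native: every user-facing function takes a data
frame first and returns a tibble, fitted objects have `tidy()`/`glance()`
methods, and result types have `autoplot()` methods.

## Notation and the causal model

Write $\gamma$ for the total effect of education (per SD, 4+ years of
schooling) on the log-odds of LBP, $\gamma^*$ for the direct effect after
adjusting for the mediators, $\alpha_m$ for the per-SD effect of education on
mediator $m$, and $\beta_m$ for the effect of mediator $m$ on LBP conditional
on education. These satisfy, in a linear-in-the-parameters structural model,

$$\gamma = \gamma^* + \sum_m \alpha_m \beta_m .$$

Per-mediator indirect effects are estimated by the product method
($\alpha_m \beta_m$); the joint indirect effect by the difference method
($\gamma - \gamma^*$); proportions mediated as
$P = 100\,\cdot\,\text{indirect}/\gamma$.

## Two-sample MR machinery

**Instrument selection.** Exposure instruments pass a strict
$p < 5\times10^{-8}$ filter, greedy LD clumping ($r^2 > 0.001$ within
10,000 kb of the index SNP), exclusion of variants associated with the
outcome at $p < 5\times10^{-6}$, and an instrument-strength screen
$F = (\hat\beta/\mathrm{se})^2 > 10$. All thresholds are configurable in
`run_config()`; p-value comparisons are strict inequalities. Clumping breaks
p-value ties by lexicographic SNP id so results are independent of row order;
the window is the pairwise distance to the index SNP, inclusive.

**Harmonization.** Effects are aligned to the exposure's effect allele; swaps
flip the outcome beta, strand flips are resolved by complementing, and
palindromic variants are aligned by allele frequency when
$|\mathrm{eaf}-0.5| \ge 0.08$ in both tables and dropped otherwise. The 0.08
band is the common two-sample default and is exposed as an argument.
Harmonization is an involution: re-harmonizing aligned data is a no-op.

**Estimators.** The primary estimator is inverse-variance weighting (IVW):
the weighted through-origin regression of outcome on exposure effects with
weights $1/\mathrm{se}_y^2$,
$\hat\gamma = \sum w_j \hat b_{x,j}\hat b_{y,j} / \sum w_j \hat b_{x,j}^2$.
The default standard error is multiplicative random-effects,
$\mathrm{se}_{\text{fixed}} \cdot \max(1, \sqrt{Q/(n-1)})$, which reduces to
the fixed-effect SE exactly when heterogeneity is below its expectation.
Sensitivity estimators: MR-Egger (weighted regression with intercept after
orienting exposure effects non-negative; the intercept is the directional
pleiotropy test), the weighted median (interpolated 50% point of the
inverse-variance-weighted ordered Wald ratios; bootstrap SE), and the
weighted mode (kernel-smoothed weighted ratio density, Silverman rule-of-thumb
bandwidth scaled by `phi`, argmax on a 512-point grid; bootstrap SE).
Diagnostics: Cochran's Q for IVW and Egger fits, leave-one-out IVW, and an
MR-PRESSO-style global/outlier test re-implemented from its published logic
(leave-one-out expected values, parametric simulation of the residual sum of
squares, rank-based global p, Bonferroni per-SNP outlier test, corrected IVW
on the surviving set). Exact numerical equality with the original MR-PRESSO
package is not claimed; with the rank-based per-SNP p-value the smallest
attainable p is $1/(n_{\text{sim}}+1)$, so `n_sim` must exceed
$n_{\text{snp}}/\alpha$ for the Bonferroni outlier test to be able to reject
— the default `n_sim = 1000` supports up to 50 instruments at
$\alpha = 0.05$.

**Multivariable MR.** `assemble_mv()` unions per-trait instruments, re-orients
every harmonized set to the outcome's allele orientation so the shared
outcome column is consistent, and drops SNPs missing from any trait (the
alternative — imputing zero — would bias joint estimates; drops are logged).
`mvmr_ivw()` is weighted least squares of outcome effects on the SNP-by-trait
effect matrix without intercept; SEs come from the weighted information
matrix with the same multiplicative-RE scaling, now with $n-K$ degrees of
freedom. `mvmr_lasso()` adds one L1-penalized intercept per SNP (coordinate
descent, soft-thresholding); SNPs with nonzero intercepts at the selected
penalty are treated as invalid and removed, and the reported estimate is the
post-selection `mvmr_ivw()` on the valid set. The penalty is chosen as the
smallest grid value whose valid-set Q statistic has $p > 0.05$ — a
heterogeneity-minimizing rule; $\lambda = 0$ is rejected because a free
intercept per observation is unidentified.

**Sample overlap.** `overlap_bias()` implements the standard approximation
for the bias of a two-sample MR estimate when a fraction $c$ of participants
is shared between the exposure and outcome GWAS:
$\text{bias} = c \cdot \theta_{\text{conf}} / \bar F$, interpolating between
zero at no overlap and the confounded observational association attenuated by
instrument strength, with implied type-I error
$P(|Z| > z_{1-\alpha/2})$, $Z \sim N(\text{bias}/\mathrm{se}_{IV}, 1)$. The
formula is first order in $1/\bar F$; the acceptance suite cross-checks it
against simulation at overlap 0, 0.5 and 1 with weak instruments
($\bar F \approx 6$) and allows 15% of the predicted bias on top of
Monte-Carlo error for the neglected higher-order terms.

## Mediation decomposition

`decompose_mediation()` assembles per-mediator product-method indirect
effects with delta-method SEs
($\sqrt{\alpha^2\mathrm{se}_\beta^2 + \beta^2\mathrm{se}_\alpha^2}$,
independent two-sample coefficients), the joint difference-method effect with
$\mathrm{se} = \sqrt{\mathrm{se}_\gamma^2 + \mathrm{se}_{\gamma^*}^2 - 2\,\mathrm{cov}}$,
and proportions mediated in percent. Because $\gamma$ and $\gamma^*$ are
estimated from overlapping instrument sets their covariance is positive but
unreported in summary-level work; the default $\mathrm{cov} = 0$ therefore
*overstates* the joint-indirect SE, which is the conservative direction. CIs
for proportions use the independence delta approximation by default with a
parametric bootstrap as the alternative; both are reconstructions — published
mediation tables rarely state their CI method. Proportions are flagged rather
than suppressed when the indirect and total effects conflict in sign or when
$|P| > 100$ ("suppression"), and indirect effects with $p \ge 0.05$ are
labelled "no mediating effect", mirroring how such rows are reported in
practice.

## The observational arm

`weighted_glm()` fits logistic or linear regressions by weighted IRLS and
estimates variance by Taylor linearization: per-unit score contributions
$w_i x_i (y_i - \mu_i)$ are summed within PSU, their between-PSU variance is
accumulated within stratum with the $n_h/(n_h-1)$ finite-cluster factor, and
the result is sandwiched between the inverse weighted information. Without
design columns the weight-based HC0 sandwich is used. Weights are normalized
to mean 1 internally — coefficients and the linearized variance are invariant
to weight scale, and IRLS is then numerically stable for weights that sum to
a population total. Single-PSU strata contribute no variance (and are the
user's design problem); the design df is (number of PSUs) − (number of
strata).

The model ladder reproduces the crude-to-fully-adjusted sequence of
education–outcome models, with a trend test that recodes education as a
single ordinal 0/1/2 term. Subgroup analyses refit the model within each
stratum of a mediating factor (dropping that factor from the covariates) and
test interaction two ways: a likelihood-ratio test on the weighted
pseudo-log-likelihood, and a Wald test on the interaction coefficients
referred to an F distribution with the design df. The pseudo-likelihood LRT
is exact when all weights are equal but is anti-conservative under unequal
weights by roughly the design effect $1+\mathrm{cv}^2_w$ (the weighted score
variance exceeds the weighted information); this is a known property, the
reason the Wald F test is emitted alongside, and the reason the calibration
suite checks the LRT under an equal-weight design and the Wald F test under
the weighted one. `rubin_pool()` combines estimates across multiply imputed
datasets (within-variance plus $(1+1/m)$ times between-variance, standard
small-sample df); the imputation engine itself is out of scope — the module
pools completed datasets.

`observational_mediation()` estimates $\alpha'$ (education on the mediator:
logistic for ever-smoking, linear for BMI) and $\beta'$ (the mediator in the
outcome model adjusting for education), on binary above-high-school
education, feeding the same `decompose_mediation()` machinery. Binary
mediators on the logit scale make product- and difference-method joint
indirects diverge (noncollapsibility); the package reports both and leaves
the interpretation caveat here rather than hiding either number.

## The synthetic-data generator

`simulate_cohorts()` instantiates the structural model
genotype → education → {smoking, BMI} → LBP:

* **Genotypes**: dosages from two thresholded latent-Gaussian haplotypes per
  individual, independent blocks of 4 SNPs with AR(1) latent correlation
  0.4 — exact, controllable LD for clumping tests. Minor allele frequencies
  are uniform on (0.10, 0.45).
* **Traits**: education is a weighted instrument score (variance
  `h2_exposure = 0.25` over 40 causal blocks, one causal SNP per block) plus
  a shared standard-normal confounder $U$ (loading 0.3 on every trait) plus
  noise, built to unit variance; each mediator adds its own 25 causal blocks
  (`h2_mediator = 0.2`) to $\alpha_m \cdot$ education. The per-mediator
  instrument blocks are what make the mediator→outcome and multivariable
  paths identified; they play the role of the mediators' own GWAS signals.
* **Outcome**: the liability $\gamma^*\text{edu} + \sum\beta_m m + 0.3U$
  (+ optional per-SNP pleiotropy) receives *standard logistic* noise and is
  dichotomized at the empirical quantile giving prevalence 0.074. Logistic
  noise makes the threshold model exactly a logistic regression model, so the
  structural coefficients live on the log-odds scale that the per-SNP
  logistic summary statistics estimate. Marginal per-SNP log-odds remain
  attenuated by noncollapsibility (factor $\approx 0.92$ at these parameter
  values, $1/\sqrt{1 + 0.346\,\sigma^2_{lp}}$) — visible as a few-percent
  shrinkage of recovered $\gamma$, $\gamma^*$, $\beta$ toward zero, well
  inside the 3-SE recovery tolerances and cancelling in the mediated
  *proportions*, which are ratios.
* **Cohorts**: each trait gets its own cohort (default 20,000 for the
  continuous traits and 60,000 for the outcome, reflecting that registry
  case-control outcome GWAS are typically the largest of the set); cohorts
  are disjoint except that the first $\lceil c\,n \rceil$ outcome individuals
  reuse exposure-cohort individuals when `overlap_frac = c > 0`. Default
  effects are the mediation-model values $\gamma^* = -0.476$,
  $\alpha = -0.22$ per mediator, $\beta_{\text{smoking}} = \log 1.46$,
  $\beta_{\text{BMI}} = \log 1.18$, implying $\gamma \approx -0.596$.
* **Sizing rationale** (chosen once, with the per-SNP F calculation, not by
  iterating on test outcomes): at 20,000 individuals and $R^2 = 0.25/40$ per
  causal SNP the expected instrument F is $\approx 125$, so the genome-wide
  $5\times10^{-8}$ threshold from real-data practice works unchanged at
  synthetic scale; the 60,000-person outcome cohort gives the weaker BMI path
  ($\beta = 0.166$) a per-run z of roughly 4, so it survives the 0.05
  mediator screen as it did in the source analyses. SNP-level effects are
  drawn from a normal, so a realistic minority of causal SNPs fall below the
  significance threshold in any given run.

`simulate_ivs()` is the fast path: it samples harmonized instrument effects
directly from their sampling distributions (optionally with correlated
errors, `overlap_r` $= c\,r$, emulating cohort overlap) and is what the
replicate-heavy calibration studies use. `simulate_survey()` draws an
NHANES-like population: fixed covariate marginals, ever-smoking and BMI from
their education equations (defaults: log-odds −0.478 and −0.16 kg/m² per
education level), an LBP logit with baseline prevalence 0.39 and per-level
direct effects $\log 0.93/\log 0.72$, log-normal weights scaled to a
population total, and a stratified design with ≥2 PSUs per stratum.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: realistic human LD maps and allele-frequency
spectra, polygenic backgrounds calibrated to the real traits, case-control
ascertainment, assortative mating or dynastic effects, informative sampling
weights, and item nonresponse beyond MCAR. Parameter recovery here
demonstrates correctness of the estimators under the stated model, not
robustness to everything real data can do.

## Calibration-study conditions

The test suite fixes these conditions (sizes chosen for a laptop-scale run;
each stochastic suite states its replicate count in the test):

* *IVW coverage* is assessed at $\gamma = -0.658$ over 300 fast-path
  replicates of 50 instruments under mild balanced pleiotropy (per-SNP
  direct effects $N(0, (0.3\,\mathrm{se}_y)^2)$). Mild heterogeneity is the
  realistic regime — the source analyses themselves report heterogeneity —
  and it is the regime the default multiplicative-RE model is specified for;
  under exact homogeneity the $\max(1,\cdot)$ floor makes the interval
  conservative (~0.99 coverage) by construction.
* *Egger intercept size*: 400 null replicates, 40 SNPs. *Q/df*: 200
  replicates, 30 SNPs. *MR-PRESSO*: 50 replicates of a planted +10 SE
  outlier among 30 SNPs, 1000 simulations each, plus 50 clean replicates for
  specificity.
* *Interaction tests*: 150 null survey replicates of n = 1500; the LRT under
  the equal-weight design, the Wald F under log-normal weights (see above).
* *Overlap*: 400 fast-path replicates per overlap fraction {0, 0.5, 1} with
  30 instruments of mean F ≈ 6 and confounded association 0.6.
* *End-to-end recovery*: one full default-scale run (≈ half a minute) must
  put every structural coefficient within 3 SE of its generating value and
  the joint mediated proportion within 3 SE of
  $100(1 - \gamma^*/\gamma) \approx 20\%$.

## Numerical and degenerate-input choices

* Weak instruments ($F \le 10$) are dropped by default (`action = "flag"`
  keeps them marked) — the convention states the threshold but not the
  action.
* `wald_ratio()` SE is first-order (outcome error only) by default;
  second-order is available and validated against Monte-Carlo.
* Zero exposure effects: `wald_ratio(bx = 0)` and all-zero IVW are errors,
  not NaNs. A zero-variance trait column in MVMR raises a rank error naming
  the column.
* `se = 0` degenerates p-values to 1 (zero estimate) or 0 rather than NaN.
* Bootstrap and simulation seeds are explicit arguments everywhere; no
  function touches the global RNG state without restoring it.
* Bonferroni significance labelling in the pipeline uses
  $p < 0.05/13$ by default (`bonferroni_m`), as a labelling step only —
  changing it never changes estimates.
* Mediator screening in `run_mr_arm()` (drop mediators with null unadjusted
  outcome effects before MVMR; drop MVMR-null mediators before mediation) is
  an explicit, logged, config-driven step (`screen_alpha = 0.05`), so
  exclusions of null mediators are reproducible decisions rather than
  hard-coded trait names.

## Known limitations

* MVMR conditional instrument strength (conditional F) is not computed;
  plain per-column mean F stands in.
* MVMR-Egger and MVMR-median are not implemented.
* The difference-method SE ignores the $\gamma,\gamma^*$ covariance
  (conservative); a joint bootstrap over shared instruments would tighten
  it.
* The survey arm implements Taylor linearization only — no replicate-weight
  (BRR/jackknife) variance — and the imputation engine is out of scope.
* Figure rendering is limited to the `autoplot()` methods; the pipeline's
  file outputs are CSV/JSON.
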