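---
title: "Cross-classified growth-curve modelling of parcellated task-fMRI data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-classified growth-curve modelling of parcellated task-fMRI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parcelgrowth)
```

# The problem

Developmental task-fMRI studies often ask whether the brain's response to a
task condition changes across adolescence, and whether that change is
specific to particular functional territories. `parcelgrowth` implements a
parcel-level answer: per-session whole-brain contrast images are reduced to
one mean estimate per atlas parcel, harmonized, and modelled jointly with a
cross-classified polynomial growth model in which observations are nested in
*both* participants and parcels — two crossed grouping factors, neither
nested in the other.

The motivating design is an accelerated three-wave cohort: participants are
scanned up to three times roughly three years apart, with wave age
distributions centred near 10, 13 and 16 years, so the pooled sample covers
ages 9–17 although no single participant does. Each session contributes a
2 x 2 within-person condition design (information *domain*:
Academic/Social; evaluation *target*: Other/Self), and each parcel carries a
category label (*self*, *social*, or *control*) describing the functional
literature it belongs to.

# Signal extraction and harmonization

For each contrast image and each atlas parcel, the extracted value is the
arithmetic mean of the image over the parcel's voxels. Three deliberate
choices:

* **No resampling.** The image and atlas must agree exactly on grid shape
  and voxel spacing (`validate_alignment()`); alignment is an upstream
  responsibility and silently resampling is a classic source of
  irreproducibility.
* **Non-finite voxels are dropped** from numerator and denominator rather
  than zero-filled; a parcel with no finite voxel becomes a missing row with
  a warning.
* **Within-parcel standardization divides by the parcel's sample standard
  deviation** (denominator $n-1$) computed over all sessions and conditions
  of that parcel, with no mean-centering. Dividing (rather than z-scoring)
  equates variability between parcels while preserving the condition
  contrasts the model estimates. Pooling over all sessions and conditions is
  the default (`pooling = "parcel"`); a per-condition-cell divisor is
  available (`pooling = "cell"`) for sensitivity analyses.

Outliers are then removed globally: observations farther than 3 grand
standard deviations from the grand mean of all standardized values are
excluded, and `exclude_outliers()` reports the count and fraction. The
grand statistics are computed once over the whole table, not per parcel;
with a single global threshold the exclusion set is a deterministic function
of the input.

# The two growth models

Let $Y_{ijk}$ be the standardized response of participant $j$ in parcel $k$
at observation $i$. Age enters centred at 13 years ($a = \text{age} - 13$),
so every intercept-like quantity refers to a 13-year-old, and the quadratic
term is the square of the centred age. The two condition factors are coded
$-0.5/+0.5$ (Academic/Social, Other/Self), making main effects averages over
the other factor's levels. Parcel category uses treatment coding with
*control* as the reference level, so each within-cell growth term appears
three times: a control-parcel column and its two label-interaction columns.

* **Domain model** ("Model 1"): within-cell terms
  $\{1, a, a^2, D, aD, a^2D\}$, giving $6 \times 3 = 18$ fixed effects.
* **Domain-by-target model** ("Model 2") adds
  $\{T, TD, aT, a^2T, aTD, a^2TD\}$: 12 terms, 36 fixed effects.

Coefficients are named by the convention `gamma_<b>00` (control) and
`gamma_<b>01.self` / `gamma_<b>01.soc` (label moderation), where `b` indexes
the within-cell term.

Random effects cross participants and parcels. The canonical structures are:

| block | Model 1 | Model 2 |
|---|---|---|
| participant | intercept, age, domain | intercept, age, domain, age x domain, target, target x domain, age x target, age x target x domain |
| parcel | intercept, age, age², domain | all 12 terms |

with unstructured (full) covariance in each block. The parameter counts are
then $18 + 6 + 10 + 1 = 35$ and $36 + 36 + 78 + 1 = 151$
(`count_parameters()`), counting $q(q+1)/2$ covariance parameters per
full-covariance block plus one residual variance. Both structures are fully
configurable (`make_model1_spec()` / `make_model2_spec()` take term lists,
and `re_block()` supports diagonal covariance), because in practice random
structures are trimmed until fits converge off the boundary.

# Estimation

The engine is written from first principles around the profiled deviance of
the Gaussian mixed model. Writing the stacked random effects as
$Z\Lambda(\theta)u$ with $u \sim N(0, \sigma^2 I)$ and residuals
$N(0, \sigma^2 I)$, the penalized normal equations

$$
\begin{pmatrix} \Lambda'Z'Z\Lambda + I & \Lambda'Z'X \\ X'Z\Lambda & X'X \end{pmatrix}
\begin{pmatrix} u \\ \gamma \end{pmatrix} =
\begin{pmatrix} \Lambda'Z'y \\ X'y \end{pmatrix}
$$

are solved by a Cholesky factorization of the (1,1) block followed by block
elimination; $\gamma$ and $\sigma^2$ are concentrated out analytically,
leaving only the relative covariance factors $\theta$ (per block, the lower
triangle of the Cholesky factor of $\Psi_b/\sigma^2$) to optimize. The REML
criterion adds the log-determinant of the profiled fixed-effect system. All
cross-products ($Z'Z$, $Z'X$, $X'X$, …) are formed once per fit.

Numerical choices:

* **Parameterization.** Diagonal entries of each relative factor are stored
  on the log scale (unconstrained optimization, positive-definiteness by
  construction); off-diagonals are free. L-BFGS-B bounds the log-diagonals
  below at −8, and a fit with any relative scale below $10^{-3}$ is flagged
  *singular* — reported, never raised as an error, because trimming boundary
  terms is an analyst decision.
* **Solver path.** When the total random-effect dimension is at most 800
  (e.g. 40 participants x 3 terms + 30 parcels x 4 terms = 240), the
  factorization runs on dense BLAS; above that, on a sparse Cholesky
  (`Matrix`), which is the regime of a full cohort (74 x 8 + 352 x 12 =
  4816 columns).
* **Gradient.** On the dense path the analytic gradient of the profiled
  deviance is used (derived via the envelope theorem for the penalized
  residual sum of squares plus trace identities for the two log-determinant
  terms, and verified against finite differences); the sparse path uses
  finite differences. `control = list(fd_gradient = TRUE)` forces finite
  differences everywhere.
* **Convergence.** `optim`'s L-BFGS-B with `factr = 1e7` (about $10^{-9}$
  relative in the deviance) and an iteration budget of 400 by default.
* **Degenerate inputs.** A rank-deficient fixed design is rejected naming
  the collinear columns. A response that is interpolated exactly (penalized
  residual sum of squares numerically zero, e.g. noise-free synthetic data)
  leaves the covariance scales unidentified: the fit is returned at the
  boundary with a warning and the singular flag set, with fixed effects
  equal to the least-squares solution.

Equivalence with an independent implementation (`lme4`) is enforced in the
test suite to $10^{-7}$ relative on the REML criterion, alongside a dense
marginal-likelihood oracle written directly from
$V = \sigma^2(I + Z\Lambda\Lambda'Z')$, and closed-form ANOVA estimators on
balanced one-way layouts.

# Inference

Coefficient and contrast tests are Wald tests with Satterthwaite degrees of
freedom: for $V = \widehat{\mathrm{Var}}(c'\hat\gamma)$,
$\nu = 2V^2/\mathrm{Var}(V)$, where $\mathrm{Var}(V)$ combines the gradient
of $V$ with respect to the covariance parameters (including the log residual
scale) with the inverse curvature of the deviance at the optimum
(finite-difference Hessian, cached per fit). When the curvature is not
positive definite the engine falls back to the normal approximation
($\nu = \infty$) with a warning. Classical limits are recovered: $n_1 +
n_2 - 2$ for a two-group comparison without random effects, $g - 1$ for the
grand mean of a balanced one-way random-intercept layout.

Model comparison uses AIC with a 2-point rule: the richer model is selected
only if its AIC is lower by at least 2; within the 2-point equivalence band
the more parsimonious model wins. Because the literature is genuinely
ambiguous about whether information criteria for mixed models should be
computed from ML or REML deviances, `run_growth_analysis()` reports
REML-based estimates but refits by ML (warm-started) for the comparison by
default (`aic_objective`), and both deviances are available.

Hypothesis tests are organized in four families with Bonferroni correction
inside each family: the domain-moderation pair in social parcels (m = 2),
the target-moderation pair in self parcels (m = 2), and two four-test
families for the four-way interactions and their targeted age-13 simple
slopes (m = 4 each).

# Simple slopes and trajectories

A simple slope is the instantaneous age derivative of a fitted condition
difference at a given age, within a parcel label. For the
Self−Other difference conditioned on domain code $D$ in label $\ell$:

$$
\frac{\partial}{\partial a}\Delta(a) =
(\gamma_{aT} + \gamma_{aT,\ell}) + 2a\,(\gamma_{a^2T} + \gamma_{a^2T,\ell})
+ D\,(\gamma_{aTD} + \gamma_{aTD,\ell}) + 2aD\,(\gamma_{a^2TD} + \gamma_{a^2TD,\ell})
$$

so at age 13 ($a = 0$) only the linear terms remain. `slope_weights()`
builds the contrast weights (placing $2(a-13)$ on quadratic terms), and
`simple_slope()` routes them through `wald_contrast()`; a `"quadratic"`
component returns the curvature coefficient of the difference instead. The
implementation is validated against the central finite difference of the
predicted contrast curve and against hand arithmetic on the shipped
reference coefficients (`reference_gamma()`), which reproduce the reported
age-13 slopes (0.027 for Self−Other on social content in self parcels,
−0.010 for Social−Academic on self-evaluation in social parcels) to within
rounding of the published values.

`predict_trajectories()` evaluates fixed-effect means per (label, domain,
target) cell over an age grid (default 9–17 years in 0.1-year steps, the
sampled range; outside it predictions are flagged as extrapolations), and
optionally per-parcel curves by adding each parcel's predicted random
deviations (BLUPs), whose label-wise average equals the fixed curve plus the
mean parcel deviation by linearity.

# The synthetic cohort generator

`simulate_cohort()` draws the accelerated design directly: per-wave sample
sizes 57/44/34, wave age means 10.08 / 13.06 / 16.33 years (SDs 0.32 / 0.33
/ 0.46), and 35/17/22 participants with 1/2/3 waves. Two points where the
generator had to commit beyond what those margins determine:

* **Within-participant age linkage.** Ages across waves are linked, not
  drawn independently: each participant gets a truncated-normal wave-1
  baseline age and inter-wave gaps drawn N(2.98, 0.3²) and N(3.27, 0.3²)
  years — the gap means are the differences of the wave age means, so the
  simulated wave means reproduce the design's, and longitudinal age paths
  are strictly increasing. Truncation bounds (default 9–17.5 years) avoid
  impossible ages.
* **Retention-pattern assignment.** Which waves the single- and two-wave
  participants attend is not determined by the margins; the default uses an
  attrition-style assignment (21/7/7 single-wave participants at waves
  1/2/3; 12/3/2 two-wave participants with waves 1+2/2+3/1+3) whose margins
  reproduce both the per-wave counts and the retention totals exactly.

`simulate_observations()` reads a model specification generatively:
participant deviations $u_j \sim N(0, \Psi_j)$, parcel deviations
$u_k \sim N(0, \Psi_k)$, residuals $N(0, \sigma^2)$, response
$X\gamma + Z_j u_j + Z_k u_k + \varepsilon$; everything is bitwise
reproducible from the seed. The generator works at the parcel-estimate
level; `generate_nifti_fixture()` additionally builds miniature NIfTI
image/atlas pairs (disjoint box parcels, optional Gaussian voxel noise) so
the extraction stage can be exercised end to end.

What the generator deliberately does **not** emulate: spatial
autocorrelation between neighbouring parcels, heavy-tailed or artifact-driven
outliers, motion-related signal loss, scanner or session effects, and any
hemodynamic structure — synthetic data are exactly Gaussian and exchangeable
within the model's assumptions. Passing recovery tests therefore certify the
estimation machinery, not the biology: they show the pipeline recovers known
truth when its assumptions hold, which is the strongest claim desk-scale
simulation can make.

# Problem sizes and experiment design

Recovery experiments default to a reduced design — 40 participants (73
sessions, same retention proportions) x 30 parcels (6 self / 9 social / 15
control) x 4 conditions, about 8,760 rows — chosen so that a replicate
simulate-and-fit cycle takes under a second and a 200-replicate coverage
experiment runs in minutes. Coverage experiments simulate and fit the domain
model's full generative structure (16 covariance parameters); the size
(type-I error) experiment for the primary target-moderation test uses the
domain-by-target fixed effects with intercept-only random blocks, keeping
400+ replicates cheap. Replicate fits warm-start at the previous replicate's
covariance parameters, which changes only the iteration count, not the
optimum.

Recovery confidence intervals default to the normal approximation
(`ci_method = "normal"`): at several thousand observations per fit the
difference from t-intervals is negligible for most coefficients, but note
that contrasts whose Satterthwaite degrees of freedom are governed by the 30
parcels (label contrasts) can undercover by a point or two at this scale;
`ci_method = "satterthwaite"` is available when calibration matters more
than runtime.

# Limitations

* Gaussian responses and homoscedastic residuals only; no autocorrelated
  residual structures, generalized responses, or Bayesian estimation.
* Satterthwaite (not Kenward–Roger) small-sample correction.
* Parcel categories are consumed as input; deriving them from meta-analytic
  maps is out of scope. Recategorization is achieved by editing the label
  table and rerunning.
* Refitting a full published cohort is a long computation whose agreement
  with reported coefficients also depends on the original software's
  objective and convergence behaviour; `reproduce_published_fit()` exists
  for that purpose but is an external, full-scale check, not part of the
  test suite.
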