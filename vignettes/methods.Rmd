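---
title: "Separating genetic and environmental components of SES–brain associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating genetic and environmental components of SES-brain associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical machinery it
implements: the generative model behind the synthetic cohort, the
conventions each analysis stage adopts, why the genuinely open design
choices were resolved the way they were, and what a green test does and
does not establish.

## 1. The generative model

Everything downstream is exercised against a synthetic world whose
structure mirrors what the analyses assume about a population imaging
cohort.

**Latent factors.** Each subject carries a genetic value $G$ and an
environmental factor $E$, iid standard normal and independent of each
other. $G$ stands for the aggregate common-variant genetic propensity
relevant to SES; $E$ for everything environmental that covaries with SES.

**Polygenic indices.** A polygenic index built from a finite GWAS sample
is a noisy proxy of $G$. Two indices built from disjoint GWAS subsamples
share the signal but not the noise:
$$\mathrm{PGI}_k = \sqrt{r}\,G + \sqrt{1-r}\,\varepsilon_k,\qquad k=1,2,$$
with $\varepsilon_1 \perp \varepsilon_2$ and $r \in (0,1]$ the
reliability. Consequences used throughout: $\mathrm{cor}(\mathrm{PGI}_1,
\mathrm{PGI}_2) = r$ (so the split-sample correlation estimates the
reliability) and the regression of either index on $G$ has slope
$\sqrt{r}$.

**SES indicators.** Each indicator has loadings $(\ell_G, \ell_E)$ and a
unit-variance latent index $\ell_G G + \ell_E E + \sqrt{1-\ell_G^2-
\ell_E^2}\,\nu$. Numeric indicators are that index; categorical indicators
cut it at equiprobable normal quantiles, preserving a known latent
correlation structure for the component-recovery tests. The default
battery (four numeric, two categorical with 3 and 4 levels) uses strongly
*differentiated* loadings — each indicator predominantly genetic
(e.g. 0.97/0.05) or predominantly environmental (0.05/0.97), in mirrored
pairs. Two reasons:

- *Substantive*: the field's SES batteries mix highly heritable
  indicators (education, occupational class) with weakly heritable ones
  (neighborhood quality), and the second SES component is exactly the
  dimension on which they disagree.
- *Statistical*: the attribution stage's truth-recovery property assumes
  the two-component summary spans the latent $(G,E)$ plane with high
  fidelity. With diffuse loadings the second dimension's eigenvalue sinks
  into the multiple-correspondence noise dimensions contributed by the
  categorical indicators (capture of $G$ and $E$ drops to ~0.4), and
  controlling a genetic proxy then *cleans* the components of their
  $G$-noise — a suppression effect that biases percent attributions by
  tens of points (a zero-share region can show −48%). The default battery
  yields capture ≈ 0.93–0.94 for both factors and mirrored loadings keep
  the capture symmetric, which is what makes "percent reduction ≈ genetic
  share" a theorem-in-the-limit rather than an accident. This residual
  imperfect capture still leaves a small upward bias (a few points,
  e.g. the BMI attribution at mediation share 0.6 sits near 63–65%); the
  tests average replicates and state their tolerances accordingly.

**BMI as a partial mediator.** With mediation share $m$,
$$\mathrm{BMI} = -\sqrt{m}\,E + \sqrt{1-m}\,u,$$
(low SES environment, higher BMI). The environmental path decomposes
*exactly* as
$$E = (1-m)\,E + \sqrt{m}\,(-\mathrm{BMI}) + \sqrt{m(1-m)}\,u,$$
i.e. the generator routes the fraction $m$ of the environmental effect
through BMI by construction; the identity is asserted verbatim in the
tests. In the weak-signal limit (voxel effects of a fraction of a percent,
as in population cohorts) controlling BMI removes the share $m$ of the
environmental association.

**Voxel volumes.** The mask is the full grid, partitioned into
`n_regions` axis-aligned blocks (deterministic and trivially contiguous).
A voxel in region $j$ with genetic share $s_j$ and coefficient $\beta_j$
gets
$$y = \beta_j\left(\sqrt{s_j}\,G + \sqrt{1-s_j}\,E\right) +
      \lambda_{\mathrm{TIV}}\,\widetilde{\mathrm{TIV}} + \sigma Z,$$
where $Z$ is Gaussian-kernel-smoothed white noise on a torus, renormalized
to unit marginal variance. The circulant construction gives the noise a
closed-form axis-lag correlation (the kernel's discrete autocorrelation,
$\approx e^{-h^2/4L^2}$ at length scale $L$), which the variogram tests
check exactly. The default $L = 2$ voxels is a free parameter of the
stated world, not a claim about empirical GMV residuals — no published
value exists for that quantity. Defaults: $\beta$ chosen so single-voxel
partial R² sits near 1% (the order reported for SES–GMV effects),
$\lambda_{\mathrm{TIV}} = 0.4$ so that TIV adjustment visibly halves SES
effect sizes, and TIV itself loads 0.09 on each factor so its SES partial
R² is ≈ 1.6%.

All randomness flows from one integer seed; the generator saves and
restores the global RNG state so cohorts and volumes are bit-reproducible
and callers' random streams are untouched.

## 2. SES components (FAMD)

Numeric columns are standardized with population variance; each
categorical level becomes an indicator column centered and scaled by
$1/\sqrt{p_\ell}$ ($p_\ell$ the level proportion); the combined matrix
$Z/\sqrt{n}$ is decomposed by SVD. Total inertia equals (number of numeric
variables) + (levels − number of categorical variables), an identity the
tests assert exactly. Per-variable squared loadings are the summed squared
coordinates of the variable's columns — squared correlation for numeric
variables, correlation ratio for categorical ones — and sum to the
eigenvalue per component.

Conventions:

- **Sign**: each component is flipped to correlate nonnegatively with the
  first numeric variable (ties fall through to the next variable). The
  original study fixes signs implicitly through group means that are out
  of reach here, so a deterministic rule is adopted.
- **Scale**: components enter all regressions standardized to unit
  variance; the reported standardized coefficients imply that convention.
- **Missing data are rejected**, matching the complete-case design of the
  motivating study; unseen categorical levels at transform time are an
  error, not an imputation.
- `k = 2` components by default.
- The pairwise indicator association matrix (absolute correlation /
  correlation ratio / Cramér's V) is a descriptive extra and feeds nothing.

## 3. Voxelwise regression and permutation FWE

Per voxel, OLS of GMV on the predictors-of-interest plus covariates.
The joint test drops all predictors-of-interest from the model:
$F = \frac{(SSE_r - SSE_f)/q}{SSE_f/(n-p)}$, partial
$R^2 = (SSE_r - SSE_f)/SSE_r$. Standardized coefficients z-score the
outcome and the predictors-of-interest only; covariates stay in native
units (the F map is invariant to covariate rescaling, which is tested).
Voxels whose outcome sits numerically in the covariate span report zero
association rather than 0/0 noise.

**Permutation scheme.** The original study says only "permutation
testing"; Freedman–Lane is the standard choice for covariate-adjusted
mass-univariate inference and is what is implemented: residualize outcome
and predictors on the covariates, permute the residualized predictor rows
jointly, re-residualize, refit, and record the max-F over voxels. The
critical value is the $k$-th largest of the null max-F draws with
$k = \lfloor \alpha(B+1) \rfloor$, which controls FWER at level $\alpha$;
it is also reported on the uncorrected-p scale. Calibration is verified by
a 200-dataset global-null simulation whose rejection count must fall in
the central 95% region of Binomial(200, 0.05).

**Power.** The minimal detectable partial R² solves
power$(\lambda) = $ target for the noncentral F with
$\lambda = f^2 (n - p)$, $f^2 = R^2/(1-R^2)$, by bisection to 1e-8. The
$\lambda = f^2(n-p)$ convention (rather than $f^2 n$) is asserted by a
self-consistency test; at cohort scale the two differ below reporting
precision.

**Clusters** are 26-connected components of supra-threshold voxels
(connectivity is unstated in the original; 26-neighborhood is the common
volumetric choice), ordered by size then peak F, labeled by majority
region.

## 4. GIV regression

With classical measurement error, OLS of an outcome on
$\mathrm{PGI}_1$ shrinks the true-score effect by the reliability. Stage 1
regresses $\mathrm{PGI}_1$ on $\mathrm{PGI}_2$ and the covariates; stage 2
regresses the outcome on the fitted values and covariates. The stage-2
coefficient is consistent for the effect of the index's signal component.
Standard errors use the standard 2SLS form: residuals recomputed with the
*original* regressor, homoskedastic plug-in (whether the original study's
GIV standard errors carry a generated-regressor correction is unstated;
this choice is documented rather than asserted). First-stage F below 10
warns of a weak instrument (a convention; the study gives none). The
instrumenting direction follows the study ($\mathrm{PGI}_2$ instruments
$\mathrm{PGI}_1$); a symmetrized average is available but off by default.

## 5. Attribution decomposition

Three nested models per outcome: *before* (covariates + SES components),
*after-PGI* (adds the index), *after-PGI-BMI* (adds BMI). The association
metric is the joint partial R² of the two SES components in each model;
percent reductions are computed between consecutive models and reported
raw — sampling noise can push them outside [0, 100], and voxels with a
before-association under 1e-6 are flagged undefined and excluded from
averages (both behaviors deliberate). A coefficient-based per-component
change map comes from the Wald machinery, since the original figure's map
metric is not fully specified in the main text.

**How GIV enters the after-model.** The corrected "after" model is the
2SLS second stage: GMV on SES components + fitted PGI + covariates, with
the first stage regressing $\mathrm{PGI}_1$ on SES components +
$\mathrm{PGI}_2$ + covariates. Because the composite error of the
structural model is uncorrelated with the instruments, the second-stage
SES coefficients are consistent for the SES effect *conditional on the
true genetic value* — this is the variant that actually disattenuates the
decomposition. (Residualizing GMV on the stage-1 fit alone, the most
literal reading of "residualize on the instrumented component", removes
only the reliability fraction of the genetic path; the implemented variant
is one of the algebraically close alternatives anticipated in the design.)
In a fully genetic region at reliability 0.5, GIV-corrected attribution
approaches 100% while naive control stops near 50% — the acceptance suite
measures exactly that.

**Wald change test.** Both coefficient vectors are linear functionals of
the same outcome, $\hat\beta = A y$, so the change has variance
$\sigma^2 \lVert a_b - a_a \rVert^2$ with $\sigma^2$ from the after-model
(HC0 sandwich optional). The plug-in was validated against a fixed-design
Monte Carlo oracle (7% agreement). A pairs bootstrap is *not* an equality
oracle here: the coefficient change is a near-degenerate contrast whose
pairs-bootstrap variance includes variation over the regressor covariances
(e.g. the sample PC–PGI correlation), which conditional regression
inference deliberately excludes; the tests keep the bootstrap only as a
bounded sanity check.

**Averaging convention.** Map-level summaries average defined voxels
within the before-model significant set, unweighted. Cluster-level shares
rerun the three-model decomposition on the per-subject mean GMV of the
cluster's voxels; the three parts sum to the before-association
identically.

## 6. Brain-to-SES prediction

Stacked block ridge with full cross-fitting: within each of five outer
training folds, each block (parcel) gets ridge fits along a 13-point
log-spaced penalty grid $10^{-3}\ldots10^3$ (closed-form SVD solves —
exact, and the grid means what it says), the penalty chosen by an inner
five-fold CV whose held-out predictions double as the cross-fitted inputs
to the stacker; the stacker is nonnegative least squares (guarding against
block-level sign flipping) with a free intercept. Outer-fold predictions
are fully out of sample, which a permutation (leakage) audit verifies.
ΔR² is the increment in R² over the covariate-only model on the held-out
predictions; its CI is a percentile bootstrap over subjects (the original
CI method is unstated). The reference's exact stacking variant is not
reproduced in the available text; this is a documented divergence.

## 7. Functional annotation

The significant set is the voxels with uncorrected p below 1% in the VBM
map. Per concept map: difference in mean value between that set and the
rest, and a Welch two-sample t ("pseudo-T" — the original names but does
not define it; validity rests on the permutation null, not the t
reference). The null permutes the *F map*: surrogates are fresh Gaussian
fields at a calibrated smoothing scale whose values are replaced by the
original F multiset in rank order, so each surrogate holds exactly the
original values, spatially rearranged with matched autocorrelation; the
significant set is re-derived per surrogate at the same quantile (same set
size), preserving the two-group structure. $p = (1 + \#\{T^\ast \ge
T\})/(B+1)$, never below $1/(B+1)$; FDR flags are Benjamini–Hochberg;
categories are ordered by the mean of their top-five concept scores.

**Calibration details.** The smoothing scale is found by bisection (≤ 50
iterations) on the mean signed relative error between the surrogate and
source variograms over integer circular axis lags — every lag decreases
monotonically in the scale, so the signed mean has a unique root, whereas
a short-lag-only objective does not (rank remapping leaves a small lag-1
roughness floor). Distances respect the periodic boundary of the fields.
Known limitation: the lag-1 semivariance of a smooth map is a small,
high-relative-variance quantity, so per-surrogate-ensemble agreement at
lag 1 is ~±30–40% even when lags 2+ match within 15%; signal-bearing F
maps may also end calibration above tolerance, in which case the sampler
returns its best scale with a warning. This sampler is a documented
stand-in for the published spatial-autocorrelation-preserving permutation
method, not a reimplementation of it.

## 8. Synthetic world vs. real data

What a green suite establishes: the machinery is algebraically correct
(oracle tests), statistically calibrated (FWE, enrichment, CI coverage),
and recovers planted truth (reliability, attenuation, genetic shares,
mediation share, prediction signal) in a world that satisfies its
assumptions. What it does not establish: any of the motivating study's
empirical magnitudes — those are bound to restricted cohort data. The
generator also simplifies reality in ways worth keeping in mind: linear,
homoskedastic effects; a single environmental factor; mediation without
confounding of the BMI–GMV link; stationary isotropic noise on a full
rectangular mask; no site or motion artifacts beyond labeled covariates;
and polygenic indices produced directly at a stated reliability rather
than from simulated genotypes. The one analytic quantity that *is*
comparable to the motivating study — the minimal detectable partial R² of
the 23,931-subject design (0.17% at 90% power) — is recomputed by
`scripts/acceptance.R`.

## 9. Numerical and engineering choices

- Degenerate voxels (outcome in the covariate span) report zero
  association; degenerate targets and constant instruments are rejected.
- Percent-reduction denominators under 1e-6 are flagged, not clipped.
- Bisection tolerances: 1e-10 on detectable R² (reported to 1e-8 better),
  15% relative on variogram calibration.
- All permutation and bootstrap machinery takes explicit seeds; same seed,
  same config means bit-identical outputs (tested end to end through the
  pipeline manifest checksums).
- NIfTI-1 I/O is a minimal built-in implementation (no R NIfTI package in
  the dependency budget): single-file .nii/.nii.gz, common dtypes, srow
  affine; cross-validated against an independent Python implementation in
  the tests.
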