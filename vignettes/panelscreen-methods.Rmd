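---
title: "Methods: screening strain panels for diet-by-genotype effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening strain panels for diet-by-genotype effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscreen)
```

# The study design this package serves

A strain-panel intervention study crosses a panel of reproducible inbred
strains with sex and a dietary treatment (ad libitum feeding, AL, versus
intermittent fasting, IF, started in adulthood), then follows every animal
to natural death with repeated phenotyping. Because each strain is a fixed
genotype with replicates, strain-level variance components are directly
estimable: heritability of lifespan, and — the screen at the heart of the
package — *genotype-by-treatment* (GxT) variance, the degree to which the
diet effect differs across genetic backgrounds.

# Models

## Heritability

Broad-sense heritability uses the random-intercept model
$y_{ij} = X_{ij}\beta + u_j + \varepsilon_{ij}$ with
$u_j \sim N(0, \sigma^2_u)$ per strain and fixed sex, diet and sex-by-diet
covariates; $H^2 = \sigma^2_u/(\sigma^2_u + \sigma^2_\varepsilon)$.
Narrow-sense heritability replaces the iid strain effect with
$u \sim N(0, \sigma^2_g K)$, where $K$ is the strain-level additive
relatedness matrix, consumed as input and rescaled so its mean diagonal is
1 (which puts $\sigma^2_g$ on the residual-variance scale and makes a
global scaling of $K$ irrelevant). Individual replicates are always
modelled; collapsing to strain means biases heritability upward.

The kinship model is fitted by rotating the strain random-effect design:
with $K = LL^\top$, the design columns $Z$ are replaced by $ZL$ so that iid
machinery estimates $\sigma^2_g$. The factor $L$ comes from a symmetric
eigendecomposition with negative eigenvalues clipped at zero, so a merely
positive-semi-definite $K$ (e.g. after resampling strains with
replacement) still works.

The share of variance explained by the design covariates is reported as
$\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \sigma^2_u +
\sigma^2_\varepsilon)$ — a descriptive decomposition on the same footing
as the random shares, which sum to one with them.

Two confidence-interval methods are provided and neither is privileged:
**profile** intervals invert the REML profile of the heritability ratio at
the $\chi^2_1$ 0.95 cutoff (endpoints satisfy
$2\{\ell(\hat h) - \ell(h_{end})\} = 3.84$ by construction, verified in the
tests to 0.01); **bootstrap** intervals resample *strains* — the
exchangeable genetic unit — with replacement (default B = 500, percentile
interval). An estimate at the zero boundary yields a one-sided interval
flagged as such.

## The GxT screen

Each phenotype is rank-normal transformed
($\Phi^{-1}\{(r - 3/8)/(n + 1/4)\}$, Blom offset, average ranks for ties),
which makes every downstream fit invariant to monotone re-expressions of
the raw assay scale. The full model is

```
y ~ diet * sex * timepoint + bw6mo
    + (1 + diet | strain) + (1 | mouse_id) + (1 | batch)
```

with baseline (6-month) body weight as a covariate, a per-mouse intercept
for repeated measures, and collection-batch intercepts. The
`(1 + diet | strain)` block has an unstructured 2x2 covariance whose
diet-slope variance is the GxT parameter and whose correlation $\rho$
links strain baseline to strain diet response ($\rho < 0$: strains with
high baseline respond less, or more negatively).

* **Diet coding.** The random diet slope uses treatment coding with AL as
  reference, so the strain intercept is the strain's AL level and the
  slope is its IF minus AL response; $\rho$ must be read under that
  convention. (Sum coding would change $\rho$'s meaning, not the fit.)
* **GxT test.** A REML likelihood-ratio test against the `(1 | strain)`
  reduction drops two covariance parameters (slope variance and
  correlation), so the statistic is referred to $\chi^2_2$. This reference
  is conservative when the null sits on the variance boundary; a 50:50
  $\chi^2_{1}/\chi^2_{2}$ mixture option exists but is off by default.
  Calibration under the null (simulated slope SD of zero) is verified by
  simulation: the empirical rejection rate at $\alpha = 0.05$ stays at or
  below 6%.
* **Thin late timepoints.** Mortality can empty whole diet x sex cells at
  late visits, aliasing the three-way interaction; such timepoints are
  dropped with an explicit report rather than silently absorbed.
* **Contrasts.** Population-averaged diet effects, overall and within sex,
  are contrasts of model-based means on an equal-weight reference grid
  over the other factors, with Satterthwaite degrees of freedom.
  Benjamini–Hochberg FDR is applied across phenotypes, separately for the
  diet contrast and the GxT test.

## Strain diet-effect scores, clustering, model selection

For each phenotype and stratum the score of strain $j$ is
$\zeta_{EB,j} + \widehat{\Delta}_{stratum}$: the empirical-Bayes (BLUP)
strain diet slope plus the population IF−AL contrast in that stratum, so a
score reads directly as "this strain's expected diet response". The scaled
variant z-scores each strain's scores across phenotypes within a stratum
("scaled within strain"), matching the within-strain normalization used
for heat-map display; an across-strain variant is a flag away. Rows and
columns are clustered by Ward linkage on Euclidean distance with k = 3
clusters by default (a configurable knob, since no selection criterion is
prescribed); the row order of a designated reference stratum (default: the
first) is reused across strata so panels stay comparable. Model strains
are the argmax and argmin of a phenotype's scores, with lexicographic
tie-breaking.

## Survival analysis

Kaplan–Meier estimation, lifespan quantiles (median; 90th percentile as
the "maximum lifespan" summary; undefined quantiles are returned missing,
never extrapolated), overall and pairwise log-rank tests with BH
adjustment, and Cox regression of diet, sex and their interaction with
strain as a stratification term. Ties use the Efron approximation
(Breslow by flag); the two coincide without ties. The cage sensitivity
analysis uses a cluster-robust sandwich variance by housing cage rather
than a mixed-hazard (frailty) model — the point estimates are untouched
and only the variance is corrected, which is the transparent option when
the frailty distribution is unknown.

Restricted mean survival time (RMST) is the area under the KM curve to a
truncation age $\tau$ (default: the smaller of the groups' largest
observed times, recorded in the result); its variance is the Greenwood-type
sum $\sum_{t_i \le \tau} A_i^2 d_i / \{Y_i(Y_i - d_i)\}$ with $A_i$ the
remaining area after $t_i$, and differences get a normal CI and z-test.
Lifespan variability is compared as per-cell coefficients of variation
(SD/mean) with an exact Wilcoxon signed-rank test on paired per-strain
differences; zero differences are dropped per the signed-rank convention
and an all-zero comparison gives p = 1.

## Trajectories

Weekly body weight is smoothed per mouse by local quadratic regression
with tricube weights over the nearest third of the data (neighbourhoods
are floored at degree + 2 points so short series stay solvable; series
under 5 points pass through flagged). Summaries are mean mass (MM, grams)
and +AUC, the trapezoidal integral over the observed age range with
baseline zero, in gram·weeks — age is kept in weeks, the sampling unit,
and that choice is recorded in the output. A positive-part variant (area
above the first observation) sits behind a flag because "total AUC" is
the primary reading.

Ages are rescaled to proportion of life lived (PLL = age/lifespan), with
20 equidistant PLL bins for population summaries (bin i is
$[(i-1)/20, i/20)$, the last bin closed). The frailty index is the mean of
the non-missing ordinal items (0 / 0.5 / 1) at a visit — the standard
deficit-index convention for missing items; per-mouse FI slopes are OLS on
PLL and the final FI is the last assessment before death. Deficit
incidence binarizes items as severe (exactly 1; 0.5 is non-severe): a
mouse is affected if any visit scored severe, and the IF−AL incidence
difference is reported per strain.

## Temperature and the late-life inflection

Body temperature is modelled with a penalized-spline additive mixed model:
parametric sex and strain (strain deliberately fixed so its terms can be
tested), optional diet, cubic B-spline smooths with second-difference
penalties (basis dimension 10, reduced with a warning when the data cannot
support it) for PLL and baseline body weight, REML smoothing-parameter
selection, and a per-mouse random intercept. Approximate smooth-term
F-tests carry the usual caveat (they ignore smoothing-parameter
uncertainty); inference leans on the nested comparison instead.

The nested diet comparison is an analysis of deviance on the
maximum-likelihood scale: each fit carries an ML companion score
(smooth and random coefficients integrated out, parametric terms
maximized) and twice the score difference is referred to $\chi^2$ with df
equal to the added parametric coefficients. The residual sum of squares
alone is *not* used, because the per-mouse intercepts absorb between-mouse
terms such as diet almost completely — a comparison on RSS has essentially
no power against them — and REML scores are not comparable across
parametric structures.

The late-life inflection is located by a continuous broken-stick fit:
candidate knots on a 0.01 grid in [0.50, 0.95], least squares for the two
connected segments at each knot, and the RSS-minimizing knot reported with
its segment slopes. If the best broken stick does not beat a single line
at the 0.05 F-test level, the result is "no inflection" rather than an
arbitrary knot. A spline-curvature alternative was considered and set
aside: the broken stick is directly testable against an exhaustive grid
oracle and robust at moderate sample sizes.

## Longevity biomarkers

For each trait x timepoint with at least 20 complete observations,
rank-normalized lifespan is regressed on the rank-normalized trait with
diet, sex and rank-normalized baseline body weight fixed and strain and
batch as random intercepts; the trait coefficient is therefore a
standardized beta. Its p-value is the F test with Satterthwaite
denominator degrees of freedom; when the mixed fit is inestimable the
screen falls back to the fixed-effects regression and says so in the
output. Weekly body weight enters as the MM and +AUC traits rather than
per timepoint. One pooled BH pass covers all trait x timepoint tests.
Mice must be alive to be measured, so each timepoint's sample is
survival-conditioned by construction; the screen documents rather than
corrects this conditioning.

# The synthetic-cohort generator

`sim_config()` defaults encode the study conditions: 10 strains x 2 sexes
x 2 diets x 20 mice (800 animals), lifespans in months from a Gaussian
mixed model with mean 23, strain SD 2.87 and residual SD 4.97 — a strain
variance fraction of 0.25 and a coefficient of variation near 0.25 — plus
fixed effects (male +2 months; diet +0.3; male x diet +1.4, concentrating
a ~1.7-month benefit in fasting males). A Gompertz mode with strain
log-hazard frailty is available for survival realism; the Gaussian mode is
the default because it matches the heritability analysis model and makes
parameter recovery checkable. Censoring defaults to zero (euthanasia for
moribundity is recorded as death); when requested it is administrative,
uniform over the last 40% of a mouse's life.

Phenotypes get strain intercept SD 1, strain diet-slope SD 0.5,
intercept–slope correlation −0.4, residual SD 1 and batch SD 0.3. The
paper-scale studies report only p-values for these effects, so the effect
sizes are the package's own choices, set to be recoverable at the default
design size — they are testability parameters, not empirical claims.
Body weight follows a piecewise rise–plateau–terminal-drop template
(peak at 40% PLL, decline to 90% of peak by 90% PLL, then a terminal
drop); temperature declines at −0.5 °C per unit PLL with a knee at PLL
0.8 adding −4 °C per unit; frailty items share a latent deficit process
linear in PLL, cut at fixed thresholds into 0 / 0.5 / 1 with item-specific
loadings. Cages hold 4 mice within strain x sex x diet, exercising the
cage sensitivity analysis. All randomness flows from the single config
seed; phenotype rows exist only while the mouse is alive.

What the generator does **not** emulate: realistic physiology (hematology
reference ranges, immune gating structure), founder-haplotype genetics
(the kinship matrix is a synthetic PSD surrogate with unit mean diagonal),
assay dropout other than death, and non-Gaussian measurement error.
Passing tests therefore demonstrate statistical correctness of the
estimators under the assumed covariance structure, not robustness to every
feature of real colony data.

# Numerical choices

* **REML fitting** delegates to `lme4`/`lmerTest` behind the package's
  interface. After the derivative-free optimizer converges, covariance
  parameters are polished by a few Newton steps on the REML deviance with
  finite-difference derivatives (step 4e-5), which tightens agreement with
  closed forms (balanced one-way components, BLUP shrinkage) to ~1e-8;
  the polish doubles as a convergence check, and the noisy gradient/Hessian
  heuristics of the underlying stack are silenced in its favour. A second
  optimizer start is attempted on reported non-convergence. Boundary
  (singular) fits are accepted as legitimate screen outcomes.
* **Rank-deficient fixed designs** raise an error naming the aliased
  columns; the GxT screen pre-empts the known mortality-driven case by
  dropping unsupported timepoints with a report.
* **Missing data** are handled by listwise deletion per model with the
  dropped count recorded on the fit.
* **Determinism.** Ward/Euclidean clustering, the knot grid search and all
  table outputs are deterministic; the only randomness is the config seed
  and explicit bootstrap seeds, and the end-to-end pipeline is verified to
  be byte-identical across runs.

# Validation problem sizes

The test suite checks REML log-likelihoods against a dense-covariance
oracle on 50 random toys (n <= 200), heritability recovery on 50 simulated
cohorts of 10 strains x 80 mice at a true fraction of 0.25, null
calibration of the GxT variance test on 200 single-visit cohorts with 100
further replicates at each planted slope SD (0.5 and 1.0), rho and BLUP
recovery on 100 seeded replicates, and inflection recovery on 20
replicates of 400 points — sizes chosen so each property is measured with
useful precision while the whole suite stays quick to run on one core.

# Known limitations

* The Satterthwaite machinery applies to the iid-random-term fits; the
  kinship-rotated fit reports BLUPs and variance components but not
  Satterthwaite contrasts (heritability inference uses profiles or the
  strain bootstrap instead).
* The conditional SDs of kinship-scale BLUPs treat the rotated levels'
  conditional variances as independent — an approximation adequate for
  ranking, not for joint inference.
* The GxT variance LRT's naive $\chi^2_2$ reference is conservative at
  the boundary; power comparisons across phenotypes are therefore
  descriptive (variance components are reported, no cross-phenotype
  variance-ranking test is attempted).
* Cure-type censoring, competing risks, interval censoring and joint
  longitudinal–survival models are out of scope.
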