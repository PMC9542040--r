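---
title: "Methods: phylogenetic multilevel modelling of hypoxia tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic multilevel modelling of hypoxia tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Critical oxygen tension (Pcrit) — the lowest ambient oxygen partial
pressure at which a fish still sustains its standard metabolic rate — is a
widely used index of hypoxia tolerance. Comparative Pcrit data are messy in
two distinctive ways: measurements reach the literature in five different
unit systems (kPa, mmHg, percent air saturation, mg/L, µmol/L), and species
sharing evolutionary history cannot be treated as independent observations.
phylocrit handles both: it standardizes heterogeneous respirometry records
through explicit oxygen physics, and it models the standardized data with a
Bayesian multilevel model whose random-effect covariance comes from a
phylogeny.

## The model

For record $i$ of species $s(i)$,

$$y_i = \mathbf{x}_i^\top \boldsymbol\beta + a_{s(i)} + u_{s(i)} + \varepsilon_i,$$

with $y_i$ the Pcrit in kPa (untransformed — the intercept is then directly
interpretable on the kPa scale),
$\mathbf{a} \sim \mathrm{MVN}(0, \sigma^2_{\mathrm{phylo}}\,\mathbf{C})$ a
phylogenetically structured species intercept,
$\mathbf{u} \sim \mathrm{MVN}(0, \sigma^2_{\mathrm{species}}\,\mathbf{I})$
an unstructured species intercept capturing species-specific ecology not
explained by phylogeny, and iid Gaussian residuals. The fixed effects of
the final model are measurement temperature $T$, log10 genome size (a cell
size proxy), log10 body mass, salinity, residual metabolic rate, and the
two interactions $T \times$ genome size and $T \times$ body mass; the
candidate set additionally covers relative acclimation temperature,
respirometry method, percent-of-maximum body mass (with quadratic and
temperature-interaction variants) and a maximum-body-mass substitution for
genome size.

Priors are weakly informative on the natural covariate scales:
$\beta_k \sim \mathrm{N}(0, 10^2)$ and half-Normal(0, 5) on each of the
three standard deviations. Both scales are configurable in `model_spec()`.
Covariates are deliberately *not* centered or scaled, so coefficients stay
on the scale a reader of the standardized table expects.

### The phylogenetic correlation matrix

Branch lengths are rarely trustworthy in large supertrees, so the tree is
given Grafen heights: each node sits at (number of descendant tips − 1),
normalized so tips are at 0 and the root at 1. Heights are then raised to
the power $\rho$ (default 0.4); for $\rho < 1$ every internal height in
(0, 1) increases, which stretches branches near the tips and up-weights
recent divergence. Because normalization and the power transform commute
($\,(h/H)^\rho = h^\rho/H^\rho$), the order of the two steps is immaterial
— a point sometimes left ambiguous in descriptions of the transform. The
correlation of two tips is the shared root-to-MRCA path length,
$1 - h^\rho(\mathrm{mrca})$, giving a unit-diagonal PSD matrix;
the unit diagonal makes $\sigma^2_{\mathrm{phylo}}$ directly the
phylogenetic variance, which the variance partition relies on (and asserts
at run time). `rho_profile()` offers a grid search over $\rho$ scored by
PSIS-LOO for users who want to re-derive the default from their own data.

### Oxygen physics

Unit standardization needs two physical ingredients, and since web-based
converters are not reproducible dependencies, both are implemented from
standard formulas and exposed directly:

* **Saturation vapour pressure** — Buck's (1981) equation, accurate to
  < 0.05% over 0–45 °C. Air above water is vapour-saturated, so percent
  air saturation converts as
  $p\mathrm{O}_2 = (\mathrm{pct}/100) \times 0.2095 \times (P - p_v(T))$.
* **Oxygen solubility** — the Garcia & Gordon (1992) combined refit of the
  Benson & Krause data, the de-facto standard in oceanography and
  respirometry. Concentration units convert by Henry-law proportionality
  through the saturation concentration. The fit is per kilogram of water;
  per litre differs by water density (< 3% even at 35 PSU), well below the
  precision of literature Pcrit values, so the two are treated
  interchangeably. Swapping in another solubility formula only requires
  replacing `o2_saturation_concentration()`.

Atmospheric pressure defaults to 101.325 kPa (760 mmHg) and is an argument
everywhere it enters.

### Residual metabolic rate

Whole-organism metabolic rate is strongly determined by body mass,
temperature and salinity. The `resid_mr` covariate is the residual of the
record-level OLS fit `log10(MR) ~ salinity + temp + log10(mass)`; positive
values mean an individual respires more than expected for its size and
water. Records without a measured rate get residual 0 — the baseline
expectation — with an `mr_imputed` flag carried through so a sensitivity
refit excluding them is a one-line filter. The fit is record-level rather
than species-mean (each measurement has its own covariates); a species-mean
analysis can be run by aggregating before `fit_mr_baseline()`.

## Computation

The Gaussian likelihood makes most of the model conditionally conjugate,
so posterior sampling uses a blocked Gibbs scheme authored in the package:

* $(\boldsymbol\beta, \mathbf{w})$, with $\mathbf{w} = \mathbf{a} +
  \mathbf{u}$ the combined species effect, is one joint Gaussian block.
  Sampling them together (rather than in two conditional blocks) removes
  the strong intercept–random-effect autocorrelation and brings the fixed
  effects close to iid sampling efficiency.
* The three scales are updated by univariate slice sampling on the log
  scale. Working in the eigenbasis of $\mathbf{C}$ turns each evaluation
  of the $(\sigma_{\mathrm{phylo}}, \sigma_{\mathrm{species}})$
  conditional into an $O(S)$ operation; the eigendecomposition is computed
  once per fit, with eigenvalues clipped at $10^{-12}$ for numerical
  safety (the matrix is PSD by construction and checked).
* The split of $\mathbf{w}$ into $\mathbf{a}$ and $\mathbf{u}$ is
  marginalized during sampling and reconstructed as a conditional mean
  only where needed (the shared-variance diagnostic), which improves
  mixing of the two species-level scales.

Convergence is reported per parameter as classic split-$\hat R$ and an
FFT-based effective sample size with Geyer's initial monotone sequence;
any split-$\hat R > 1.01$ flags the fit (returned with a warning, never
silently discarded). Defaults are 3 chains × 15,000 iterations with half
warmup; model screening uses 2 × 4,000 with 1,000 warmup, and the winner
is meant to be refit at full settings.

The marginal likelihood (random effects integrated out) is computed via
the Woodbury identity on species-level $S \times S$ matrices,
an $O(S^3)$ path that the test suite checks to $10^{-8}$ against a dense
$n \times n$ brute-force evaluation.

### Model comparison

PSIS-LOO is computed from the per-record conditional log-likelihood draws:
importance ratios $1/p(y_i \mid \theta_s)$, generalized-Pareto smoothing of
the largest $\min(0.2S, 3\sqrt S)$ ratios (Zhang–Stephens estimator with
the standard weak-prior shape regularization), truncation at the largest
raw ratio, and a per-record shape diagnostic $\hat k$ with a logged warning
above 0.7. Model weights are pseudo-BMA,
$w_m \propto \exp(\mathrm{elpd}_m - \max_m \mathrm{elpd})$ — the simplest
scheme that assigns each candidate a probability within the set.
Leave-one-record-out is the only cross-validation scheme offered.

Predictor screening uses p(MAP): the kernel-density ratio of the posterior
at zero to the posterior at its mode, reported per fixed effect in
`summarize()`.

### Variance partition and heritability

Per posterior draw, the marginal (fixed-effect) variance is the
finite-sample variance of $\mathbf{X}\boldsymbol\beta$ over the records;
the phylogenetic, species and residual variances are the squared scale
draws. The four fractions sum to one by construction. Phylogenetic
heritability is
$\lambda = \sigma^2_{\mathrm{phylo}} / (\sigma^2_{\mathrm{phylo}} +
\sigma^2_{\mathrm{species}} + \sigma^2_{\mathrm{resid}})$ — the share of
the non-fixed-effect variance attributable to phylogeny. Means are
reported with medians alongside, since the two differ for the skewed
fraction posteriors. A supplementary diagnostic (optional) reports how
much of the fixed-effect signal is itself phylogenetically structured: the
squared correlation, per draw, between $\mathbf{X}\boldsymbol\beta$ and
the conditional-mean phylogenetic effect.

### Aerobic-scope projection

`project_fas_grid()` evaluates the posterior-*mean* fixed effects (random
effects at zero, residual metabolism at zero) on a user-supplied
temperature grid for a hypothetical fish, then maps predicted Pcrit
through FAS = 21/Pcrit with the 2 kPa floor (capping FAS at 10.5). Using
posterior means rather than full posterior-predictive draws is a
documented choice — the projection is a fixed-effect surface, not a
predictive distribution; the floor guards the ratio where the Gaussian
fixed-effect surface predicts very low (even negative) Pcrit, e.g. large
cold-water fish. The 21 kPa numerator is the nominal atmospheric
$p\mathrm{O}_2$, deliberately not humidity-corrected, to match the
standard printed form of the conversion. Grid temperatures outside the
fitted range are flagged as extrapolation. No GIS layer handling is
included: the grid is a plain vector/CSV of cell temperatures.

## The synthetic generator

`synthetic_truth()` + `simulate_dataset()` generate data from exactly the
model above, so every stage of the pipeline can be verified by parameter
recovery without any external download. Defaults place the synthetic world
at the fitted world's published operating point: the final-model
coefficient means, $\sigma_{\mathrm{phylo}} = 2.22$,
$\sigma_{\mathrm{species}} = 1.02$, and $\sigma_{\mathrm{resid}} = 1.67$
(the residual scale is a derived default, chosen so $\lambda \approx
0.56$). Covariate distributions are *emulation, not reproduction* — the
real covariate joint distribution is unpublished — and are config-exposed:

* temperature uniform on 5–32 °C (consistent with reported 25th/75th
  percentiles of 15 and 28 °C);
* species-level log10 body mass N(0.8, 0.7) with within-species spread
  N(0, 0.25) and a 0.6-decade margin to the species maximum;
* log10 genome size N(0, 0.25) pg;
* half the species marine (salinity drawn from 30–36 PSU), half
  freshwater (0);
* species-level residual metabolism N(0, 0.15), record-level log10 MR
  noise 0.09 — the pair that puts the baseline regression's R² near the
  observed ~0.94 under these covariate spreads;
* 20% of records lack a metabolic rate; 80% are acclimated at their
  measurement temperature.

Pcrit values the Gaussian model generates below 0.1 kPa (about 1% of
records in the default regime) are clamped, with the count reported in the
truth object. What the generator does **not** emulate: measurement error
in Pcrit estimation from raw oxygen traces, unit heterogeneity (it emits
kPa), taxonomic misspellings, and non-uniform literature sampling of
species. Passing recovery tests therefore demonstrates correctness of the
inference machinery under the model, not robustness to those real-data
pathologies.

## Problem sizes used by the tests

The test suite runs entirely on synthetic data at sizes chosen to give
each check real statistical power at desk scale: interval coverage over 20
replicate worlds of 60 species / 300 records; sign recovery of both
temperature interactions and variance-fraction recovery at the full study
size (170 species / 600 records, the latter averaged over three replicate
worlds because the phylogeny-vs-species split carries realization noise of
order ±0.1 at ~3.5 records per species); exact-refit LOO comparison at
n = 30; dense-matrix likelihood oracles at n ≤ 20; and 2,000 replicate
draws for the phylogenetic-correlation structure check. Screening-level
MCMC settings are used inside replicated experiments.

## Known limitations

* With few records per species, $\sigma_{\mathrm{phylo}}$ and
  $\sigma_{\mathrm{species}}$ are only weakly separable for a single
  realization; their sum (and the fixed effects) remain well identified.
  Interpret single-dataset $\lambda$ intervals, not point estimates.
* The Gaussian response admits negative predicted Pcrit in extreme
  covariate corners; the FAS floor handles projection, but users modelling
  near-zero Pcrit may prefer a transformed response, which the package
  does not currently offer.
* Solubility is per kg of water while concentration units are per litre;
  the ≤ 3% discrepancy is accepted and documented rather than corrected
  with an equation of state.
* The sampler is exact-conditional Gibbs + slice; it has no divergence
  diagnostics of the Hamiltonian kind, so convergence assessment rests on
  split-$\hat R$/ESS and the recovery suite.
* `resid_mr` is an estimated covariate. When it is re-estimated from
  noisy metabolic rates (rather than taken as known, as the recovery
  experiments do), its coefficient attenuates toward zero in the usual
  errors-in-variables way; the model treats the covariate as exact.
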