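---
title: "Synthetic DTI-ALPS: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic DTI-ALPS: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsim)
```

## The problem alpsim addresses

The DTI-ALPS method estimates glymphatic (perivascular) fluid mobility from
a ratio of directional diffusivities measured in a region lateral to the
body of the lateral ventricle, where three orthogonal structures coexist:
projection fibers running inferior–superior (z), association fibers running
anterior–posterior (y), and the medullary vessels — with their perivascular
spaces — running right–left (x). The index

$$\mathrm{ALPS} = \frac{\mathrm{mean}(\mathrm{projD}_{xx},\, \mathrm{assocD}_{xx})}
                       {\mathrm{mean}(\mathrm{projD}_{yy},\, \mathrm{assocD}_{zz})}$$

is designed so that the numerator follows the perivascular axis in both
fiber systems while the denominator follows directions perpendicular to
both the fibers and the vessels; under isotropic diffusion it equals 1.

A persistent criticism of the method is that commissural fibers of the
corpus callosum cross the analysis region, so the index may reflect white
matter microstructure rather than perivascular physiology. The
corpus-callosum *variant* indices probe this directly in regions where
fiber geometry is simple (all callosal fibers run along x) but vessel
orientation differs: `ccgALPS = ccgDyy/ccgDzz` in the genu,
`ccbALPS = ccbDzz/ccbDyy` in the body, `ccsALPS = ccsDyy/ccsDzz` in the
splenium — always vessel-axis diffusivity over the axis perpendicular to
both vessels and fibers.

Because the underlying clinical dataset (psychiatric patients with
obstructive sleep apnea, scanned at 4 PM and again at 9 AM around an
overnight polysomnography) is not public, alpsim rebuilds the entire
analysis as a *synthetic* study: voxel phantoms with the geometry above, a
calibrated tabular cohort, and the full statistical battery. Everything a
test asserts is therefore a property of the generative models, not of real
patients.

## The voxel phantom and signal model

`phantom_spec()` describes a 20×20×20-voxel grid (2 mm isotropic) carrying
seven cubic regions of 8 voxels each: left/right projection, left/right
association, and callosal genu, body and splenium. Region placement is
schematic — no template with published coordinates exists — and is
configurable. Each labelled voxel mixes two compartments:

* a **fiber** compartment, cylindrical tensor with axial/radial
  eigenvalues λ∥ = 1.7×10⁻³, λ⊥ = 0.3×10⁻³ mm²/s (typical coherent white
  matter), principal axis along the region's fiber direction, weight
  1 − f;
* a **perivascular** compartment, cylindrical tensor with λ∥ = 3.0×10⁻³
  (facilitated fluid movement, approaching free water) and
  λ⊥ = 0.3×10⁻³ mm²/s along the region's vessel direction, weight
  f = 0.1 by default.

The default f and perivascular eigenvalues were chosen once so that the
fitted variant indices land moderately above 1 — the qualitative regime the
method predicts (vessel-direction diffusivity elevated, but less than in
the ALPS region proper). The noiseless signal is the compartment mixture
`S = S0 Σ fᵢ exp(−b gᵀDᵢg)`; noise is Rician (magnitude of a
complex-Gaussian–perturbed signal) with σ = S0/SNR and SNR 20 by default,
the standard model and a typical magnitude-image SNR for 3 T EPI.

The gradient scheme is twelve electrostatically spread directions at
b = 1000 s/mm² plus two b = 0 volumes. The emulated protocol states only
"12 axes"; the shipped table is an optimisation stand-in, flagged as such
in the code, and validated for full design-matrix rank at construction.
The duplicate b = 0 volumes are averaged before fitting, mirroring the
protocol's two signal averages.

## Tensor fitting

`fit_tensor()` uses ordinary log-linear least squares on
`ln(S/S0) = −b gᵀDg`. The estimator is deterministic, exact for noiseless
single-compartment data (the property suite requires recovery to 1e-9
relative error), and the field-standard first pass; weighted or nonlinear
variants would matter at low SNR but would buy nothing for the questions
this package asks. Numerical guards: signals ≤ 0 (possible under magnitude
noise) are floored at 1e-6·S0 and the voxel flagged; negative eigenvalues
are clamped to zero *only* inside the FA formula, while raw axial
diffusivities Dxx/Dyy/Dzz are reported unclamped because they feed the
index ratios and clamping would bias them.

When the two-compartment mixture is fitted with a single tensor, the
vessel-axis apparent diffusivity is inflated — e.g. along an axis where the
fiber contributes λ⊥ and the perivascular compartment λ∥pvs, the
log-signal fit sees `−ln((1−f)e^{−bλ⊥} + f e^{−bλ∥pvs})/b ≈ 0.40×10⁻³`
rather than 0.3×10⁻³ at f = 0.1. This is exactly the mechanism by which
perivascular diffusivity elevates the indices, and the monotonicity
property (fitted Dzz/Dyy in the callosal body is non-decreasing in f) pins
it down.

## Regional metrics

`regional_means()` pools left and right ALPS regions of the same class
before averaging, so a single projection and a single association mean
enter the ratio. Whether the original analysis averaged hemispheres, used
one, or averaged two per-hemisphere indices is not stated; pooling before
the ratio is the simplest rule consistent with one reported index per scan
and can be changed by supplying per-hemisphere label maps.

Framewise displacement uses the Power convention — the sum of absolute
backward differences of the three translations plus 50 mm times the sum of
absolute rotation differences; the source names FD but not a formula, and
this is the dominant convention. Session differences are always
9 AM − 4 PM.

## The synthetic cohort

`generate_cohort()` draws a two-session table for 50 subjects via a
Gaussian copula. Per-variable marginals are normal, truncated at hard
bounds (volumes ≥ 0, sleep efficiency in [0, 100], SpO₂ ≤ 100, …); the ALPS
column has session-specific marginals 1.391 ± 0.261 (4 PM) and
1.419 ± 0.253 (9 AM). The planted correlation matrix carries the published
imaging-marker correlations (e.g. ALPS–rCPV −0.44, rCPV–rWMHV 0.547), the
reported ALPS–sleep correlations (REM latency −0.47, total sleep time
0.33, sleep efficiency 0.29) and the age correlations of the volumetric
ratios (0.61, 0.65); every unreported pair is 0, including ALPS–age and
FD–ALPS, which were reported as null. PSG marginal means and SDs are *not*
literature anchors — none were printed — only plausible clinical values for
a psychiatric OSA cohort, exposed in `cohort_config()`.

Three structural choices deserve explanation:

* **Session correlation 0.7.** Scan-level variables are built as
  `z_session = √ρ z_subject + √(1−ρ) z_innovation` with ρ = 0.7. Combined
  with the session marginals this yields
  SD(ΔALPS) = √(0.261² + 0.253² − 2·0.7·0.261·0.253) ≈ 0.199, the printed
  dispersion of the session difference — the main reason for the default.
* **Exact second-moment calibration.** When the cohort is larger than the
  variable count, the latent Gaussian blocks are drawn with their sample
  covariance constrained to equal the planted matrix
  (`MASS::mvrnorm(empirical = TRUE)`). The generator's purpose is to
  emulate *one specific printed cohort*, not the sampling distribution of
  such cohorts, and this removes latent-level Monte-Carlo noise from the
  calibration while the realised table stays stochastic through the
  truncation transforms, the session mixing and cross-block products.
  Small cohorts fall back to plain draws.
* **Nearest-positive-definite repair.** The planted matrix assembled from
  published pairwise values is very slightly indefinite (minimum eigenvalue
  ≈ −3×10⁻⁴); `Matrix::nearPD()` repairs it, and generation aborts if any
  planted entry would move by more than 0.05 (the observed maximum shift is
  below 1×10⁻⁴).

Diagnosis groups (bipolar 14, depression 14, schizophrenia 7, ADHD 6,
OCD 1, none 8) are assigned as mutually exclusive labels, with 9 subjects
CPAP-flagged; other cohort sizes scale these counts by largest remainder.
Absolute volumes are derived from the generated ratios (`cpv = rCPV·tiv`),
keeping the ratio identities exact by construction.

**Tabular vs voxel mode.** The tabular cohort is the statistical
calibration surface. `attach_imaging(mode = "voxel")` additionally realises
each scan as a phantom whose per-region perivascular fractions are obtained
by inverting the two-compartment attenuation for the tabulated index
targets; after simulation and fitting, the measured indices *track* the
targets but inherit fit approximation and noise, and sub-isotropic targets
clamp at f = 0 — which is why forcing exact covariance through voxels is
not attempted.

What the generator does **not** emulate: treatment (CPAP) effects, diurnal
physiology beyond the planted session shift, non-Gaussian tails or
zero-inflation in respiratory indices, spatial correlation between
neighbouring regions, and any registration or segmentation error. Passing
tests therefore certify the pipeline's arithmetic and calibration, not
clinical validity on real data.

## The statistical battery

* **Correlation panels** (`pearson_matrix_fdr()`): pairwise complete-case
  Pearson r with two-tailed p; Benjamini–Hochberg FDR within the panel (the
  declared family is one heatmap grid — the source reports per-analysis
  correction without defining the family, so the scope is an argument);
  strength categories very weak/weak/moderate/strong/very strong at
  |r| cut points 0.2/0.4/0.6/0.8. The FD–ALPS motion check is a single
  pre-specified test reported outside any family.
* **Standardized regression** (`standardized_ols()`): continuous variables
  z-scored, 0/1 dummies left intact, OLS, normal-approximation 95% CIs,
  VIF via `car::vif()`. Significance ⇔ CI excluding zero, matching the
  forest-plot convention.
* **Mediation** (`mediate()`): product-of-coefficients with linear models,
  `ACME = a·b`, `ADE = c′`, total from the reduced model — for nested OLS
  fits on the same cases `ACME + ADE = total` is an algebraic identity and
  is asserted to 1e-9. CIs are percentile bootstrap over case resamples
  (1000 draws by default); percentile was chosen because the source states
  only "nonparametric bootstrapping". Degenerate resamples are redrawn and
  counted; >10% is an error. The proportion mediated ACME/total is
  reported as undefined when the total is numerically near zero.
  `mediation_battery()` runs exactly the ten published X → M → Y paths in
  table order, age-adjusted, from one base seed. Effects default to raw
  units with a z-scored option: the published table labels its effects
  standardized yet prints magnitudes in the hundreds (consistent with raw
  diffusivities of order 10⁻³ entering a ratio outcome), so both surfaces
  are offered rather than chasing the printed magnitudes.
* **One-sample t tests** (`one_sample_t()`): variant indices against the
  isotropic reference 1.0; a 2000-draw null simulation in the property
  suite checks the nominal 5% type-I error.
* Two-sided tests and α = 0.05 throughout; complete-case handling per
  analysis.

Multi-predictor regressions enter predictors jointly by default
(`forest_data(joint = FALSE)` gives per-predictor models); the source is
ambiguous on this point.

## Pipeline and reproducibility

`run_pipeline()` chains the stages and writes the report bundle (cohort
CSV with a YAML sidecar recording seed and repair diagnostics, correlation
matrices, forest tables, the mediation table, t tests and a summary JSON).
One global seed fans out to fixed per-stage offsets so stages can be rerun
in isolation; two runs with the same configuration are byte-identical. Any
stage error aborts with the stage name. The battery requires at least 20
scans; miniature runs (used to exercise the voxel path quickly) emit
cohort, motion and descriptives only. `inst/scripts/alpsim` exposes the
verbs `simulate-phantom`, `simulate-cohort`, `fit`, `metrics` and
`run-all` as a thin shell front-end.

## Problem sizes and runtime choices

The shipped defaults — a 20³ grid with 8-voxel regions, 50-replicate noise
ensembles, 50-subject cohorts, 1000-draw bootstraps (reduced in unit tests
where only point estimates are asserted), 10⁵-replicate Monte-Carlo
oracles for the noisy-fit bias check — were chosen so the entire suite
runs in well under a minute per component on a single core while keeping
every Monte-Carlo tolerance (3 SE bands, binomial 99% bands) meaningful.

## Known limitations

* The single-tensor fit is the object of study, not a recommendation; no
  multi-tensor or free-water modelling is provided.
* Voxel mode reproduces planted covariance only approximately, and cannot
  represent sub-isotropic index targets (fraction floor at 0).
* The 12-direction table is a stand-in for an unpublished vendor scheme.
* Region placement is schematic; no spatial normalisation, registration or
  template ROI machinery exists, by design.
* PSG marginals are plausible, not published; analyses that depend on
  their absolute scale (rather than the planted correlations) should not
  be read against the literature.
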