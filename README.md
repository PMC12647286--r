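# alpsim — synthetic DTI-ALPS imaging and statistics

`alpsim` is an R package for studying the **DTI-ALPS index** — a
diffusion-MRI proxy for glymphatic (perivascular) fluid mobility — and its
corpus-callosum variants on fully synthetic data. It is aimed at
neuroimaging methodologists who want a controlled test bench for the ALPS
family of indices: known ground truth, configurable fiber/vessel geometry,
realistic noise, and the complete downstream statistical battery used in
clinical ALPS studies.

The package provides four layers:

1. **Voxel phantoms and DWI simulation** — two-compartment diffusion
   phantoms carrying the ALPS-ROI geometry (projection fibers along z,
   association fibers along y, perivascular axis along x) and the corpus
   callosum (fibers along x; vessels along y in genu/splenium, along z in
   the body); monoexponential mixture signals with Rician noise; rigid
   head-motion traces.
2. **Tensor fitting and maps** — log-linear least-squares single-tensor
   estimation, Dxx/Dyy/Dzz/MD/FA maps.
3. **Indices and metrics** — regional means, the ALPS index
   `mean(projDxx, assocDxx) / mean(projDyy, assocDzz)`, the variant
   indices `ccgALPS = ccgDyy/ccgDzz`, `ccbALPS = ccbDzz/ccbDyy`,
   `ccsALPS = ccsDyy/ccsDzz`, session differences (9 AM − 4 PM), and
   Power-convention framewise displacement.
4. **Cohort generator and statistics** — a Gaussian-copula two-session
   cohort (n = 50, psychiatric-OSA-like descriptives and a planted
   correlation structure), FDR-corrected Pearson correlation panels,
   standardized regression with VIF, bootstrap causal mediation
   (ACME/ADE/total effect, ten-model battery), one-sample t tests against
   the isotropic reference 1.0, and an end-to-end reproducible pipeline.

See the methods vignette (`vignettes/alps-methods.Rmd`) for the models,
calibration targets and design decisions.

## Worked example

Simulate a noisy phantom with a 10% perivascular compartment, fit tensors
and compute the indices:

```r
library(alpsim)

ph  <- build_phantom(phantom_spec())        # f = 0.1, 20^3 grid
dwi <- simulate_dwi(ph, snr = 20, seed = 1) # 12-direction b=1000 scheme
reg <- regional_means(tensor_maps(fit_tensor(dwi)))
alps_indices(reg)
#> ALPS indices (4PM): ALPS 1.396  ccgALPS 1.425  ccbALPS 1.863  ccsALPS 1.225
```

All four indices exceed 1: the perivascular compartment (fast diffusion
along the vessel axis) inflates the vessel-direction apparent diffusivity
even though every fiber tensor is radially symmetric. Noise at 8 voxels
per region makes a single replicate wobble (ccbALPS here); ensemble means
over 50 replicates settle near 1.42–1.48.

Generate the calibrated synthetic cohort and run the statistics:

```r
tab <- generate_cohort(cohort_config(n_subjects = 50, seed = 1))
tab
#> Synthetic scan table: 100 scans, 50 subjects, 58 columns, mode 'tabular'
#>   ALPS 4PM: mean 1.391 (SD 0.259)
#>   ALPS 9AM: mean 1.419 (SD 0.266)

standardized_ols(tab, "rCPV", c("alps", "ccgALPS", "ccbALPS", "ccsALPS"))
#> Standardized multiple regression: rCPV ~ alps + ccgALPS + ... (n = 100)
#>     term   beta    se ci_lower ci_upper        p   vif significant
#>     alps -0.362 0.077   -0.513   -0.212 8.52e-06 1.223        TRUE
#>  ccgALPS -0.306 0.074   -0.450   -0.161 7.49e-05 1.125        TRUE
#>  ccbALPS  0.123 0.071   -0.016    0.263 8.69e-02 1.052       FALSE
#>  ...

one_sample_t(tab$ccgALPS, 1)
#> One-sample t test vs 1: mean 1.06, t(99) = 7.211, p = 1.123e-10
```

The regression recovers the planted structure: the ALPS index and ccgALPS
carry significant negative associations with relative choroid plexus
volume after adjusting for age and diagnosis dummies (age itself is the
strongest factor), while ccbALPS/ccsALPS do not. Mediation models are
available per path (`mediate(tab, "assocDxx", "assocDyy", "alps")`) or as
the full ten-model battery (`mediation_battery(tab)`).

The whole analysis, with a report bundle of CSV tables and a summary JSON,
is one call (or `inst/scripts/alpsim run-all --seed 1 --out out/run` from
a shell):

```r
run_pipeline(pipeline_config(n_subjects = 50, seed = 1), out_dir = "out/run")
```

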