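Package: alpsim
Title: Simulation and Statistical Analysis of DTI-ALPS Glymphatic Imaging Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the diffusion tensor image analysis along the
    perivascular space (DTI-ALPS) index and its corpus-callosum variants with
    fully synthetic data. Builds two-compartment diffusion phantoms with the
    fiber and medullary-vessel geometry of the ALPS region of interest and the
    corpus callosum, simulates Rician-noise diffusion-weighted volumes and
    rigid head-motion traces, fits single diffusion tensors by log-linear
    least squares, and computes ALPS, ccgALPS, ccbALPS and ccsALPS indices
    together with framewise displacement. A Gaussian-copula cohort generator
    plants published descriptive statistics and correlation structure into a
    two-session synthetic cohort, and a statistics layer provides
    FDR-corrected Pearson correlation grids, standardized multiple regression
    with variance inflation factors, bootstrap causal mediation
    (ACME/ADE/total effect), and one-sample t tests against the isotropic
    reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    RNifti,
    car,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
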