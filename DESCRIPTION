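Package: alffr
Title: Static and Dynamic Amplitude of Low-Frequency Fluctuations for
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("alffr", "maintainers", email = "alffr@example.org", role = c("aut", "cre"))
Description: A tested pipeline for resting-state BOLD fMRI amplitude analysis:
    temporal preprocessing (volume discard, Gaussian smoothing, band-pass
    filtering, linear detrend), static ALFF and global-mean-normalized ALFF,
    sliding-window dynamic ALFF (across-window variance, z-scored), voxelwise
    covariate-adjusted group and paired contrasts, Gaussian-random-field
    cluster-level correction with residual-based smoothness estimation, and
    longitudinal delta-metric versus delta-clinical Pearson correlation with
    Bonferroni correction. Includes a synthetic BOLD cohort generator (planted
    band-limited oscillations, AR(1) noise, spatially smoothed fields, clinical
    covariates with planted delta-correlations) so every stage is testable
    without scan data, plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
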