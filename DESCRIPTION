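Package: dseqc
Title: DSE Variance Decomposition and DVARS Inference for fMRI Quality Control
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality-control diagnostics for 4D functional MRI time series based
    on a sum-of-squares decomposition of the data into fast (D-var), slow
    (S-var) and edge (E-var) components, of which the classical DVARS measure
    is the fast part (DVARS^2/4). Provides the DSE summary table with expected
    values under independent and time-space-separable noise models, a lag-1
    temporal autocorrelation heuristic, a chi-squared hypothesis test for
    DVARS spikes with robust (IQR / half-IQR, power-transformed) estimation of
    the null moments, standardized DVARS variants including the practical
    significance measure delta-percent-D-var, simulation generators for
    heteroscedastic Gaussian and AR(1) voxel noise with injected variance
    spikes, and bias / calibration / power experiment drivers. Reads and
    writes NIfTI-1 volumes and plain matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
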