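Package: acfmap
Title: Autocorrelation-Decay Complexity Mapping for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Voxel-wise complexity mapping of resting-state BOLD fMRI via the
    decay rate of the temporal autocorrelation function. Each voxel's
    autocorrelation function is modelled as an exponential decay
    ACF(t) = a*exp(-b*t); the decay rate b (and the mean lifetime
    tau = TR/b) index how chaotic or persistent the local dynamics are.
    The package implements the full analysis chain around this statistic:
    NIfTI input/output, nuisance conditioning (detrending, confound
    regression, zero-phase Butterworth band-pass filtering), voxel-wise
    group inference with cluster-extent thresholding, Lilliefors normality
    screening, leave-one-subject-out Gaussian-process classification with
    permutation testing, seed-to-voxel functional connectivity with
    clinical correlations, cost-thresholded graph metrics, and a synthetic
    phantom-cohort generator with known regional decay rates for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    signal,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    nortest,
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
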