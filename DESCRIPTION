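Package: vctkit
Title: Simulation and Analysis of Video Cone Tests for Insecticide-Treated Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for video cone tests (VCTs) of insecticide-treated bed
    nets. Provides an agent-based simulator of the WHO cone assay with four
    behavioural states (net contact, flight, resting, knockdown) and a
    grayscale video renderer; a per-pixel mixture-of-Gaussians movement
    detector that counts moving mosquitoes at 0.1-s intervals; activity
    aggregation into upper/lower cone regions and 5-s bins; scan-sampling
    behavioural-state summaries; bioassay endpoints (knockdown at 60 min,
    mortality at 24 h, Abbott control correction); a summary-statistic
    comparison workflow (Welch t tests, Cohen's d, confidence intervals,
    Levene's test, two-way ANOVA with estimated marginal means and Tukey
    contrasts); and chemical quality-control computations for HPLC
    insecticide quantification and Raman spectral preprocessing
    (Savitzky-Golay smoothing, asymmetric least squares baseline).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    Matrix,
    car,
    emmeans,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
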