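Package: meahazard
Title: Acute Neuronal Hazard Scoring from Multiwell Micro-Electrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Karel", "Devos", email = "kdevos@example.org", role = c("aut", "cre"))
Description: Tools for in vitro seizure-liability screening with multiwell
    micro-electrode arrays (MEA). From spike-timestamp exports the package
    computes a panel of electrophysiological parameters per well (weighted mean
    firing rate, Poisson Surprise burst statistics, spike-train synchrony via
    the area under the pairwise cross-correlogram, inter-spike-interval
    organization, network-burst metrics), converts them to baseline-corrected,
    vehicle-normalized percent effect sizes, calibrates no-effect/mild/strong
    zone cutoffs from statistical tolerance intervals, and maps effects through
    a weighted scoring matrix to one of four hazard labels. Companion machinery
    reproduces stability-based LASSO parameter selection with balanced-error-rate
    evaluation, a random-forest classifier of effect direction (inhibitory,
    excitatory, vehicle-like), reference-panel predictivity metrics, and a
    seeded synthetic 48-well plate simulator so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
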