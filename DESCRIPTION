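Package: nirsbp
Title: Blood-Pressure-Aware Analysis of Functional Near-Infrared Spectroscopy
Version: 0.1.0
Authors@R:
    person("nirsbp", "maintainers", email = "nirsbp@example.org", role = c("aut", "cre"))
Description: Tools to quantify how transient systemic blood-pressure changes
    confound event-related brain near-infrared spectroscopy (NIRS). Implements
    modified Beer-Lambert law conversion between two-wavelength optical-density
    changes and oxy-/deoxyhaemoglobin concentrations with an age-dependent
    differential pathlength factor, zero-phase low-pass filtering, polynomial
    detrending, epoch extraction with baseline correction and outlier
    rejection, beat-to-beat systolic/diastolic/mean arterial pressure
    extraction from continuous finger-pressure waveforms, response
    amplitude/latency metrics, planned statistical comparisons and
    NIRS-versus-pressure coupling regressions. Ships a seeded synthetic-session
    generator emulating deep (cortical) and shallow (extracranial) channel
    physiology with known ground truth, and an end-to-end pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
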