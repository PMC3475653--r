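Package: sifr
Title: Systemic Impact Factors for Missense Mutations in Pathway Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the systemic consequence of a missense mutation as the
    product of its protein stability change (ddG, kcal/mol) and the control
    coefficient of a pathway readout with respect to the rate term the mutation
    perturbs. Ships two reduced ODE models (the fission-yeast G2-M transition
    and the human Ras-Raf-Mek-Erk cascade) with named per-term perturbation
    channels, threshold-event readouts, curve metrics (amplitude, duration,
    peak time), local sensitivity sweeps, Boltzmann-weighted ensemble ddG
    summaries, replica-exchange Monte Carlo parameter calibration against
    reference time courses, and phenotype correlation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
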