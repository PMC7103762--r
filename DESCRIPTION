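Package: uvpolsim
Title: Stochastic Simulation of RNA Polymerase II Transcription Under UV Damage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Event-driven, continuous-time simulation of RNA polymerase II
    transcription on a small ensemble of model genes competing for a finite
    polymerase pool. UV-type DNA lesions stall elongating polymerases, queues
    form behind stalls subject to head-to-tail exclusion, lesions are repaired
    with exponential kinetics, and stalled polymerases can dissociate and be
    either recycled to the free pool or degraded. Includes scenario presets for
    wild-type and degradation-deficient regimes, replicate orchestration into
    binned polymerase density maps, gene-length-stratified metagene profiles,
    exponential half-life fitting of the surviving polymerase pool, a
    degradation-hazard calibration routine, and a synthetic nascent-RNA
    coverage generator with spike-in scale-factor normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    generics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
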