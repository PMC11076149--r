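Package: vaxtwin
Title: Digital-Twin Simulation of Tumor Antigen Presentation and
    Optimal Neoantigen Vaccine Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds an in-silico population of a patient's cancer cells by
    stochastically simulating the MHC class I antigen presentation pathway
    (mutation presence from DNA variant allele frequencies, transcript and
    MHC abundance from gamma-Poisson expression models, proteasomal cleavage
    and peptide-MHC binding competition as multinomial draws, surface
    presentation from predicted complex stability), converts the simulated
    populations into per-cell log no-response coefficients for every
    candidate vaccine element, and selects a budget-constrained neoantigen
    vaccine composition by exact integer optimization under MinSum or
    MinMax objectives. Includes baseline ranking selectors, recall and
    coverage analytics, replicate-consensus (intersection-over-union)
    measures, and a synthetic-patient generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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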