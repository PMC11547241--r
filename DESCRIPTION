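Package: dropscreen
Title: Multiplex Drop-Off Digital PCR Screening and Quantification of
    Circulating Tumor DNA Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of multiplex drop-off digital PCR
    (dPCR) experiments aimed at detecting and quantifying rare somatic
    mutations in plasma cell-free DNA, modeled on a three-color
    droplet-crystal platform. The package encodes a multiplex ERBB2
    screening assay and its confirmatory wild-type/mutant duplexes as
    data, decodes three-channel droplet fluorescence signatures,
    classifies droplets with polygonal gates (including the correction
    for duplication clusters superimposed on the wild-type gate),
    converts droplet counts to copies per reaction, copies per mL of
    plasma and mutant allele frequencies via Poisson partition
    statistics with limit-of-blank correction, calibrates LOB95/LOD95
    detection limits from blank panels, implements the two-step
    screen-then-identify diagnostic strategy, and summarises assay
    validation (CV, linearity, sensitivity) and cohort-level results.
    A synthetic droplet-chamber generator emulates the instrument so
    every step can be exercised and tested without raw chip data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
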