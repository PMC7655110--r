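Package: carloops
Title: Cohesin-Residency Loop Models and Contact-Map Statistics for
    Mitotic Yeast Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A generative simulator of positioned chromatin loops on a
    yeast-like mitotic chromosome, built around per-cell stochastic
    cohesin occupancy of cohesin associated regions (CARs), together
    with the aggregate contact-map statistics used to analyse Micro-C
    style data: contact-decay curves with sliding-window slopes,
    aggregate peak analysis (APA) pile-ups with centre-over-corner
    enrichment ratios, iterative-correction matrix balancing,
    observed-over-expected transforms, a donut-filter loop caller,
    insulation-score boundary detection, aggregate domain analysis with
    pseudo-size rescaling, and emulated cohesin ChIP tracks with peak
    calling and occupancy estimation.  Named depletion scenarios (Mcd1,
    Brn1, Wpl1, Pds5) perturb occupancy and extrusion processivity so
    that the corresponding loop-pattern phenotypes can be generated and
    analysed entirely on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
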