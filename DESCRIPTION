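Package: ddscreen
Title: Droplet Digital PCR Mutation Screening for Urine Liquid Biopsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-channel droplet digital PCR
    (ddPCR) data for multiplex hotspot-mutation screening in urine
    cell-free DNA. Provides an in-silico model of a duplex HEX/FAM
    screening assay (one wild-type probe, several same-fluorophore
    mutant probes), a droplet-level synthetic-data generator with
    exact multinomial template partitioning and a per-molecule
    misread mechanism for false-positive mutant signal, Poisson
    quantification of channel concentrations and mutant allele
    fraction (MAF), control-cohort false-positive MAF cutoff
    calibration at full specificity with subtraction, and
    cohort-level diagnostic evaluation (tie-aware ROC/AUC,
    sensitivity and specificity, multi-marker panel combination, and
    the associated nonparametric test battery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
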