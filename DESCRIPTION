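Package: cyp2c19sup
Title: CYP2C19 Haplogenotype Calling and Personalized Proton Pump
    Inhibitor Dosing for Stress Ulcer Prophylaxis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls CYP2C19 star-allele haplogenotypes from the two common
    functional variants rs12248560 (defining *17) and rs4244285 (defining
    *2), classifies the six predictive metabolizer phenotypes (PM, IM, AM,
    EM, RM, UM), and applies a versioned clinical rule table to produce
    proton-pump-inhibitor dosing recommendations for stress ulcer
    prophylaxis in critically ill patients.  Projects population
    haplogenotype and phenotype frequency profiles from haplotype
    frequencies under Hardy-Weinberg equilibrium, estimates haplotype
    frequencies from genotyped cohorts, and compares populations with a
    Monte Carlo exact chi-square test and Cramer's phi effect size.
    Ships a seeded synthetic-cohort simulator, VCF and tabular genotype
    I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
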