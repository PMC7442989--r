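Package: lpakiv2
Title: Carrier Calling and Population Genetics of LPA KIV-2 Null Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for a nonsense variant hidden inside the
    LPA kringle-IV type 2 (KIV-2) coding copy-number repeat. Implements
    allele-specific qPCR carrier calling from Ct distributions (bagged
    clustering threshold, two-component normal fit, quantile-tail
    ambiguity exclusion), population-genetic characterization (EM
    haplotype frequencies and D'/R2 linkage disequilibrium for a
    carrier-status locus versus a biallelic SNP, Hardy-Weinberg
    carrier-to-allele-frequency conversion, Fisher exact proxy-SNP
    scanning, allelic-location probabilities), collapsed-repeat NGS
    carrier calling from mutant-read fractions with coverage-tiered
    confidence, and covariate-adjusted association of carrier status
    with lipoprotein(a) concentrations pooled by fixed-effect
    inverse-variance meta-analysis. A synthetic-data module generates
    every input with truth labels so the full pipeline is testable
    without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
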