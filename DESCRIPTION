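Package: faiselect
Title: Multi-Trait Genotype Selection with the FAI-BLUP Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-trait selection analysis for replicated clonal crop
    breeding trials. Fits per-trait linear mixed models by EM-REML through
    Henderson's mixed-model equations to obtain genotype BLUPs and
    entry-mean heritabilities; rescales predicted genotypic values in a
    direction-aware 0-100 range; performs exploratory factor analysis
    (eigen extraction, Kaiser retention, varimax rotation) and scores
    genotypes and an ideotype; ranks genotypes by inverse genotype-ideotype
    distance converted to spatial probabilities (the FAI-BLUP index);
    and predicts per-trait selection gains with goal classification and
    sense-grouped totals. Includes a synthetic-trial generator with
    factor-structured genotypic covariance for validation, derived-trait
    formulas (AUDPC, starch content, flour yield), and a one-call pipeline
    with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    pracma
Config/testthat/edition: 3
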