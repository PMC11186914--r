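Package: metenviro
Title: Envirotyping and Multi-Scale QTL Analysis of Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the environments of a plant
    multi-environment trial (MET) from daily weather and nitrogen-management
    records, identifying yield-limiting environmental indicators by partial
    least squares regression with variable selection, clustering environments
    into envirotypes, estimating genotype adjusted means (BLUEs), variance
    components and heritabilities at the environment, envirotype and MET
    scales with linear mixed models, running kinship-corrected genome-wide
    association scans with leave-one-chromosome-out relatedness and
    effective-test significance thresholds, classifying QTL regions as
    stable, interactive or environment-specific, and computing windowed
    nucleotide diversity and Weir-Cockerham FST between sub-populations.
    Includes a seeded synthetic MET generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
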