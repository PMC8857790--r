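Package: acmgrank
Title: Phenotype-Driven Variant Prioritization with ACMG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes genomic variants for clinical review by combining
    two orthogonal axes of evidence: gene-disease validity and variant
    pathogenicity. Gene validity is scored from phenotype-driven gene
    discovery (HPO superclass expansion, known-gene queries over
    OMIM/Orphanet/MedGen/ClinVar-style tables, cross-species models,
    paralogues, protein-protein interaction neighborhoods, and tissue
    expression) using analyst-tunable weights. Variant pathogenicity is
    assessed per ACMG/AMP evidence criteria with justifications and combined
    into the standard five-tier call, including trio de novo detection from
    PED files. Variants are then sorted into four causality bins and ranked;
    a lasso (polygon) filter selects variants in the validity-pathogenicity
    plane. All evidence lives in local plain-text tables and a seeded
    synthetic-data generator makes the whole pipeline testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
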