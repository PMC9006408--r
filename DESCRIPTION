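Package: ontorules
Title: Semantic Biclustering of qPCR Expression Profiles with Ontology-Term Rules
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to turn gene-by-tissue qPCR quantification-cycle (Cq)
    matrices plus ontology annotations into tissue-comparison significance
    labelings, per-term enrichment and coverage statistics, and conjunctive
    ontology-term rules ("semantic biclusters") that discriminate
    significantly from non-significantly regulated genes. Includes delta-Cq
    normalisation against a reference gene, max-plus-two imputation of qPCR
    dropout, per-gene one-way ANOVA with Tukey HSD post-hoc tests,
    hypergeometric term enrichment, exact Fisher tests for categorical
    contingency tables, a two-group complete-separation filter, a beam-search
    rule inducer over ontology DAGs with minimum-specificity constraints, a
    grid runner with t-score based rule selection, and a synthetic-data
    generator with planted rules so every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    digest,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
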