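Package: gemmerge
Title: Consensus Integration of Metabolic Reaction Databases into Tiered
    Genome-Scale Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automated integration of two independent metabolic-reaction
    databases into nested consensus reconstructions at three confidence tiers
    (core, intermediate, complete). Compounds are matched across sources by
    cross-references, synonym lists, a trainable logistic-regression name
    similarity classifier and a ladder of chemical-structure comparisons
    (canonical SMILES, stereochemistry-purged, tautomer-normalized, pH 7.4
    reionized, circular-fingerprint similarity). Reaction-driven iterative
    propagation extends the matching until a fixpoint. Reconstructions can be
    validated for stoichiometric consistency (positive conserved-mass
    witnesses, non-conserved metabolites, minimal inconsistent net
    stoichiometries, elementary leakage modes), analysed as undirected
    substrate-product graphs (degree, clustering, betweenness, closeness,
    centralisation, heterogeneity), and exported as TSV, annotated SBML Level
    3 and GraphML/SIF. A deterministic synthetic-fixture generator emulates
    paired databases with planted discrepancies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (obabel on the PATH) for SMILES
    canonicalization, InChI generation, pH-dependent protonation and ECFP
    fingerprints.
Config/testthat/edition: 3
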