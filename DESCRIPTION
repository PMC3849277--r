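Package: gofunsim
Title: Gene Ontology Semantic Similarity, Fuzzy Term Statistics and
    Functional Clustering
Version: 0.1.0
Authors@R: person("gofunsim", "maintainers", email = "gofunsim@example.org",
    role = c("aut", "cre"))
Description: Computes Gene Ontology (GO) term information content under an
    annotation (corpus-frequency) model and three topology models (descendant
    leaf counting, semantic-contribution propagation, and a topological
    position recursion), pairwise GO term semantic similarity under nine
    approaches, and protein functional similarity under 27 named
    configurations combining term similarities (average, maximum, best-match
    average, average best matches) or weighting annotation closures directly
    (Jaccard, Dice, universal and unweighted indices).  On top of the
    similarity layer it provides fuzzy agreement-level term statistics:
    retrieval of proteins by GO term (binomial test), term enrichment
    analysis (hypergeometric test) with Bonferroni correction, and protein
    clustering (hierarchical with Newick export, and spectral k-means).
    Includes OBO 1.2 and GAF 2.x parsers, deterministic toy fixtures, seeded
    random ontology/annotation generators, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
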