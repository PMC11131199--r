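Package: cazyome
Title: Comparative CAZyome Profiling and CAZyme Gene Cluster Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of carbohydrate-active enzyme
    (CAZyme) repertoires across bacterial genomes. Builds per-gene consensus
    CAZyme calls from three-tool dbCAN2-style annotations, detects CAZyme
    gene clusters (CGCs) by a gene-neighbourhood co-localisation rule, maps
    glycoside hydrolase and polysaccharide lyase families to biomass and
    substrate categories, computes per-genome hydrolytic-potential metrics
    (family diversity, coding frequency, multi-modularity, secretion ratios),
    and compares groups of genomes with Jaccard/PCoA ordination, PERMANOVA,
    ANOSIM, Kruskal-Wallis enrichment with Benjamini-Hochberg correction and
    LEfSe-style linear discriminant effect sizes. Ships a synthetic
    annotated-genome generator with known ground truth so the whole pipeline
    is testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    MASS,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
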