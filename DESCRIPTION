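Package: phylofrac
Title: Phylosymbiosis Detection in Fractions of Host-Associated Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for phylosymbiosis -- congruence between host phylogeny and
    microbiome compositional structure -- from an OTU count table, sample
    metadata and a host tree. Provides taxonomic agglomeration, filtering and
    rarefaction of count tables; Bray-Curtis and Jaccard dissimilarities with
    Ward dendrograms and OTU-bootstrap branch support; the clustering
    information distance (a generalized Robinson-Foulds metric) with a
    tip-shuffle permutation test; Mantel, partial Mantel and single-factor
    PERMANOVA permutation tests with exhaustive enumeration for small panels;
    and a bootstrap/subsampling procedure that partitions the microbiome into
    fractions carrying phylosymbiotic signal. A synthetic-data generator with
    a planted phylosymbiotic OTU fraction and study batch effects makes every
    stage testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
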