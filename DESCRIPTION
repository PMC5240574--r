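Package: RINGcat
Title: Detection, Classification and Expression Analysis of RING Finger
    Protein Domains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Catalogs RING zinc-finger domains in protein sequences by
    exhaustive metal-ligand pattern search, classifies them into the eight
    plant RING types (RING-H2, RING-HCa, RING-HCb, RING-v, RING-C2, RING-D,
    RING-S/T, RING-G) using residue-identity and inter-ligand spacing rules,
    and distinguishes RING-v domains from PHD fingers by their spacing
    signature. Downstream tools compute per-type spacing histograms and
    consensus windows, ligand-anchored residue-frequency matrices with
    over-represented residue calling, domain-architecture grouping from a
    user-supplied annotation table, ligand-anchored multiple alignments with
    separately aligned variable loops, and hierarchical clustering of
    tissue expression profiles (uncentered Pearson distance, complete
    linkage) with preferential-tissue calling. A synthetic proteome and
    expression generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
biocViews: SequenceMatching, Classification, Clustering, GeneExpression
RoxygenNote: 7.3.3
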