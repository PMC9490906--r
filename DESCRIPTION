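Package: spikelnc
Title: Population-Scale lncRNA Discovery and Genetics for the Wheat Spike Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for characterising long non-coding RNAs
    (lncRNAs) in a population transcriptome setting: candidate lncRNA calling
    from reference-guided assemblies via structural class codes plus
    expression, length and coding-potential consensus filters; cis/trans
    lncRNA-mRNA target pairing from genomic proximity, Spearman co-expression
    and pairing free energy; population-genetic characterisation (nucleotide
    diversity, Weir-Cockerham Fst, SNP density, haplotype tables with a
    major-haplotype rule, lineage diversity shifts); competing endogenous RNA
    (ceRNA) triangle inference from shared miRNA binding sites; per-SNP trait
    association with population-structure correction, candidate-window
    assignment and QTL/introgression co-localization; and cross-species
    conservation scoring with a distance-based species tree. A synthetic-data
    generator emulates the statistical structure of a nine-group
    Triticum/Aegilops diversity panel so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
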