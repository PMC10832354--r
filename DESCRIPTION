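Package: anchorlift
Title: Allele-Aware Liftover of VCF Records Across Genome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts variant call format (VCF) records between genome
    assemblies through UCSC chain files using maximally extended record
    representations. Each variant is reduced to its unique maximally
    extended form, the 5' and 3' anchor bases of that form are mapped
    through the chain, and the destination sequence between the mapped
    anchors decides whether the reference allele is unchanged, swapped
    with an alternate allele, or replaced by a novel reference allele.
    Anchors falling inside chain gaps are recovered by global affine-gap
    realignment of the flanking sequence. Allele-indexed annotations
    (Number=A/R/G fields, AF- and AC-like fields, GWAS-VCF effect sizes)
    are updated consistently whenever the allele order changes. A
    synthetic assembly-pair generator produces paired genomes, their
    exact chain, planted variants and a truth table for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    optparse
Config/testthat/edition: 3
biocViews: VariantAnnotation, Genetics, Software
RoxygenNote: 7.3.3
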