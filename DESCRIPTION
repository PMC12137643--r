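Package: orchardpop
Title: SNP-Array Design, Kinship Networks and Mixed-Model GWAS for
    Clonal Orchard Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis toolkit for high-density SNP-array studies of
    clonally propagated orchard crops such as peach. Implements the
    staged array-design filter cascade (quality control, shared-variant
    and probe-uniqueness filters, genotype-performance categories,
    legacy-array integration, annotation and funnel reporting),
    SNP-based and pedigree-based kinship with threshold network
    clustering, identity-by-descent segment handling with shared-region
    discovery per kinship cluster, an eigendecomposition-based linear
    mixed model association scan with variance-explained reporting,
    LD-block haplotype analysis with least-significant-difference group
    comparisons and minimum-spanning haplotype networks, a
    two-population sliding-window selection scan, a three-marker
    early-flowering classifier with contingency-based accuracy
    evaluation, and a gene-dropping simulator that generates genotypes,
    phased haplotypes, pedigrees, IBD truth and QTL phenotypes for
    validating the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vcfR,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
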