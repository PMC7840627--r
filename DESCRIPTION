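Package: comphet
Title: Compound-Heterozygous Disease-Gene Discovery in Livestock Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for mapping recessive and compound-heterozygous
    Mendelian disease variants in closed livestock flocks from SNP-array and
    trio whole-genome sequencing data. Provides SNP-array quality control,
    Mendelian-error parentage verification and maternity assignment,
    runs-of-homozygosity detection with allele-matched shared-autozygosity
    intersection across cases, a nonparametric allele-sharing linkage scan
    with a Monte-Carlo gene-drop null, a trio-based variant funnel (privacy
    against local and global control cohorts, trio phasing, inheritance-mode
    classification, linkage-region prioritisation), and an isoform-aware
    transcript consequence engine with canonical splice-site disruption,
    cryptic-acceptor rescue, frameshift translation and HGVS c./p.
    nomenclature. A pedigree gene-drop simulator generates synthetic flocks
    with known truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
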