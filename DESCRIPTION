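Package: haploscent
Title: Haplotype-Resolved Allelic Imbalance, Divergence and Introgression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for phased diploid plant genomes: syntenic
    allele pairing between haplotype assemblies, Nei-Gojobori (1986) Ka/Ks and
    flanking-region divergence between alleles, classification of allele pairs
    into consistent/inconsistent/no allele-specific expression across flower
    developmental stages, attribution of structural variants to gene regions,
    windowed nucleotide diversity, Weir-Cockerham Fst with top-quantile sweep
    calling, Patterson's D with block-jackknife Z and Martin's fd introgression
    scans, and candidate-gene haplotype to metabolite association. Includes a
    seeded synthetic-data generator that emulates the assumed data structure
    (diploid genome pair, allelic counts, four-population panel with planted
    introgression, haplotype-driven phenotype) for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    SummarizedExperiment,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
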