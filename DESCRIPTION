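Package: MutMapBSA
Title: Bulked-Segregant SNP-Index Mapping of EMS-Induced Mutations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Causal-mutation mapping for EMS-mutagenised plant populations by
    bulked-segregant analysis in the MutMap style. Reads multi-sample VCFs
    (wild-type parent, mutant parent, recessive F2 bulk), applies a six-rule
    SNP filtration cascade (depth, genotype quality, parental homozygosity and
    divergence, EMS transition spectrum), computes the per-site SNP index from
    bulk allele depths, smooths it with a sliding window along chromosomes and
    calls candidate regions above a fixed index threshold. Also provides
    continuity-corrected chi-square tests for Mendelian segregation ratios,
    KASP-style genotype-phenotype co-segregation checks, gene-model-aware
    consequence annotation of point mutations (splice-junction disruption with
    intron retention, premature stop codons, truncated proteins), and a seeded
    simulator of the whole experimental design (EMS mutagenesis, F2 cross with
    Haldane recombination, recessive-bulk selection, finite-depth pooled read
    sampling) so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    graphics,
    BiocGenerics,
    withr
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
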