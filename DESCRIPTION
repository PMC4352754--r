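Package: crisprAudit
Title: Variant-Aware Auditing of CRISPR/Cas9 Guide Specificity
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing the genomic specificity of CRISPR/Cas9
    guide RNAs in the presence of personal genetic variation. Provides
    PAM-constrained genome-wide enumeration of candidate target sites and
    k-mismatch off-target scanning with PAM-anchored mismatch positions
    (both a brute-force and a pigeonhole seed-and-verify scanner),
    overlay of single-nucleotide variants onto off-target sites to detect
    mismatch "conversion" events that sensitise an allele to cutting,
    zero-intercept regression of conversion fractions against off-target
    counts, quantification of Cas9 activity from amplicon deep-sequencing
    reads (cut-site indel fractions, allele-specific assignment at a
    discriminating SNV, on-target-normalised efficiencies), clone-level
    variant screening filters (sample-specific variants, discordant-read
    support, flanking guide-homology search), and fully seeded synthetic
    data generators with ground truth for end-to-end validation.
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
    GenomeInfoDb,
    BiocGenerics,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
biocViews: CRISPR, Sequencing, Alignment, SNP, GenomeWideAssociation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
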