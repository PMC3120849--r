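Package: dgetag
Title: Tag-Based Digital Gene Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for tag-based digital gene expression (DGE)
    profiling, the LongSAGE-style protocol in which NlaIII/MmeI digestion
    yields 21-nt CATG-anchored cDNA tags counted per gene. Builds virtual
    reference tag libraries (all CATG+17 subsequences of a transcriptome,
    both strands), cleans raw 35-nt tag reads into 21-nt clean tags, maps
    tags with at most one mismatch while filtering multi-gene tags,
    quantifies sense and antisense expression as transcripts per million
    clean tags (TPM), tests differential expression between two libraries
    with the Audic-Claverie Poisson exact test under FDR control, performs
    hypergeometric term enrichment and hierarchical clustering of
    differential-expression patterns, and summarises taxane metabolite
    concentration tables. A seeded simulator generates transcriptomes,
    tissue expression profiles and raw tag reads with ground truth so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
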