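Package: polyedit
Title: Allele-Aware CRISPR Guide Design and Fragment-Analysis Editing
    Quantification for Polyploid Protoplast Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Scoring of CRISPR/Cas9 ribonucleoprotein (RNP) editing in
    polyploid protoplast cell pools.  Provides allele-aware
    characterization of target regions (locus parsing, gene models,
    inter-allelic SNP/indel calling and polymorphism-prevalence
    statistics), SpCas9 PAM-site scanning with allele-consensus
    filtering, polymorphism-avoiding diagnostic amplicon (IDAA) primer
    placement, quantification of editing efficiency and indel spectra
    from size-calibrated capillary-electrophoresis fragment traces,
    multiplex (twin-RNP) synergy statistics, a full-allelic knockout
    probability model, in-silico versus in-vivo guide rank concordance,
    and a seeded synthetic-data generator that emulates tetraploid
    haplotypes, per-allele editing outcomes and chromatogram traces with
    known ground truth, so the whole pipeline can be exercised end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    pracma,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
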