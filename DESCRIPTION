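Package: lesionseg
Title: Strand-Resolved Analysis of Lesion Segregation in Mutagen-Induced Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of strand-phased somatic mutagenesis in tumours arising
    from a single burst of DNA base damage. Chromosome-scale mutational
    asymmetry is used to phase the lesion-containing strand per genomic
    segment and per tumour; downstream analyses quantify composition-weighted
    mutation and multiallelic rates, transcription-coupled repair across
    expression strata, replication-timing and fork-directionality strand
    biases, translesion-synthesis mutation clusters with permutation nulls
    and equally-optimal indel alignment enumeration, positional damage versus
    repair profiles around genomic features, and the variant-allele-frequency
    enrichment signature of translesion resynthesis-induced mutagenesis
    (NER-TRIM). A synthetic lesion-segregation simulator with ground-truth
    labels supports parameter-recovery and null-calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
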