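Package: raddmap
Title: De Novo ddRADseq Linkage Markers for Outbred F1 Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds mapping-ready SNP markers from double-digest RAD
    sequencing of an outbred F1 (CP) family when no reference genome is
    available. Constructs a de novo locus catalog by streaming k-mer
    digital normalization (with a center-star alternative), counts read
    support with a lenient seeded matcher and removes low-support and
    very-high-copy (plastid-like) loci, genotypes individuals with a
    minimal pileup caller or an imported VCF, classifies parental
    configurations into the five CP-informative segregation types, applies
    the premapping filter cascade (multi-SNP sequences, SNP position,
    missing data, segregation-distortion chi-square, individual exclusion,
    similarity deduplication) with stage-by-stage accounting, exports
    JoinMap CP-format files with fixed framework orders, and provides
    linkage quality control: independence-LOD grouping, two-point
    recombination fractions, Kosambi distances, map-inflation and
    framework-order diagnostics, and per-linkage-group summaries. A
    configurable family simulator with full ground truth (crossovers,
    repeat families, a plastid-like high-copy sequence, per-base error)
    makes every stage testable, including sequencing-depth downsampling
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
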