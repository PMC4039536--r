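Package: repliscape
Title: Replication-Timing Analysis of BrdU-IP-Seq Experiments in Budding Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for analyzing DNA replication timing from
    BrdU immunoprecipitation sequencing (BrdU-IP-Seq) of hydroxyurea-arrested
    or S-phase-synchronized Saccharomyces cerevisiae cultures. Converts aligned
    read fragments to smoothed, quantile-normalized coverage tracks; calls
    BrdU-enriched peaks with a Poisson local-background test and cross-references
    them against annotated replication origins; classifies origins into
    Rif1-repressed, Rif1-unregulated and Rif1-activated classes with a negative
    binomial exact test under Benjamini-Hochberg FDR control; and computes
    genomic-landscape statistics (replication-timing quartile metaprofiles,
    centromere/telomere proximity tables, distance-by-class tests, binding-site
    overlap counts). Includes a stochastic generator of wild-type versus rif1
    deletion BrdU incorporation experiments with known per-origin firing times,
    so every pipeline stage can be exercised against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    yaml
Config/testthat/edition: 3
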