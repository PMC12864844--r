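Package: glorimap
Title: Single-Nucleotide m6A Mapping, Scoring and Site Statistics for
    GLORI-Style Deamination Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-base N6-methyladenosine (m6A) analysis of
    GLORI-style deamination sequencing in transcript coordinates: per-adenosine
    scoring (A/(A+G)) with background-calibrated Fisher filtering and replicate
    aggregation; transcript-topology summaries (metagene binning, exon-junction
    distance, inter-site spacing, adjacent-site score correlation); a
    single-molecule co-methylation linkage test on reads spanning adjacent
    sites; a gradient-boosted sequence-context model of site stoichiometry;
    cross-species site-context conservation by best-Hamming window scanning;
    and the resampling statistics used for enrichment claims
    (expression-matched stratified bootstrap, Jaccard permutation test,
    hypergeometric lineage test). A synthetic-data module generates
    transcriptomes, methylation truth, converted reads, homologs, differential
    expression tables and gene sets so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
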