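Package: chromstates
Title: Four-State Chromatin Segmentation and Heterochromatin Feature
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments a genome into four chromatin states (Aquamarine,
    Lazurite, Malachite, Ruby) from binarized multi-protein occupancy
    tracks using a Bernoulli-emission hidden Markov model trained by
    Baum-Welch and decoded by Viterbi, tests per-state protein enrichment
    with two-sided rank-based statistics, and provides region bookkeeping
    for heterochromatin annotation: per-megabase gene and
    origin-recognition-complex site densities for named regions, and
    eight-level RPKM expression-category profiling across tissues.
    Includes a synthetic-data generator with known ground truth (hidden
    state paths, region feature densities, expression categories) so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
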