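Package: mirmark
Title: Cross-Platform Validation of Bladder Cancer miRNA Expression Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for evaluating published microRNA (miRNA)
    markers of bladder cancer against three expression-profiling platforms.
    It quantifies miRNA abundance from raw small-RNA reads (adapter trimming,
    length filtering, read collapsing, mismatch-tolerant mapping to a mature
    miRNA reference, reads-per-million normalisation), applies three
    platform-specific differential-expression calling procedures (per-sample
    fold-change voting for deep sequencing, ratio thresholds for suppression
    subtractive hybridisation libraries, and a p-value plus fold-change rule
    for microarray signals), scores each marker's sensitivity, specificity
    and the summary AUC = (Sp + Sn)/2, and measures directional concordance
    of the observed calls with a published marker catalogue, including
    cross-method congruence sets. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is exercised end to
    end at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
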