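Package: midiexpress
Title: Expressive MIDI Performance Analysis for Teaching Versus Performing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing expressive piano performance captured as MIDI:
    Standard MIDI File and note-table input/output, score-to-performance
    alignment with pitch-error classification (extra, missing, substituted),
    extraction of expressive features (inter-onset intervals, key-overlap
    time and ratio, key velocity, velocity differences at dynamics
    transitions), screening rules (tempo-based participant exclusion,
    3-SD outlier removal), and an inferential layer with Shapiro-Wilk-gated
    paired comparisons and 2x2 repeated-measures ANOVA with generalized eta
    squared and Tukey-adjusted post-hoc contrasts. A calibrated synthetic
    cohort generator emulating teaching-versus-performing modulations makes
    the whole pipeline testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    stats,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    emmeans,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
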