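Package: updown
Title: Automated Reading and Scoring of Handwritten Up-Down von Frey Sheets
Version: 0.1.0
Authors@R: person("updown", "maintainers", email = "updown@example.org",
    role = c("aut", "cre"))
Description: Tools for the up-down (staircase) method of estimating 50%
    mechanical withdrawal thresholds with von Frey filaments. Generates
    printable scoring templates for mouse, rat and human (MDT/MPT) assays,
    reads scanned sheets back (frame location, perspective correction,
    per-cell mark classification with a k-nearest-neighbour ensemble),
    validates and repairs the recorded response sequences against the
    exhaustive lexicon of legal up-down tables via Levenshtein closest
    match, and computes Dixon 50% thresholds (10^(Xf + kappa*delta)/10000
    grams). Includes a full synthetic fixture stack: psychometric subject
    simulation, protocol execution, handwriting-style glyph generation and
    scan-noise rendering with ground truth, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
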