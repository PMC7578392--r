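Package: f0entrain
Title: Prosodic Entrainment Analysis for Dyadic Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures fundamental-frequency (f0) entrainment between the two
    speakers of a conversation. Reads Praat TextGrid annotations and
    frame-wise pitch tracks, restricts analysis to linguistically meaningful
    utterances, summarises each speaker's mean f0 and f0 interquartile range
    over the first and last thirds of the conversation, and scores
    convergence or divergence as the change in perpendicular distance from
    the dyad's joint feature point to a pitch-matching (or octave
    half-matching) reference line. Per-speaker responsibility and signed and
    adjusted entrainment contributions attribute the change to individual
    speakers. Includes the study-level regression and effect-size layer, a
    synthetic dyad generator with exact ground truth for validation, and a
    command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
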