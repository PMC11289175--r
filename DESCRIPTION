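Package: mafi
Title: Mouth and Facial Informativeness Norms from Speechreading Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how visually informative spoken words are from silent
    speechreading guesses. Computes a phonologically weighted feature edit
    distance between IPA transcriptions of target words and typed responses,
    normalizes by word length, and aggregates per-word mouth and facial
    informativeness (MaFI) scores together with companion metrics
    (Levenshtein distance, speechreading accuracy, percent phonemes correct).
    Also codes visually salient phoneme and viseme features (frontness,
    roundness, lower lip tuck, protrusion, labial closure, lip rounding),
    computes per-word informativeness loads, fits feature regressions with
    lexical covariates compared by likelihood ratio against a lexical
    baseline, correlates norm sets across speaker or perceiver variants, and
    simulates speechreading response corpora under a viseme-confusion noise
    model so the full pipeline is testable without human data.
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
    dplyr,
    stringi
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    lmtest
Config/testthat/edition: 3
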