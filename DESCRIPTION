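Package: situfuzz
Title: Fuzzy Situation Inference from Smartphone Context Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fuzzy rule-based engine for recognising user-defined daily-life
    situations (e.g. "working", "relaxing at home") from smartphone-style
    context streams: GPS position, clock time, day of week and activity-class
    probabilities. Situations are fuzzy rules over linguistic terms (near,
    morning, weekend, ...) evaluated by per-rule max-product composition;
    the package adds location-staleness confidence decay, a battery-aware
    simulated inference loop with an availability contract for ecological
    momentary assessment clients, a transition history store, a synthetic
    daily-routine trace generator with ground-truth labels, and accuracy
    scoring of inferences against labels or user confirmation logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
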