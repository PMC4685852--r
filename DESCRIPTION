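Package: rhythmscape
Title: Rhythm Landscapes for Developmental Analysis of Vocal Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to visualize and quantify the development of vocal rhythm
    from note-onset data, designed around songbird recordings sampled
    intermittently across ontogeny. Builds inter-onset-interval (IOI),
    note-duration and silent-gap distributions and two-dimensional
    developmental "rhythm landscapes"; detects rhythm bands as local maxima
    of kernel-smoothed daily IOI distributions, tracks them across recording
    days and classifies new-band emergence as branching from a stem band or
    de-novo appearance; measures rhythm proficiency as the Jensen-Shannon
    divergence to the crystallized (final-day) distribution, with
    exponential-decay fits and paired crystallization tests; and ships a
    seeded simulator of developmental song timing so every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
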