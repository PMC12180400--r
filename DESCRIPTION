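Package: birdsurv
Title: Comparing Bird Survey Methods: Point Counts, Acoustic Recorders and
    Citizen Science
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing bird survey methods - fixed-radius point
    counts, annotated recordings from autonomous recording units (ARUs) and
    citizen-science checklists - on a common statistical footing. Provides
    species accumulation curve fitting with survey-completeness effort
    estimates, effort-matched resampling of one-minute recordings into
    simulated point counts, frequency-of-occurrence tables with a
    normality-gated paired comparison (Kolmogorov-Smirnov gate choosing
    between a paired t-test and the Wilcoxon signed-rank test),
    heard-versus-seen cue composition, forest-dependency tallies, and a
    multi-label neural classifier head over per-recording acoustic
    embeddings. A parameterised synthetic-community generator makes every
    stage runnable and testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
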