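Package: diurnal
Title: Diurnal Rhythmicity Analysis of Expression and Occupancy Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of 24-hour rhythms in
    feature-by-sample time courses sampled at zeitgeber times over one or
    more days. Fits per-feature harmonic (cosinor) regressions and derives
    amplitude, phase and an F-test p-value; estimates the false discovery
    rate of rhythm calls by permutation of sample time labels; filters,
    partitions and summarises rhythmic gene sets across conditions
    (reverse cumulative amplitude frequencies, phase histograms, circular
    phase-shift summaries); clusters temporal profiles by partitioning
    around medoids with the number of clusters selected by the best
    average silhouette width; and compares locus occupancy scores between
    day and night (or between two timepoints) with an empirical-Bayes
    moderated t-statistic. A synthetic-data generator plants rhythms and
    day/night effects with known parameters so that every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
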