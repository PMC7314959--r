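Package: phenofield
Title: PhenoCam Field Phenotyping: Greenness Signals, Phenological Timing and
    Spatially Corrected Genotype Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn repeated RGB imagery of a field trial into
    genotype-level phenology. Extracts a robust per-plot green chromatic
    coordinate (gcc) signal from time-stamped frames and polygon plot masks,
    collapses it to a daily median series smoothed with a Savitzky-Golay
    filter, detects phenological transition points (start of green-up, green
    peak, senescence peak, end of senescence) and phase durations, corrects
    plot values for field heterogeneity and viewing geometry with a
    two-dimensional P-spline (PS-ANOVA) mixed model yielding genotype BLUEs
    and effective-dimension heritability, and relates phenological timing to
    in-season and harvest traits. Includes a fully specified synthetic
    campaign generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    signal,
    splines,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
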