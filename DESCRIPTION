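Package: rhythmdiff
Title: Differential Rhythmicity Analysis for Circadian Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects rhythmic genes in around-the-clock expression profiles
    with a rank-based JTK-style test (tie-grouped cosine references, exact
    Kendall-S null, 20-28 h period grid, single-cycle concatenation), tests
    for between-group rhythm differences with parametric and robust harmonic
    regression combined into a meta p-value, classifies genes into
    differential-rhythmicity categories (unchanged, phase change, other
    difference, gained, lost) with a configurable decision table, summarises
    peak phases with circular statistics (mean vector, Rayleigh test, 95
    percent confidence arcs), and simulates pooled circadian transcriptome
    designs with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
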