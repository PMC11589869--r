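Package: secretolyze
Title: Kinetic Analysis of Calcium-Triggered Exocytosis from Membrane
    Capacitance Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify secretion kinetics of neuroendocrine cells
    from whole-cell membrane capacitance recordings. Decomposes flash
    (calcium uncaging) evoked capacitance responses into readily and
    slowly releasable pool components, sustained secretion and secretory
    delay; quantifies premature (tonic) secretion during submicromolar
    calcium loading; analyses slow calcium-ramp recordings into
    interval-wise fusion rates, Hill-equation calcium dependence and the
    calcium concentration of half-maximal pool depletion (P50); and ships
    a seeded forward kinetic simulator that generates synthetic
    recordings with the statistical structure the analysis assumes, so
    the whole pipeline is testable without experimental data. Includes
    the group-comparison workflow commonly used with such recordings
    (normality gate, ANOVA/Tukey or Kruskal-Wallis/Dunn).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
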