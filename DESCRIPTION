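Package: thermoniche
Title: Thermal Niche Analysis of Dung Beetle Assemblages from Infrared
    Thermography and Community Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of the thermal niche of dung beetles:
    extraction of thorax, abdomen and environment temperature traces from
    thermographic frame stacks (maximum of 3x3-pixel regions of interest,
    greybody radiometric correction, emissivity estimation), estimation of
    endothermy (excess temperature) and least-squares temperature slopes
    during flight, rule-based classification of physiological
    thermoregulation mechanisms (abdominal passive vs active heat transfer),
    indicator-species analysis (IndVal with permutation inference) and daily
    activity classification from pitfall capture schedules, diel summaries of
    ground-temperature sensor logs, and comparative statistics (linear mixed
    models with type-III Wald chi-square tests and Tukey contrasts,
    Kruskal-Wallis with Conover-Iman post hocs). A seeded synthetic-data
    generator emulates every input with known ground truth so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    car,
    emmeans,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
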