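Package: polmorph
Title: Colour-Vision Modelling, Reproductive Statistics and Genetic
    Diversity for Colour-Polymorphic Flower Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for colour-polymorphic, deceptively
    pollinated orchid populations. Models flower reflectance spectra in
    the hymenopteran hexagon colour space (photoreceptor quantum catches
    with von Kries adaptation, colour and green contrast, pairwise colour
    distances) and classifies colour pairs against a psychometric
    discrimination threshold calibrated from behavioural data.
    Reproduces reproductive-success statistics from tagged-plant records
    (contingency-table chi-square tests, regressions, association
    measures, fruit-set rates, seed-viability tests) and population
    diversity statistics from dominant binary markers (expected
    heterozygosity, Shannon index, AMOVA phi-PT with permutation tests)
    and aligned sequences (Jukes-Cantor distances, within- and
    among-group diversities, coefficient of differentiation). Includes
    seeded synthetic-data generators for every input so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
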