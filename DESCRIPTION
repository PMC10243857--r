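Package: zincmt
Title: Zinc-Metallothionein Affinity, Speciation and Unbinding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of zinc binding to multi-site thiolate
    proteins such as metallothionein-2. Provides chelating-probe competition
    equilibrium models and their inversion to stepwise dissociation constants,
    a mass-balance speciation solver, fluorescence-based free-zinc calibration
    with Hill-equation fitting, first-order thiolate-oxidation kinetics,
    a zinc-buffering species-distribution model, and post-processing of
    steered molecular dynamics metal-unbinding trajectories (contact numbers,
    dissociation pathways, rupture-force statistics, pulling work). Seeded
    synthetic-data generators emulate every supported input kind so complete
    pipelines can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
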