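Package: amdscreen
Title: Two-Eye Markov Model for Cost-Effectiveness of AMD Screening
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A first-eye and second-eye combined Markov state-transition
    model of age-related macular degeneration (AMD) for evaluating the
    clinical effectiveness (reduction in blindness) and cost-effectiveness
    (incremental cost per quality-adjusted life year) of population
    screening programmes in a Japanese setting. Provides an annual-cycle
    individual-level microsimulation and an exact deterministic cohort
    (expected-value) engine over the same event rules, natural-history and
    treated transition probabilities for neovascular AMD, screening and
    consultation detection pathways, anti-VEGF injection and photodynamic
    therapy costing, better/worse-eye utilities, discounting, incremental
    cost-effectiveness ratios, screening-programme grid search, one-way
    (tornado) sensitivity analysis and probabilistic sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
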