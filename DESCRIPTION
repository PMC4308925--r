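Package: dorsalhorn
Title: Quantification of Dorsal Horn Neuronal Responses and Behavioural
    Pain Pharmacology in the Rat MIA Osteoarthritis Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vivo dorsal horn electrophysiology
    and behavioural pharmacology in the monosodium iodoacetate (MIA) rat
    model of osteoarthritic pain. Quantifies electrically evoked responses
    by afferent latency band (Abeta, Adelta, C, postdischarge), computes
    the input and wind-up measures of spinal excitability, applies the
    baseline-stability screen and maximum-percentage-change dose-effect
    measure across cumulative dosing timecourses, estimates 50% paw
    withdrawal thresholds by the Dixon up-down staircase, and runs the
    accompanying statistical battery (exact and approximate Mann-Whitney U,
    Kruskal-Wallis with Dunn's posttest, repeated-measures ANOVA with
    Bonferroni-corrected paired t-tests). A synthetic-cohort generator
    emulates MIA/sham experiments with state-dependent drug inhibition so
    every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
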