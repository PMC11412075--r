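Package: plastrec
Title: Phenotypic Plasticity and Post-Drought Recovery Indices for
    Family Trials
Version: 0.1.0
Authors@R:
    person("Plastrec", "Developers", email = "plastrec@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing intra-population functional variability in
    common-garden drought experiments with maternal families. Computes the
    relative distance plasticity index (RDPI) for phenotypic plasticity (PP)
    and post-drought recovery (RE) per trait and family, tests among-family
    differences by permutation, fits a log-linear model of stomatal
    conductance against predawn water potential with family-specific
    intercepts and slopes (sequential ANOVA, coefficient confidence
    intervals and compact letter display), runs two-way ANOVA with
    assumption checks on recovery gas exchange, and performs hierarchical
    clustering with bootstrap support, principal components analysis and
    FDR-corrected correlation analysis of the family index profiles. A
    synthetic-data generator emulates a split-plot watering experiment
    (families x watering regimes x blocks) so the whole pipeline can be
    exercised end-to-end without access to restricted field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    ape
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
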