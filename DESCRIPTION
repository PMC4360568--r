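Package: mutload
Title: Poisson Models of the Genomic Load of Deleterious Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for the genomic load of
    deleterious mutations in a stable human population. Provides the
    Poisson zygote-load model with a mutation-selection truncation
    equilibrium solver, a forward-in-time simulator of synergistic
    selection across essential genetic systems, first-cousin autozygosity
    estimators of the mean load from recessive-disease fractions,
    the algebra linking X-linked carrier prevalence to excess male
    infant mortality, and critical branching-process calculators for
    neutral-mutation survival and the divergence clock. Includes seeded
    synthetic-cohort generators for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
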