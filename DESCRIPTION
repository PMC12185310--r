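Package: twindirect
Title: Direct and Indirect Genetic Effects on Externalising Phenotypes in Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates direct from indirect genetic effects on externalising
    phenotypes using dizygotic twin pairs: within/between-family polygenic-score
    regressions with bias-corrected accelerated (BCa) bootstrap inference on the
    indirect effect, univariate ACE/ADE twin variance decomposition by full-
    information maximum likelihood (with an optional sibling-interaction term),
    and one-factor confirmatory factor analysis with FIML under missingness for
    common, reporter- and age-specific factor scores. Includes a synthetic
    twin-cohort generator emulating the passive gene-environment-correlation
    mechanisms that bias polygenic prediction (genetic nurture, assortative
    mating, population stratification) and a study pipeline that runs the full
    design across a phenotype-by-age-by-reporter grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
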