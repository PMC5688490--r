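Package: costkit
Title: Ingredients-Based Costing of Maternal, Newborn and Child Health
    Intervention Packages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An ingredients-based costing engine for maternal, newborn and
    child health (MNCH) intervention packages. Computes per-case unit costs
    from drug and supply ingredients, provider time by cadre, and
    outpatient-visit/inpatient-day overheads; scales them by target
    populations, need and effective coverage into annual facility-level
    costs; adds above-facility program costs; and compares scenarios to
    produce incremental costs and cost-per-life-saved league tables. Also
    implements the translog cost-function factor-share estimator (with
    heteroskedasticity-robust Huber/White covariance) that supplies the
    other-direct-cost and indirect-cost proportions applied to
    outpatient/inpatient "hotel" costs, together with a synthetic-data
    generator for toy-country scenarios and facility cost records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
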