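Package: ozonekin
Title: Competition Kinetics and Abatement Modeling for Wastewater Ozonation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determination of apparent second-order rate constants for reactions
    of micropollutants with ozone by multicompound competition kinetics, with
    quality-control gates and competitor averaging; acid-base speciation and
    speciation-corrected Hammett/Taft structure-reactivity correlations;
    hydroxyl-radical exposure determination from para-chlorobenzoic acid probe
    depletion and hydroxyl-radical scavenging budgets; first-order abatement
    modeling of micropollutants during full-scale wastewater ozonation with
    Monte Carlo uncertainty propagation and derivative-based sensitivity
    indices; and qualitative metabolite-versus-parent reactivity rules. A
    synthetic-data module generates competition experiments, probe-compound
    assays and plant field datasets with the statistical structure the
    estimators assume.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
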