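Package: rmdefense
Title: Resource-Competition Models of Restriction-Modification Defense in
    Host-Phage Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how nutrient supply selects for restriction-
    modification (RM) antiviral defense in bacteria. Implements three chemostat-
    style host-phage interaction models (a general model with one shared phage, a
    parallel model with host-specific phages, and a memory model in which progeny
    virions inherit the host methylation pattern and so partially evade matching
    RM systems), steady-state supply sweeps with warm starts, Latin hypercube
    parameter ensembles, rule-based calling of complete RM systems from
    precomputed domain and alignment evidence tables, genus-level statistics of
    RM systems per genome (quantiles, linear and negative-binomial regressions on
    genome size, rank-sum comparisons), and synthetic-data generators with
    planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    lhs,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
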