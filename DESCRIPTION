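Package: ppealloc
Title: Fairness-Efficiency Optimization of Emergency PPE Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Location-allocation planning for personal protective equipment
    (PPE) during infectious-disease emergencies. Models victims' bearing
    capacity as a convex waiting-cost curve that plateaus at a maximum
    per-kilogram loss, combines unmet-demand (fairness) and delayed-delivery
    (efficiency) losses into a single loss objective, and trades it off
    against logistics cost in a three-layer reserve/distribution-center/area
    network. Provides the mixed-integer linear formulation, a preemptive
    goal-programming transformation, a branch-and-bound solver with an
    LP-relaxation warm-start heuristic, exhaustive oracles for validation,
    Pareto-front tracing, sensitivity scans, instance (de)serialization, a
    packaged case study, a seeded synthetic-instance generator, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
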