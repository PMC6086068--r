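Package: protractr
Title: Protracted Speciation Simulation and Birth-Death Rate Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates lineage-level genealogies under the protracted
    speciation model, in which speciation is a duration rather than an
    instant: population lineages split, convert into good species, and
    are extirpated, each as independent exponential-rate events. Provides
    closed-form calibration between macro-level speciation/extinction
    rates and the three micro-level rates, random-representative pruning
    of genealogies to ultrametric species trees, sister-pair (cherry)
    statistics, a constant-rate birth-death likelihood with maximum
    likelihood estimation on branching times, and reproducible pipelines
    for a latitudinal-diversity-gradient scenario comparison and a full
    factorial sweep of the micro-rate parameter space.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, stats
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
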