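# protractr

Speciation is not an instant. A new species begins as an incipient
population lineage that must persist long enough to complete reproductive
isolation — and whether it does so is governed by population-level rates,
not by the macroevolutionary "speciation rate" that birth-death models
estimate from phylogenies. `protractr` simulates lineage-level genealogies
under this protracted speciation model and pushes them through the standard
macroevolutionary pipeline, so that one can ask: which population-level
processes produce a given diversity pattern, and can birth-death inference
tell them apart?

The package is aimed at researchers in diversification modelling and
macroevolution. It provides:

* **an exact Gillespie simulator** of protracted genealogies: population
  splitting at rate λ′, conversion of incipient lineages into good species
  at rate χ, extirpation at rate μ′ (all per lineage per Myr), run forward
  over a fixed time span from a crown start, conditioned on survival of
  both crown lineages;
* **closed-form calibration** between macro rates and micro rates:
  χ = 1/(2t) from a mean sister-species age t, λ′ = λ/χ, and
  μ = (μ′)^(e^{λ′}(1−χ)) with its inverse;
* **species-tree utilities**: random-representative pruning (one surviving
  population lineage per extant species), Newick I/O, branching times,
  cherry (sister-pair) identification and cophenetic distances;
* **constant-rate birth-death ML** on branching times (crown-conditioned
  reconstructed-process likelihood, multi-start quasi-Newton optimiser);
* **two turnkey experiments**: a three-scenario latitudinal-diversity-
  gradient comparison for birds, and a 5×5×5 sweep of the micro-rate space
  with birth-death re-estimation and a confounding report of
  indistinguishable parameter combinations.

## Worked example

Calibrate tropical-bird micro rates from macro estimates (λ = 0.17,
μ = 0.04, mean sister age 3.4 Myr):

```r
library(protractr)
calibrate_micro_rates(0.17, 0.04, 3.4)
#>   conversion_rate splitting_rate extirpation_rate conversion_rate_rounded
#> 1       0.1470588          1.156        0.3048935                    0.15
#>   splitting_rate_rounded extirpation_rate_rounded
#> 1                   1.13                      0.3
```

So a tropical bird species takes on average 1/χ ≈ 6.8 Myr to complete
speciation, each species lineage spawns ≈ 1.13 diverging populations per
Myr, and a per-population extirpation rate of ≈ 0.3 suffices to produce the
low macro extinction rate of 0.04, because a species only dies when *all*
its populations do.

Run the full gradient experiment (3 scenarios × 100 replicates × 6 Myr,
about 5 s):

```r
run_ldg_experiment(n_reps = 100, duration = 6, seed = 42)
#> Scenario 'tropical' (100 replicates, 6 Myr):
#>   mean species richness   49.79 +/- 4.00 (SE)
#>   mean sister distance    3.020 +/- 0.039 (SE, 1659 pairs)
#> Scenario 'temperate-1' (100 replicates, 6 Myr):
#>   mean species richness   41.33 +/- 2.83 (SE)
#>   mean sister distance    2.081 +/- 0.037 (SE, 1366 pairs)
#> Scenario 'temperate-2' (100 replicates, 6 Myr):
#>   mean species richness   32.67 +/- 2.11 (SE)
#>   mean sister distance    3.126 +/- 0.052 (SE, 1100 pairs)
#> Welch's t-tests:
#>   richness_trop_vs_temp1   t =    1.727, df =    178.5, p = 0.086
#>   distance_trop_vs_temp1   t =   17.517, df =   3020.7, p = 1.65e-65
#>   distance_temp2_vs_temp1  t =   16.482, df =   2056.3, p = 2e-57
```

Tropical conditions (slow conversion, low extirpation) yield more species
than temperate scenario 1 despite a *lower* macro speciation rate, and
temperate scenario 2 reaches temperate richness through an entirely
different mechanism (fast splitting, slow conversion) — visible only in the
sister-distance column, where its mean matches the tropical one.

Single simulations are equally accessible:

```r
g <- simulate_genealogy(pbd_params(1.16, 0.5, 0.6, duration = 6), seed = 7)
g
#> Protracted-speciation genealogy: 121 lineages (63 extant), 20 species extant, 6 Myr
#>   start: crown; conditioning: both; restarts: 3
tree <- sample_species_tree(g)     # ultrametric phylo, one tip per species
bd_ml(branching_times(tree))       # birth-death ML fit
```

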