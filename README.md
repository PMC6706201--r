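# frugidisp

Estimating animal-mediated seed dispersal distance (SDD) by five methods,
with a ground-truth synthetic-data generator for validating each one.

## The problem

The straight-line distance from a seed's source plant to its deposition site
drives seedling survival, gene flow and spatial genetic structure, but no
single field method measures it cleanly. Practice uses a family of
estimators that integrate different parts of the seed dispersal loop, and
comparisons between them within one dispersal system are rare. `frugidisp`
implements the five standard approaches on a common data model, tuned to the
biology of two Neotropical trees dispersed exclusively by tamarin monkeys
(a sparse canopy tree with large fruit crops, and a dense understory tree
foraged by trap-lining):

| Method | Principle |
|---|---|
| **OSD** | Euclidean distance between observed feeding and defecation locations |
| **GSC** | Seed coats are maternal tissue: an exact multilocus genotype match to an adult identifies the mother |
| **PAS** | Maximum-likelihood microsatellite parentage of seedlings/saplings (LOD scores, simulation-calibrated strict 95% confidence, 700 m pollen filter) |
| **CMG** | Distances between all scan-point pairs of a daily travel path whose time lag falls in the gut-passage window |
| **IBM** | Minute-by-minute energy-driven foraging simulation that deposits seeds after gut passage |

The PAS core is the single-parent log-likelihood ratio summed over loci,

    LOD = sum_l ln[ ((1 - e) T(g_o | g_c) + e P(g_o)) / P(g_o) ],

with `T` the Mendelian transition probability against a Hardy–Weinberg
background, `P` the HW genotype probability and `e` the genotyping-error
rate; assignment requires the LOD lead over the runner-up (delta) to exceed
a threshold calibrated by CERVUS-style simulation.

A synthetic-data module generates landscapes (Poisson-placed adults),
Hardy–Weinberg microsatellite genotypes with Mendelian offspring and exact
maternal seed coats, correlated-random-walk movement tracks scan-sampled
every 30 min, and dispersal events drawn from a known kernel — so every
estimator is validated by parameter recovery against a truth table.

## Worked example

Run the bundled canopy-tree demo scenario end to end (synthetic generation,
all five estimators, statistical comparison, ~30 s):

```r
library(frugidisp)
res <- run_scenario(demo_config("parkia"), "parkia_run", seed = 42)
res$report
```

```
Seed dispersal distance: method comparison
  Kruskal-Wallis: H(4) = 1434.15, p = 2.73e-309
  OSD  n =  117  mean =   230.1 m  [206.7, 254.2]
  GSC  n =  120  mean =   192.0 m  [157.6, 229.5]
  PAS  n =  149  mean =   229.7 m  [204.3, 255.9]
  CMG  n = 3255  mean =   225.3 m  [220.6, 230.1]
  IBM  n = 2988  mean =   104.5 m  [101.6, 107.4]
```

Each line is one estimator's distance sample: its size, bootstrap mean
(10,000 resamplings) and 95% percentile interval in metres. The
Kruskal–Wallis line tests whether the five methods draw from one
distribution (five methods give 4 degrees of freedom). Here the three
observation/genetics-based estimators and the movement model agree near the
generating kernel's scale, while the foraging simulation — which answers
"where would seeds go under these foraging rules", not "where did they go" —
sits lower; `res$report` also holds the pairwise Wilcoxon and
Kolmogorov–Smirnov matrices and per-method kernel-density estimates with
bootstrap envelopes. `parkia_run/` contains every table (locations,
genotypes, tracks, assignments, distances, comparison CSVs) plus a
`manifest.json` with per-stage seeds and MD5 hashes; re-running with the
same seed reproduces every file byte-identically.

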