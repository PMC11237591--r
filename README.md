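# habgen

Ecology and evolution of microbial habitat generalists and specialists from
multi-habitat amplicon surveys.

Surveys that sample several habitat types (e.g. moss, sediment, soil, tree
holes and water across a set of parks) recover thousands of zOTUs whose
habitat strategies differ radically. `habgen` is an R pipeline for asking,
from a taxon-by-sample count table with habitat/park metadata plus a
phylogeny:

1. **Who is a generalist / specialist / opportunist?** Three niche-breadth
   indices per taxon — Levins' breadth *B* = 1/Σpᵢ², Shannon breadth
   *H* = −Σpᵢ log pᵢ over habitat-use proportions, and occurrence frequency
   *F* — are compared against a permutation null of the community table; a
   taxon must fall above (below) the 95% null envelope on **all three** to
   be called a generalist (specialist). Strictness filters (top-decile
   generalists, >50-read specialists) define the sets used downstream.
2. **What assembles their communities?** Pairwise βNTI (standardised beta
   nearest-taxon distances against tip-shuffle nulls) and modified
   Raup–Crick indices on Bray–Curtis partition sample pairs into
   homogeneous/heterogeneous selection, homogenizing dispersal, dispersal
   limitation and drift (βNTI beyond ±2 → selection; else RC beyond ±0.95 →
   dispersal; else drift), with exact per-group fractions.
3. **How are they wired together?** Compositionally aware correlation
   networks via a SparCC estimator with bootstrap significance
   (|R| ≥ 0.6, p < 0.05), greedy modularity, Zi–Pi node roles and keystone
   tallies, degree-preserving rewired nulls, and stability analyses
   (50%-removal experiments, global-efficiency vulnerability,
   attack-tolerance robustness, functional complementarity and niche
   overlap of interdomain networks).
4. **Do the strategies diversify differently?** A binary-state
   speciation–extinction (BiSSE) likelihood (compiled pruning/ODE backend)
   with the two-step constrained-vs-full maximum-likelihood protocol and a
   χ² likelihood-ratio test, plus each state's diversification potential
   **DP = λ + t − μ** and the DP_s/DP_g ratio.

A first-class synthetic-data module (`synthetic_design()`,
`generate_community()`, `generate_bd_tree()`, `simulate_bisse()`,
`generate_correlated_compositions()`) plants known generalists,
specialists, spatial decay, correlation structure and diversification
regimes, so every stage is validated against ground truth. See the methods
vignette (`vignettes/habitat-generalists-specialists.Rmd`) for the models,
null-model choices and numerical conventions.

## Worked example

```r
library(habgen)

g   <- generate_community(synthetic_design(n_taxa = 150, n_parks = 4,
                                           replicates = 2, depth = 3000,
                                           seed = 21))
tab <- rarefy(filter_min_reads(g$table, 10), seed = 2)
tab
#> <community_table> 148 taxa x 40 samples, 5 habitats
#>   total reads 119,840, occupancy 65.7%

prof <- null_classify(tab, n_perm = 300, seed = 7) |> strict_filter()
dplyr::count(prof, class, class_strict)
#>   class       class_strict     n
#> 1 generalist  generalist       2
#> 2 generalist  opportunist     15
#> 3 opportunist opportunist    100
#> 4 specialist  opportunist      3
#> 5 specialist  specialist      28
```

148 of 150 planted taxa survive the 10-read filter; 17 are called
generalists (the 2 strongest make the strict top-decile set), 31
specialists (28 carry more than 50 reads and are kept as strict
specialists), and the rest are opportunists. Individual profiles carry the
three indices and their null envelopes:

```r
dplyr::select(prof, taxon, levins_b, shannon_h, occ_f, class)[c(1, 20, 40), ]
#>   taxon   levins_b shannon_h occ_f class
#> 1 zotu001     4.94    1.60   1     generalist
#> 2 zotu020     1.15    0.301  0.35  specialist
#> 3 zotu041     1.02    0.0655 0.225 specialist
```

`zotu001` uses the five habitats almost uniformly (*B* ≈ 4.94 of a maximal
5, present in every sample), while `zotu020` is confined to one habitat
(*B* ≈ 1.15). On the evolutionary side, simulating a 300-tip tree where
specialists speciate three times faster and fitting it back:

```r
s <- simulate_bisse(c(lambda_g = 1, lambda_s = 3, mu_g = 0.1, mu_s = 0.1,
                      q_gs = 0.05, q_sg = 0.05), 300, seed = 8)
f <- bisse_fit(s$tree, s$states, seed = 1)
f
#> <bisse_fit> 300 tips
#>   lambda_g 1.109  lambda_s 4.342  mu_g 0.555  mu_s 1.928
#>   q_gs 0.0617  q_sg 0.04269
#>   logLik full -124.065 vs constrained -163.951; chi2(3) = 79.771, p = 3.44e-17
#>   DP_g 0.5967  DP_s 2.476  DP_s/DP_g 4.149
```

The constrained (state-independent) model is rejected decisively and the
fitted speciation asymmetry (λ_s/λ_g ≈ 3.9) brackets the simulated 3×
difference; specialists carry the higher diversification potential, as
planted. `generics::tidy(f)` / `glance(f)` return the same numbers as
tibbles, and `autoplot(prof)`, `plot_zi_pi()`, `plot_assembly_summary()`
draw the standard figures.

The full pipeline — synthesis or file input, filters, classification,
distance decay, assembly partitioning, networks and stability, BiSSE — runs
from one configuration:

```r
man <- run_pipeline(demo_config("demo_out", seed = 1))
```

writing ~24 TSV/Newick/YAML artifacts plus a manifest of MD5 hashes;
reruns with the same configuration are byte-identical.

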