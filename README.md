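# roostnet

Social network and space-use analysis for tree-roosting bat maternity
colonies tracked by radio-telemetry.

Maternity colonies of bark- and cavity-roosting bats (the Indiana bat,
*Myotis sodalis*, is the motivating species) are fission–fusion
societies: bats switch day-roosts every few days, and colony-level
social structure can only be inferred from coincident use of shared
roosts. `roostnet` implements the analysis chain ecologists apply to
such data:

* **Two-mode networks** — bats and roosts as node sets, an unweighted
  edge for each observed bat–roost use; single-mode projections give
  the bat social network and the roost network.
* **Metric suite** — density, mean degree, Freeman and two-mode
  (star-normalised) degree centralization, Watts–Strogatz and Opsahl
  (4-path) clustering, leading-eigenvector modularity
  `Q = Σ_c (e_cc − a_c²)`, mean shortest path, and nominal
  assortativity (homophily) by age class.
* **Erdős–Rényi null models** — size-matched `G(n, p)` networks at the
  observed density, with add-one Monte Carlo permutation p-values
  `(b + 1)/(N + 1)` and the direction of difference (minimum 1/501 ≈
  0.002 at the conventional N = 500).
* **Roost-removal simulations** — random removal to 30% of roosts
  remaining (1,000 replicates per proportion, mean ± SE components)
  and targeted removal of the most degree-central roost.
* **Foraging space use** — biased-random-bridge utilization
  distributions (60 min / 50 m / 88 m segmentation defaults, plug-in
  diffusion estimate), weighted fixed-kernel colony UDs, 95% isopleth
  areas in hectares, UDOI and Bhattacharyya affinity, and the
  UDOI > 1 foraging-overlap network with its social-proximity
  congruence.
* **Synthetic colony generator** — telemetry (relocations, nightly
  fixes, emergence counts) with the fission–fusion structure the
  analyses assume, so the whole pipeline is testable without field
  data.

Everything takes and returns tibbles (networks are igraph objects),
fitted results have `tidy()`/`glance()` methods, and result objects
have `autoplot()` methods.

## Worked example

```r
library(roostnet)

col <- generate_colony(colony_config(seed = 11))
col
#> <bat_colony> 21 tagged bats, 25 roosts used, 199 relocations,
#>   1592 foraging fixes, 58 exit counts

bip <- build_bipartite(col$relocations, col$bats)
network_metrics(bip, "roost_2009")
#>   n_bats n_roosts n_edges mean_degree_roosts density clustering degree_centralization
#> 1     21       25      69               2.76   0.131      0.249                 0.293

roost_switching_stats(col$relocations)$summary
#> switch interval 2.66 +/- 1.32 days; roosts per bat 3.29 +/- 1.35

tidy(run_null_suite(bip, n_sims = 500, seed = 5))
#>   metric                observed null_mean null_sd direction p_value
#> 1 density                  0.131     0.131  0.0153 >          0.495
#> 2 clustering               0.249     0.269  0.0743 <          0.369
#> 3 degree_centralization    0.293     0.168  0.0409 >          0.006
```

The colony's roost use is no denser than random (its density is the
matching constant), but it is significantly more centralized than
size-matched random networks — the signature of a primary roost. The
full per-year analysis (networks, nulls, removal curves, telemetry
summaries, UDs and overlap, cross-year affinity) runs with:

```r
pl <- run_pipeline(
  list(colony_config(seed = 11),
       colony_config(seed = 12, start_date = "2010-06-01")),
  year_labels = c("y2009", "y2010"), seed = 5, out_dir = "report"
)
pl$cross_year   # year-to-year Bhattacharyya affinity + centroid shift
```

See `vignettes/colony-networks.Rmd` for the model details, parameter
conventions and generator calibration.

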