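# kinforage

Movement ecologists tracking social foragers — here, Egyptian fruit bats
(*Rousettus aegyptiacus*) radio-tagged around an oasis — routinely face the
same chain of questions: where did each animal forage each night, how large
were its home ranges, which pairs shared foraging sites, are the sharing
partners kin, and does seasonal food availability reshape the whole
network? kinforage implements that chain as a tested, reproducible R
pipeline, together with a synthetic-data generator that stands in for field
data and supplies ground truth for calibration.

The stages, each usable on its own:

* **Telemetry** — least-squares triangulation of simultaneous bearings,
  noon-to-noon night assignment, conversion of fixes to per-night
  site-visit tables (`triangulate()`, `assign_night()`, `assign_visits()`,
  `tracking_effort()`).
* **Home ranges** — minimum convex polygons: 95 % home range and 50 % core
  area with centre-distance peeling, areas in hectares (`mcp()`,
  `home_ranges()`, `seasonal_area_summary()`).
* **Relatedness** — maximum-likelihood pairwise relatedness from diploid
  microsatellite genotypes. For IBD-sharing probabilities
  (k<sub>0</sub>, k<sub>1</sub>, k<sub>2</sub>) on the simplex, each locus
  contributes k<sub>0</sub>P<sub>0</sub> + k<sub>1</sub>P<sub>1</sub> +
  k<sub>2</sub>P<sub>2</sub> with the classical IBD-conditional genotype-pair
  probabilities; the likelihood is maximised by grid search plus local
  refinement and r̂ = k̂<sub>1</sub>/2 + k̂<sub>2</sub>
  (`ml_relatedness()`, `pair_loglik()`, `estimate_allele_freqs()`).
* **Networks** — weighted space-sharing networks (edge when two bats used
  the same site the same night; weight = shared sites over the pair's site
  union), relatedness-filtered networks, co-roosting matrices, and the
  standard metrics: density ρ, normalized degree k, clustering
  coefficient C, weighted degree s (`build_sharing_network()`,
  `filter_by_relatedness()`, `build_coroost_matrix()`, `network_metrics()`).
* **Inference** — MR-QAP with double semi-partialling for dyadic
  regression (simultaneous row/column permutations of residualised
  predictor matrices), plus node-label permutation versions of the Welch
  t-test, Kruskal–Wallis and linear regression, all with the
  (count + 1)/(B + 1) two-sided p-value convention (`mrqap_dsp()`,
  `node_perm_ttest()`, `node_perm_kruskal()`, `node_perm_regression()`,
  `compare_r_distributions()`).
* **Simulation & orchestration** — pedigrees, Mendelian genotypes,
  seasonal landscapes and kin-biased nightly movement with ground truth
  (`sim_study()` and friends), and a config-driven pipeline that writes
  every intermediate artifact plus a JSON/Markdown report
  (`pipeline_config()`, `run_pipeline()`).

Fitted objects follow broom conventions (`tidy()`, `glance()`) and the
main result types have `autoplot()`/`plot_*()` helpers.

## A worked example

Simulate a two-season study with kin attraction switched on, recover the
winter visit table from the noisy fixes, build the sharing network and ask
whether relatedness predicts space sharing:

```r
library(kinforage)
set.seed(42)

study  <- sim_study(sim_config(n_bats = 15, n_nights = 6, gamma = 3, seed = 42))
visits <- assign_visits(study$fixes[study$fixes$season == "winter", ],
                        study$landscapes$winter)
net    <- build_sharing_network(visits)
net
#> Space-sharing network: 15 nodes, 92 edges (density 0.876)

glance(network_metrics(net))
#> # A tibble: 1 × 5
#>       n density mean_k mean_clustering mean_strength
#>   <int>   <dbl>  <dbl>           <dbl>         <dbl>
#> 1    15   0.876  0.876           0.878          2.74

rel <- ml_relatedness(study$genotypes)
K   <- relatedness_matrix(rel, rownames(net$W))
mrqap_dsp(net$W, list(relatedness = K), n_perm = 999)
#> MR-QAP (double semi-partialling), n = 15 nodes, 999 permutations
#>   model r = 0.2687 (r^2 = 0.0722)
#> # A tibble: 1 × 3
#>   term        estimate p.value
#> 1 relatedness    0.225   0.004
```

Most pairs in this 15-bat winter shared at least one site (density 0.876 —
with only a dozen food patches, co-occurrence is the norm), and the
positive, significant MR-QAP coefficient says related pairs shared
disproportionately many sites: the kin-attraction effect planted by the
generator (`gamma = 3`) is recovered by the inference stage. The same
analysis end-to-end, with reports and artifacts on disk:

```r
res <- run_pipeline(pipeline_config(sim = sim_config(seed = 1), seed = 1),
                    out_dir = "run1")
```

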