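---
title: "Methods: from telemetry and genotypes to kin-structured foraging networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from telemetry and genotypes to kin-structured foraging networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kinforage studies a simple question about frugivorous bats foraging in an
oasis landscape: do individuals share foraging sites with their kin more
than chance predicts, and how does seasonal food availability reshape that
pattern? The package turns two raw data streams — radio-telemetry location
fixes and diploid microsatellite genotypes — into dyadic matrices over the
same individuals (space sharing, genetic relatedness, co-roosting) and then
asks the dyadic question with permutation methods that respect the
non-independence of dyads.

This vignette records the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## From fixes to visits

Telemetry produces *fixes*: one located position of one bat, either an
exact sighting, a manual bearing solution, or a triangulated position.
`triangulate()` solves the classical least-squares line-intersection
problem: each bearing (station at $s_i$, azimuth $\theta_i$ clockwise from
north) defines a line with unit normal $n_i = (\cos\theta_i,
-\sin\theta_i)$, and the estimate minimises $\sum_i (n_i^\top(x - s_i))^2$.
Bearings are treated as full lines, not rays, which is the safer convention
when signal direction can be ambiguous; `rays = TRUE` restricts to forward
solutions. Two checks guard the geometry: at least two distinct stations,
and at least one pairwise line angle of `min_angle_deg` (default 5°) —
below that the normal equations are ill-conditioned and the fix is refused
rather than returned with spurious precision. Bearings must fall within one
simultaneity window (`window_s`, default 60 s; transmitters are scanned
every few minutes, so 60 s comfortably separates scan rounds).

Nights, not days, are the sampling unit for a nocturnal forager.
`assign_night()` maps every timestamp between local noon of day $d$ and
local noon of day $d+1$ to the night of day $d$, so a 03:00 fix belongs to
the previous evening's foraging bout.

`assign_visits()` converts fixes to a visit table: bat $i$ visited site $s$
on night $t$ iff at least `min_fixes_per_visit` (default 2) of its fixes
that night fall inside the site's circle. The threshold of 2 exists to
suppress visits conjured by a single spurious triangulation; it is
configurable. Sites are circles of radius 70.7 m (area ≈ 1 ha, the size of
a typical monitored fruit patch) unless other geometry is supplied.

`tracking_effort()` reports, per consecutive tracking night, the mean
number of newly visited sites per bat and the "probability of visiting a
new site", computed literally as that mean divided by the night number
$t$. The literal division is ambiguous in general use, so a
`method = "cumulative"` flag offers the alternative (mean cumulative
distinct sites over $t$); the default is the literal formula and the
ambiguity is deliberately surfaced rather than resolved silently.

## Home ranges

`mcp()` implements the standard minimum convex polygon estimator: compute
the arithmetic mean centre, keep the `floor(level/100 * n)` fixes nearest
it in a single peeling pass, and take the convex hull of what remains
(area by the shoelace formula, reported in hectares). Levels 95 (home
range) and 50 (core area) are the conventional pair. Choices worth stating:

* peeling is by distance from the mean centre, one pass, with distance
  ties resolved in favour of earlier records (so results are bit-for-bit
  reproducible when fixes are supplied in time order);
* `floor()` fixes the retained count exactly;
* the core area is simply a 50 % MCP — no kernel density estimation;
* fewer than five retained fixes is an error ("too few fixes"), and
  collinear fixes yield a zero-area polygon with a warning flag rather
  than an error, since a bat shuttling along a line is data, not a bug.

## Pairwise relatedness from microsatellites

The relatedness estimator is the maximum-likelihood IBD-coefficient method
used by classical pairwise-relatedness software. For a pair of individuals,
let $k_0, k_1, k_2$ be the probabilities of sharing 0, 1 or 2 alleles
identical by descent at a locus. Given population allele frequencies, each
locus contributes $\Pr(G_1, G_2 \mid k) = k_0 P_0 + k_1 P_1 + k_2 P_2$,
where the $P_m$ are the classical IBD-conditional joint genotype
probabilities under Hardy–Weinberg with no inbreeding (`ibd_pair_probs()`;
the package tests verify by enumeration that each conditional table sums to
one). The likelihood is maximised over the 2-simplex and the relatedness
coefficient is $r = k_1/2 + k_2$.

Numerical strategy: a coarse grid of step 0.02 over the simplex (1 326
points, evaluated as one matrix product per pair), then local grid
refinement with the step halved each round until the log-likelihood gain
drops below $10^{-6}$. This is deterministic, immune to the boundary optima
that plague unconstrained optimisers here (truly unrelated pairs sit at the
$k_0 = 1$ vertex), and fast enough for thousands of pairs. Three modelling
choices mirror common defaults: allele frequencies are estimated from the
full sample including the focal pair; there is no genotyping-error or
inbreeding model; and $k$ is constrained only to the simplex. The estimator
is boundary-biased upward for unrelated pairs ($\hat r \ge 0$), which is
why recovery checks use the median, not the mean, for unrelated pairs.

"Related pairs" for the filtered network default to $\hat r \ge 0.25$ (the
half-sib level). The threshold is a configuration knob: the field data the
analysis emulates never published a cut-off, so no claim is made that 0.25
matches any particular study.

## Space-sharing networks

Two bats share a foraging site when both have a visit record at the same
site on the same night — spatial co-occurrence as a proxy for interaction.
The edge weight divides the number of co-used sites by the number of
distinct sites either bat used (a Jaccard-style proportion; `min` and
`mean` denominators are available because "percentage of shared sites" is
genuinely underdetermined — the union is the default for being symmetric
and bounded in [0, 1]). Density $\rho$, normalized degree $k$ and the local
clustering coefficient $C$ are computed on the binary adjacency; the
weighted degree $s$ is the row sum of weights. $C$ is deliberately
unweighted, and isolated or degree-1 nodes take $C = 0$.

Co-roosting is a plain dyadic count of days two bats occupied the same day
roost, with the first record kept when a bat has several in one day.

## Permutation inference

All tests share the add-one p-value convention
$p = (\#\{|T^\ast| \ge |T|\} + 1)/(B + 1)$, two-sided throughout (the
analysis this package supports reports both positive and negative dyadic
coefficients, so one-sided tests would be presumptuous).

`mrqap_dsp()` is multiple regression across dyads with the double
semi-partialling quadratic assignment procedure: vectorise the
off-diagonal cells, fit OLS, then for each predictor residualise it on the
others, permute the residual **matrix** by simultaneous row/column (node)
permutations, refit, and compare coefficients. The permutation refit uses
the Frisch–Waugh identity (project the permuted residual matrix on the
fixed predictors, then a one-dimensional projection), which is
algebraically the full refit at a fraction of the cost. Symmetric matrices
contribute both triangles, which leaves coefficients untouched and matches
the convention of the standard network-analysis packages. For a single
predictor the reported model correlation is the signed Pearson correlation
of the two vectorised matrices; with several predictors it is the multiple
correlation.

The node-level tests (`node_perm_ttest()`, `node_perm_kruskal()`,
`node_perm_regression()`) compute the familiar observed statistics (Welch
t, tie-corrected Kruskal–Wallis H with Bonferroni pairwise rank post-hocs,
OLS slope and adjusted $r^2$) but replace the parametric reference
distribution with node-label permutations, because node metrics derived
from one network are not independent observations. Degenerate inputs are
defined rather than refused: zero-variance groups with equal means give
$t = 0$, fully tied samples give $H = 0$ with $p = 1$.

## The synthetic-data generator

No field dataset ships with the package, so `sim_study()` generates one
with the statistical structure the analysis assumes:

* **Pedigree and genotypes.** Discrete generations from unrelated
  founders; each dam mates with one random sire per litter (Poisson litter
  sizes), giving parent–offspring, full-sib, half-sib and unrelated pairs.
  Ground-truth relatedness comes from the tabular additive-relationship
  recursion. Genotypes follow Mendelian segregation over 13 unlinked loci
  with per-locus allele counts drawn uniformly from 3–10 (Dirichlet
  frequencies), matching the scale of a typical microsatellite panel.
* **Landscape regimes.** A rich season scatters 12 one-hectare fruit
  sites, carrying one to three of seven species, across a 5 × 5 km extent;
  a poor season offers just 2 date-palm sites clustered in one corner.
  Site positions are rejection-sampled to be non-overlapping so a fix can
  belong to at most one site.
* **Nightly movement.** Each night, bats in a freshly shuffled order each
  pick 1–3 sites with probability proportional to
  `availability × fidelity × exp(gamma × mean kinship with earlier
  arrivals)`. `gamma = 0` makes choice independent of kinship — the null
  used for calibration — and the fidelity boost is `1 + 9·phi` for
  previously used sites (`phi = 0.5` by default; `phi = 0` removes it).
  Sequential within-night assignment is what lets kin attraction reference
  bats already present. Fixes are Gaussian scatter (default SD 25 m)
  around chosen site centres plus one commuting fix per night; with the
  noise set to zero the recovered visit table equals the generator's
  ground truth exactly, which is the key oracle for the telemetry stage.
* **Defaults** mirror the scale of the motivating field study: ~30 bats
  per season, 8 nights per bat, 13 loci.

What the generator does **not** emulate: continuous-time movement,
autocorrelated fixes within a visit, torpor and energetics, weather,
detection failure, or genotyping error. Passing tests therefore show that
the pipeline recovers the structure this model plants — not that real
telemetry meets the model's assumptions.

## Calibration and recovery checks: problem sizes

The automated checks run at sizes chosen to balance statistical resolution
against desk-scale runtimes, and they are part of the package's contract:

* MR-QAP type-I error: 500 null datasets (20 nodes, independent node
  effects), 499 permutations each; the rejection rate at $\alpha = 0.05$
  is required to land in [0.03, 0.07]. At 5 nodes the sampled p-value is
  compared against the exhaustive 120-permutation oracle.
* QAP power: with `gamma = 3`, 100 simulated seasons of 20 bats; the
  sharing-vs-kinship QAP must reject in at least 80 % of them.
* Null centring: with `gamma = 0`, 200 simulated seasons; the
  sharing–kinship correlation must be centred on zero. The spread of that
  correlation is dominated by node-level structure (bats visiting 1–3
  sites per night induce strong row effects), so its mean absolute value
  sits near 0.05 even when the mean is within ±0.01 of zero.
* Relatedness recovery: 200 simulated parent–offspring pairs and 200
  unrelated pairs at 13 loci × 6 equifrequent alleles; mean $\hat r$ for
  parent–offspring must fall in [0.45, 0.55] and the unrelated median at
  or below 0.05, with the optimiser dominating all three simplex vertices
  for every pair.
* Seasonal contrast: 50–100 paired rich/poor-season simulations of 30
  bats; the poor season must show the smaller median MCP and the higher
  density, mean degree and mean clustering in at least 95 % of pairs.

## Known limitations

* The relatedness likelihood ignores genotyping error; with real
  microsatellite data a small error model would soften the $k_2$ estimates
  for near-identical genotypes.
* The "probability of visiting a new site" statistic implements a formula
  whose printed definition is ambiguous; both readings are available, and
  comparisons across studies should state which was used.
* The sharing-weight denominator is a convention, not a discovery; switch
  denominators via configuration before comparing weighted degrees across
  analyses.
* MR-QAP here covers linear models over dyads only — no logistic variant,
  no exponential random graph models.
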