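# netcoop

Cooperation in the Prisoner's Dilemma survives on networks because
structure lets cooperators cluster — but *which* wiring of a given set of
nodes and degrees promotes cooperation most is an open optimization
problem.  netcoop is an R package for researchers in evolutionary game
theory and theoretical biology that

* simulates the Prisoner's Dilemma game on undirected networks under three
  synchronous strategy-update rules (recolonization, Fermi, unconditional
  imitation) and estimates the *equilibrium cooperation level* of a
  structure, and
* optimizes scale-free network structures for cooperation with a
  **multilevel evolutionary algorithm** that rewires edges without ever
  changing the degree sequence, using a hierarchical **restoration list**
  memory to resist the selection errors caused by noisy fitness — plus a
  clustering-coefficient baseline optimizer for comparison.

## The model in brief

Each node plays one PD round per generation with every neighbor and
accumulates payoffs (weak dilemma: `R = 1`, `P = S = 0`, `T = 1 + r`,
default `r = 0.95`).  Under the recolonization rule, neighbor *y* takes
over site *x* with probability

```
W(x <- y) = (P_y - P_x) / (D * max(d_x, d_y))   if P_y > P_x, else 0,
```

with `D = T - S`; the occupant retains its site with probability
`prod_y (1 - W(x <- y))`.  The cooperation level of a structure is the
fraction of cooperators averaged over a post-transient window (Mode-A:
transient `N`, average `0.1 N` generations), starting from uniformly random
strategies — a noisy estimate by construction.

That noise misleads naive evolutionary search ("EA cheat"): a lucky
evaluation of a worse structure can displace a genuinely better one.  The
multilevel operator counters it by (1) re-sampling a structure every time a
local rewiring proposal is rejected, so survivors' estimates sharpen, and
(2) backing up promising solutions into per-slot pyramids from which they
can be restored when fresh estimates expose an adopted structure as worse.
All search moves (double edge swaps and edge switches) preserve every node
degree exactly.

## Worked example

Optimize a 200-node Barabási–Albert structure (mean degree ≈ 4) with the
five-level variant for 10 generations, then score initial and optimized
structures with 200 independent evaluations each:

```r
library(netcoop)
set.seed(11)
g0 <- generate_ba(200, 2)

set.seed(3)
multi_sample_evaluate(g0, 200)
#> <coop_estimate> avg=0.4920 (sum=98.3977 over num=200 samples)

res <- run_mlea(g0, variant_config("lv5", gen_max = 10, seed = 2))
res
#> <mlea_result> objective=cooperation best avg=0.8890 (num=1), 10 generations, 35896 evaluations
glance(res)
#> # A tibble: 1 × 5
#>   objective   best_avg best_num generations evaluations
#>   <chr>          <dbl>    <int>       <int>       <int>
#> 1 cooperation    0.889        1          10       35896

set.seed(4)
multi_sample_evaluate(res$best$graph, 200)
#> <coop_estimate> avg=0.5510 (sum=110.1938 over num=200 samples)
```

Reading the numbers: the initial structure sustains cooperation at 0.49;
after 10 generations (35,896 audited simulator calls) the optimized
structure — same degree sequence, rewired edges — sustains 0.55.  The
optimizer's internal `best avg` (0.89) is its running, few-sample estimate
and is optimistically biased; always judge structures by an independent
multi-sample score, as above.  `tidy(res)` returns the per-generation
trajectory and `autoplot(res)` plots it; `run_ea_cluster()` runs the
clustering-coefficient baseline; `run_distribution_study()` and
`run_comparison()` orchestrate the noise-diagnostic and multi-variant
experiments.  Thin command-line wrappers live in `inst/scripts/`
(`optimize.R`, `baseline.R`).

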