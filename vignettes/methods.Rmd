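---
title: "Methods: cooperation dynamics, noisy fitness, and the multilevel optimizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cooperation dynamics, noisy fitness, and the multilevel optimizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

netcoop asks a simple question with an awkward objective function: given a
scale-free population structure, how should its edges be rearranged — without
changing any node's degree — so that cooperation survives better in the
Prisoner's Dilemma played on it?  The objective (the equilibrium cooperation
level) can only be estimated by stochastic simulation, and that noise breaks
naive evolutionary search.  This vignette documents the model, the estimator,
the optimizer, and every design decision that was genuinely open.

## The game and its dynamics

Each node plays one Prisoner's Dilemma round with every neighbor per
generation and accumulates payoffs: cooperators earn $R$ against cooperators
and $S$ against defectors; defectors earn $T$ against cooperators and $P$
against defectors.  The package defaults to the *weak* dilemma
parameterization $R = 1$, $P = S = 0$, $T = 1 + r$ with cost-to-benefit
ratio $r = 0.95$.  Note that $P = S$ violates the strict ordering
$T > R > P > S$ of the textbook dilemma; `payoff_params()` therefore accepts
$T > R \ge P \ge S$ and uses the weak setting by default.

Three synchronous update rules are implemented (one generation = all sites
revise simultaneously from current-generation payoffs):

* **Recolonization** — site $x$ and its neighbors compete to re-occupy $x$.
  Neighbor $y$ succeeds with probability
  $W_{s_x \leftarrow s_y} = (P_y - P_x)/(D\,d_>)$ when $P_y > P_x$ (else 0),
  where $d_> = \max\{d_x, d_y\}$ and $D = T - S$; the occupant retains the
  site with probability $\prod_y (1 - W_{s_x \leftarrow s_y})$, and
  conditional on takeover a neighbor is chosen with relative probability
  $W_y / \sum W$.  The tie $P_y = P_x$ yields probability 0 — the formula
  defines only the strict branches, and 0 is its continuous limit from
  above.
* **Fermi** — each node picks one neighbor uniformly at random and adopts
  its strategy with probability $1/(1 + \exp((P_{\text{self}} -
  P_{\text{model}})/k))$, noise amplitude $k = 0.1$.  The underlying
  description of "a neighbor $y$ of $x$ is chosen" is ambiguous about
  whether roles are drawn per pair or per focal node; we resolve it as
  *every node acts once per generation as learner*, which gives each node
  exactly one revision opportunity and matches the other two rules.
* **Unconditional imitation** — each node copies the neighbor with the
  largest payoff provided that payoff strictly exceeds its own.  Ties among
  equally best neighbors are broken uniformly at random (the rule itself is
  silent; a uniform draw is the unbiased choice and only consumes
  randomness when an actual tie occurs, keeping the unique-argmax case
  deterministic).

The recolonization rule is intrinsically synchronous (all sites are
re-occupied from current-generation payoffs); we apply the same scheduler
to the other two rules so that "one generation" means the same thing under
every rule.

## Estimating the cooperation level, and why it is noisy

`evaluate_cooperation()` initializes each node as cooperator or defector
with probability 1/2, discards a transient, and averages the cooperation
frequency over a window:

* **Mode-A**: transient $N$ generations, average $0.1N$;
* **Mode-B**: transient $10N$, average $N$.

Both windows scale with the node count $N$ and are disjoint and
consecutive; generation counts are rounded up.  Homogeneous states are
absorbing under all three rules, so once reached the remaining window is
filled analytically with the constant frequency — a provably identical but
much cheaper computation.  Mode-A is the package default: the test suite
verifies on 300-node structures that the two modes' estimate distributions
agree in the mean, while Mode-B costs an order of magnitude more.

Because the initial strategies and the dynamics are random, repeated
evaluations of the *same* graph scatter — increasingly so for smaller
populations.  Averaging `n_samples` independent evaluations
(`multi_sample_evaluate()`) narrows the spread at proportional cost.  This
noise is the central obstacle: an EA comparing two structures by single
noisy evaluations will sometimes keep the worse one (a selection error
sometimes called the "EA cheat"), and the whole optimizer design below
exists to survive that.

## Degree-preserving moves

Two rewiring primitives, both exactly degree-preserving and simplicity-
preserving:

* **Double edge swap** (`simple_edge_swap()`): edges $(a,b),(c,d)$ with four
  distinct endpoints become $(a,c),(b,d)$ when neither exists.  Used to
  scatter the initial population around the input structure and as offspring
  mutation.  A retry bound of 100 guarantees termination on swap-saturated
  graphs such as complete graphs, where the operation degenerates to a
  flagged no-op.
* **Edge switch** (`node_select()` + `edge_switch()`): choose a node $u$
  (degree $\ge 2$) with two non-adjacent neighbors $i, j$ (degrees
  $\ge 2$), then edges $j\!-\!k$ and $i\!-\!m$ with all five nodes
  distinct and $k\!-\!m$ absent; remove $j\!-\!k$, $i\!-\!m$ and add
  $j\!-\!i$, $k\!-\!m$.  This is the local-search move: it closes a
  triangle at $u$ while preserving all degrees.  The constraints admit
  many sampling schemes; we sample $u$
  uniformly among qualifying nodes, the neighbor pair uniformly among
  qualifying pairs, and $k$, $m$ uniformly among qualifying incident
  edges, with failure reported (not raised) after 1000 bounded attempts —
  failure is a legitimate outcome, e.g. on star graphs.

Disconnecting moves are never adopted: the optimizer evaluates candidates
first and rejects any disconnected one, and because all operators return
new graphs rather than mutating, rejection needs no rollback.

## The restoration list

The memory is `2·GS` pyramids, pyramid $n$ serving slot $n$ of the working
population (parents first, then offspring).  Each record couples a backed-up
graph with its evaluation aggregate (`sum`, `num`, `avg = sum/num`).  Four
rules govern it:

* **insertion** — append at the bottom if a slot is vacant; otherwise evict
  the worst record among those with strictly smaller `avg` and `num` no
  larger than the candidate's (exactly one eviction); refuse if none
  qualifies.  Eviction weighs both quality and evidence: the displaced
  record must be *strictly* worse in `avg` (the quantity that defines
  priority) and backed by no more samples than the candidate ($\le$ on
  `num`, so a well-sampled record is never displaced by a lightly sampled
  one), and exactly one record is evicted because one vacancy suffices.
* **mutation** — a refused candidate with larger `avg` than the record at
  0-based level $m$ may still replace it with probability
  $\alpha^{\max - m}$; deeper (worse) records are easier to displace, and
  $\alpha = 0$ freezes the list.  When the operator's backup attempt is
  refused, levels are scanned from the bottom upward and the first
  qualifying replacement ends the scan — the bottom is where displacement
  is most probable and least destructive.
* **sort** — stable descending order by `avg`; stability makes runs
  reproducible when `avg`s tie.
* **information update** — when the working solution linked to a pyramid
  accumulates further samples, its backup's `sum`/`num` are overwritten and
  the pyramid re-sorted; the stored graph is never touched.

Pyramid geometry is one record per level (capacity = `max_levels`, level 0
on top): the only property the memory needs is that upper records take
priority over lower ones, and one record per level is the simplest shape
with that property.

Two comparison strategies mediate between noisy estimates with unequal
sampling: population ranking uses `avg` alone (strategy 1), while the
three-way verdict against a record (strategy 2) demands the strict
sandwiches `avg_cur < avg_adj < avg_rec` (restore) or
`avg_adj > avg_cur > avg_rec` (keep current) so that a record only
overrides fresh evidence when both the current and adjusted estimates sit
below it.

## The multilevel operator

For a working solution with mean `avg`, the operator resets the aggregate
to (`sum = avg`, `num = 1`) and walks every node in identifier order and
each of its incident edges in neighbor order (a deterministic iteration
under a fixed seed).  With probability $\min(1, \beta d_i / \sum d)$ — the
clamp only matters on small test graphs; at the study sizes
$\beta d_i/\sum d$ is a genuine probability — it proposes an edge switch
and evaluates the adjusted structure once:

1. *rejected* (disconnected or not better): the **current** structure is
   re-evaluated once more and its aggregate updated (synchronized to its
   backup if one is linked).  Surviving structures therefore accumulate
   samples exactly as the design principle demands: promising structures
   get re-sampled, mediocre ones do not.
2. *accepted and current `avg` above the pyramid top*: the current solution
   is backed up (insertion, then mutation rule), the pyramid sorted, and
   the adjusted structure adopted with a fresh single-sample aggregate.
3. *accepted but adjusted `avg` below the pyramid top*: the top record is
   restored as the working solution, keeping its aggregate; it is linked as
   its own backup so later re-samples synchronize.
4. otherwise: the adjusted structure is adopted with a fresh aggregate.

An exact tie `avg_adj == avg_cur` is routed to the rejection branch: a
no-information proposal should not reset the accumulated aggregate.  With a
constant evaluator the operator therefore provably never changes the graph
and strictly grows `num` — one of the unit tests.

## The EA loop

Each generation: roulette-select parents (probability proportional to
`avg`, uniform when all are zero — the degenerate all-defect case),
recombine with probability `Pc`, mutate each offspring by one accepted
double swap, evaluate, run the multilevel operator on *all* `2·GS`
solutions (parents and offspring, each against its own pyramid), and keep
the best `GS` by strategy 1 with stable ties.  The restoration list
persists across generations.

**Crossover.**  netcoop uses a degree-preserving
intersection-plus-repair recombination of its own design: keep all edges
common to both parents, fill per-node degree deficits from the shuffled
symmetric difference, pair residual stubs at random avoiding self-loops
and duplicates, and retry (20 times) until connected, else fall back to
the fitter parent.  Identical parents reproduce exactly.  `Pc` defaults to
0.8, a conventional crossover rate for small-population EAs.

**Variants.**  `lv1` (one level, $\alpha = 0$), `lv5` (five levels,
$\alpha = 0.5$), `lv10` (ten levels, $\alpha = 0.5$), and `lv1-M` (one
level, $\alpha = 0$, five-sample first evaluations).  We interpret the
multi-sampling of `lv1-M` as applying to *every* structure's first
evaluation — initial population, offspring, and edge-switch candidates.
Sampling only the six initial members would change the evaluation budget
by a rounding error; applying it everywhere roughly triples the cost,
which is precisely the trade-off this variant exists to study (the
acceptance script reports the measured ratio).  Re-samples in the
rejection branch always add one evaluation.

**Offspring count.**  A generation produces `GS` offspring, so parents and
offspring fill the `2·GS` pyramids exactly.

**Parents too.**  The operator runs on parents as well as offspring; this
doubles the operator cost per generation but lets parent pyramids keep
accumulating history.

**Baseline.**  `run_ea_cluster()` shares the identical skeleton but
optimizes the deterministic mean local clustering coefficient
(`clustering_coefficient()`, with degree-$<2$ nodes contributing 0 so the
mean is defined on every graph) with a canonical accept-if-better hill
climb, no memory and no re-sampling.  Its best-so-far trajectory is
provably non-decreasing, which the tests assert.

## Random numbers and reproducibility

All randomness — R level and C++ level — is drawn from R's single global
RNG stream; the C++ engine consumes `unif_rand()`.  A `seed` in the config
makes any run bit-reproducible, and the harness derives per-run sub-seeds
deterministically from one master seed.  We chose one stream over separate
labeled streams per component: it is simpler, and component-level isolation
is not needed by any analysis the package performs.  Unconditional
imitation draws randomness only on actual payoff ties, so its
deterministic cases consume no RNG state.

## What the generators emulate — and what they do not

`generate_ba()` grows preferential-attachment networks from an
`m_attach + 1`-clique seed; `generate_hk()` adds triad closure with
probability `p_triad` after each attachment, raising clustering at the same
degree-distribution family, and reduces exactly to BA at `p_triad = 0`.
The package defaults to `m_attach = 2` (mean degree ≈ 4, a common choice
for sparse scale-free game studies) and leaves it configurable.

These synthetic structures reproduce the degree heterogeneity and (for HK)
tunable clustering that drive network reciprocity, but not degree-degree
correlations, community structure, or the assortativity of real contact
networks — conclusions from passing tests transfer to real populations only
insofar as those features do not dominate.

## Problem sizes used by the tests and the acceptance script

The package's own verification runs at desk scale, chosen so the full
pipeline is exercised end to end in minutes: distribution contrasts on
200/300/800-node BA structures with 200 evaluations; lv5 optimization of
five 200-node BA structures for 10 generations with 200-sample post-hoc
scoring; the clustering baseline on a 200-node HK(p = 0.5) structure for
15 generations; and evaluation-count accounting on 100-node runs.  Studies
at full scale in this field typically use 500–1000-node structures, 30
(respectively 120 for the clustering baseline) generations and
thousand-sample scoring; every size above is a configuration field, so
full-scale runs are a parameter change, not a code change.

## Known limitations

* Only undirected, unweighted, single-layer graphs; no coevolutionary link
  adaptation, no asynchronous schedules, no mixed strategies.
* The crossover is one reasonable degree-preserving recombination among
  several; alternatives slot in behind the same interface.
* Post-hoc scores are themselves noisy estimates; at 200 samples the
  standard error of a score is a few times $10^{-3}$ on 200-node graphs,
  which the improvement criteria accommodate by comparing means across
  replicates.
* The evaluation-count comparison establishes the cost *ordering*
  (lv1-M ≫ lv1 ≈ lv5); absolute counts depend on the attempt probability,
  structure size and generation budget, and are reported, not targeted.
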