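---
title: "Factored exact stochastic simulation: the method behind lolcatSSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factored exact stochastic simulation: the method behind lolcatSSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lolcatSSA)
```

## The problem

Gillespie's stochastic simulation algorithm (SSA, the "direct method") is the
standard way to produce statistically exact trajectories of a well-mixed
chemical system: at each step a reaction $\mu$ is chosen with probability
$a_\mu / a_0$, where $a_j$ is the mass-action propensity of reaction $j$ and
$a_0 = \sum_j a_j$, and time advances by an exponential holding time
$\tau = \ln(1/u)/a_0$. Done naively, every step costs $O(M)$ work for $M$
reactions, and even the classical accelerations (the propensity-sorted ODM,
the heap-based next-reaction method) leave a second bottleneck untouched:
after a firing, every reaction whose reactants changed must have its
propensity refreshed. Large cellular models have *super-species* — ATP-like
hubs that appear as a reactant in a large fraction of all reactions — so a
single firing can invalidate thousands of propensities, and the
reaction-to-reaction dependency graph those methods use grows towards $M^2$
edges.

`lolcatSSA` implements the LOLCAT Method, an exact SSA whose two ideas attack
precisely these costs: propensity *factoring*, and a *bipartite* dependency
graph.

## Factoring propensities into clouds

For a set $T$ of reactions sharing a common reactant $x_T$ (the
*factor-species*), the propensity sum factors:

$$\sum_{i \in T} c_i\, x_T\, x_{o_i} \;=\; x_T \sum_{i \in T} c_i\, x_{o_i},$$

where $o_i$ is the other reactant of reaction $i$. If a subset $T_j \subset T$
additionally shares a secondary reactant $s_j$, its inner sum factors again
as $x_{s_j} S_j$ with $S_j = \sum_{i\in T_j} c_i$ — and $S_j$ is a *constant*,
because rates never change. A *cloud* stores exactly this factorization:

* a **primary tree** — a balanced k-ary cumulative-sum tree whose leaves hold
  $c_i x_{o_i}$ for the unshared members $T_0$ (root $R$);
* **sub-trees** — constant k-ary trees over the rates $c_i$ of each shared
  group $T_j$ (root $S_j$), contributing $C = \sum_j x_{s_j} S_j$;
* the cached cloud total $a_T = x_T\,(R + C)$.

The payoff is the update rules. When the factor-species count changes,
$a_T$ is rescaled in $O(1)$ — one multiplication updates the summed
propensity of *every* member reaction at once. When a secondary species
$s_j$ changes by $\delta$, $C$ moves by $\delta S_j$, again $O(1)$ no matter
how many reactions share $s_j$. Only a change to an unshared partner
requires touching a tree: one leaf is set to $c_i x_{o_i}$ and the
$O(\log_k |T_0|)$ path to the root is refreshed.

Cloud totals live as leaves of one more k-ary tree, the **main tree**, and
the very hottest reactions bypass all of this: a small **super-cache** holds
the reactions with the largest trial-run average propensity and is scanned
linearly first, with its sum $P_{sc}$ cached, so most draws finish after a
few comparisons.

Selection (Phase 1) draws $r = u_1 a_0$: scan the super-cache; on a miss,
descend the main tree with the residual to pick a cloud; divide the residual
by $x_T$ to enter the cloud's factored domain; descend the primary tree if
the rescaled residual is below $R$, otherwise step through the sub-trees
subtracting $x_{s_j} S_j$ and descend the winning sub-tree after a further
division by $x_{s_j}$. Because every division rescales an interval whose
length was multiplied by the same factor, the measure of $r$ values mapping
to each reaction is *exactly* its propensity — the method is a
reorganization of the direct method's lookup, not an approximation. The
package verifies this claim literally: `selection_breakpoints()` enumerates
the induced partition of $[0, a_0)$ and the test suite compares every
interval length against the brute-force propensity, and chi-square tests
compare $10^6$ frozen draws against $a_j/a_0$.

### Self-reactions

A reaction $A + A \rightarrow \dots$ has propensity $c\,x(x-1)/2$ under the
standard combinatorial convention, which factors as
$x_T \cdot \big(c (x_T - 1)/2\big)$: the leaf holds $c(x_T-1)/2$ and must be
*refreshed* (not just rescaled) when $x_T$ changes; the compiler emits a
dedicated self-reaction-leaf instruction for this. The convention is
configurable (`reaction_system(self_half = FALSE)` drops the divisor) since
both appear in the SSA literature; the default is the Gillespie convention.

### The omnipresent placeholder

Zero- and first-order reactions are padded with the placeholder species
`"0"`, which sits at index 1 with a frozen count of 1. This removes every
special case from the propensity algebra, the factoring code and the
compiler. Placeholder-only reactions (constant propensity) that miss the
super-cache are collected in a dedicated cloud whose factor count is the
frozen 1.

## The bipartite update graph and compiled programs

Instead of linking reactions to reactions (which creates $n^2$-edge cliques
whenever $n$ reactions share a consumed reactant), the dependency structure
is stored bipartite: each reaction points to the species whose counts it
changes with nonzero *net* delta (a catalytically regenerated species
creates no edge), and each species points to the reactions in which it is a
reactant. A reaction has at most 2 reactant memberships and affects at most
4 species, so the graph has at most $6M$ edges regardless of hub structure.

Because the work triggered by a given reaction never changes, it is compiled
once at preprocessing into a per-reaction *update program*: the net count
adjustments followed by the minimal correct structure instructions —
factor-rescale, sub-tree C-adjust, primary-leaf refresh, self-reaction-leaf
refresh, super-cache entry recomputation — deduplicated and sorted so
compilation is reproducible bit for bit. Phase 2 of every step just replays
the fired reaction's program.

## Preprocessing pipeline

1. **Trial run** — the direct-method oracle runs for `trial_steps` events
   (default $10^5$; holding-time-weighted averages; `trial_steps = 0` falls
   back to the initial propensities, and a stalled trial falls back to
   uniform weights) to estimate average propensities.
2. **Super-cache** — the top `supercache_size` reactions by average
   propensity (default 16, ties by index). The default balances linear-scan
   cost against hit rate; the per-step refresh cost is bounded by the cache
   size, so the default keeps both small.
3. **Greedy clouding** — a candidate cloud per species containing every
   eligible reaction with that species as a reactant; candidates are scored
   by summed average propensity; the best is fixed (ties: lowest species
   index), its members leave all other candidates, and the loop repeats.
   The score is computed per the stated rule — each remaining member counts
   once in each candidate containing it.
4. **Sub-tree partition** — within a cloud, members group by their
   non-factor reactant; groups of at least `subtree_threshold = 3` become
   constant sub-trees; smaller groups, placeholder partners and
   self-reactions stay primary.
5. **Graph + compiler** — bipartite update graph, then update programs.

## Numerical design

These choices keep a week-long incremental computation equal to its
from-scratch recomputation to near machine precision (`check_consistency()`
reports the maximum deviation, relative to the exact value and floored at
magnitude 1):

* **Path updates recompute, not accumulate.** Setting a leaf refreshes each
  ancestor as the in-order sum of its $k$ children instead of adding a
  delta. Incremental deltas perform a floating-point random walk that, after
  $10^5$ updates at magnitude $10^7$, leaves absolute residue around
  $10^{-7}$ — fatal once a drained structure's true value approaches zero.
  Child-sum refreshes leave every node a freshly rounded sum at all times;
  observed deviations stay below $10^{-15}$ at the $2000$-reaction scale.
* **$C$ uses compensated addition.** The $O(1)$ C-adjust is a Kahan add, so
  its error is bounded by a few ulp instead of growing with the update
  count, and the O(1) cost contract is kept.
* **$P_{sc}$ is resummed exactly** after every program execution (the cache
  is at most `supercache_size` entries, so this is constant work).
* **Half-open intervals everywhere.** `locate()` selects leaf $i$ iff
  $\sum_{j<i} w_j \le r < \sum_{j\le i} w_j$; zero-weight leaves (including
  the zero-padded dummies of the fixed-capacity last level) are never
  selected, and a coordinate equal to a boundary selects the next leaf, so
  ties cannot occur.
* **Right-edge clamps.** A coordinate that rounds onto a structure's total
  weight is clamped just inside the rightmost positive child; these events
  have measure zero and cannot bias the selection law.
* **Safety recompute.** All caches are rebuilt from the bare state every
  `recompute_every` steps (default $10^6$) and at every recording
  checkpoint; with the drift-free updates above this is belt-and-braces, not
  a correctness requirement.
* **RNG discipline.** Exactly two uniforms per step — selection first, then
  holding time — drawn from R's seeded generator, so (system, seed, config)
  determines the trajectory bit for bit. $u = 0$ cannot occur in R's
  `runif`, so $\tau$ is finite; extinction ($a_0 = 0$) halts the run cleanly
  and, under a time-limited run, freezes the recorded state through the
  rest of the grid.
* **Counts are doubles** holding exact integers (safe to $2^{53}$, far
  beyond any molecule count here, and free of 32-bit overflow).

The branching factor `k` defaults to 4 for all trees: descents then cost at
most 4 comparisons per level at half the height of a binary tree, a good
trade on modern hardware; the exactness contract is independent of `k`, and
the test suite exercises $k \in \{2, 4, 8, 16\}$.

## Recording and comparison semantics

Trajectories are recorded sample-and-hold on a fixed time grid (the state at
$t$ is the state after all events at times $\le t$), which matches how
steady-state statistics are computed and keeps output size independent of
event count; per-event data are available through the event counters. The
factored engine and the direct-method oracle are compared
*distributionally* — time-averaged means, Fano factors, transient means at
matched sample sizes — never path-wise, because the two data layouts map the
same uniform variate to different reactions.

Two baselines are included for counted-complexity comparisons (never
wall-clock): the textbook direct method, and an ODM baseline with a
propensity-sorted array using either the clique-forming reaction graph or
the bipartite graph (the MODM variant). Operation counters tally cloud
structure updates, super-cache refreshes, tree-node writes and scan
comparisons per step. In the separation experiments the factored engine's
cloud-update count stays below 8 per step while the clique-UDG baseline's
propensity-update count tracks the hub fan-out (three orders of magnitude at
fan-out 1000).

## What the synthetic generator emulates — and what it does not

`generate_hub_network()` reproduces the two structural observations the
method exploits: a small set of hub species participating as reactants in a
controllable fraction of reactions (default 90%), and heavy-tailed
propensities (log-uniform rates over $[10^{-2}, 10^2]$, hub counts of 1000
against 0–100 for others). Hub-consuming reactions convert the consumed hub
into a *different* hub — an ATP→ADP-style cycle — so hub counts change on
almost every firing (the regime factoring accelerates) while the hub pool is
conserved; all other slots shuffle tokens among the non-hubs, and species
are patched to appear as reactants where capacity allows. The result is a
closed, mass-conserving system that sustains $10^5$-step runs without
reaching an absorbing state, which plain uniform product assignment does
not: draining hubs deadlock a random closed network within a few thousand
events. A tenth of the reactions are made literally catalytic (first
reactant reappears as product) to exercise the net-delta rule.

What it does *not* emulate: real pathway topology (modules, cascades,
conservation relations beyond total mass), bursty regulation, or realistic
rate distributions. Passing the acceptance suite therefore demonstrates
exactness, consistency and the claimed complexity behaviour on networks with
the right *statistical shape*, not biological fidelity of any particular
model.

The canonical models (`canonical_model()`) supply closed-form oracles:
immigration–death (stationary Poisson, mean = variance = 10), exponential
decay ($\mathbb{E}x(1) = 1000e^{-1} \approx 367.88$), symmetric
isomerization, dimerization (parity invariant), and an enzyme toy whose
shared enzyme exercises clouds.

## Problem sizes in the shipped tests

The consistency stress test runs $10^5$ factored steps on a 2000-reaction,
250-species, two-hub network (the scale of the smallest published cascade
benchmark); selection exactness uses 100 random systems of up to 50
reactions across all four branching factors; the frozen-draw chi-square uses
20 structures at $10^6$ draws each; the stationary oracle runs to
$t = 1000\,$s with a 0.1 s grid, discarding $t < 10$; the decay oracle uses
200 replicates per engine; edge-count sweeps reach $10^4$ reactions. These
sizes were chosen to exercise every structure at depth while keeping the
whole suite comfortably desk-scale.

## Known limitations

* The engine is pure R. The per-step *operation counts* match the method's
  complexity claims, but absolute speed does not compete with compiled
  implementations; the package's purpose is a fully testable, exact
  reference implementation with observable internals.
* Constant volume, constant rates, mass-action kinetics only; at most two
  reactants and two products per reaction (decompose larger reactions
  upstream). The SBML ingest accepts only irreversible mass-action models
  in a narrow canonical form.
* Cloud membership, the super-cache and the sorted ODM array are fixed at
  preprocessing; none re-adapt as propensities drift during a run.
* The clique-forming graph is materialized only for baseline runs and small
  comparisons; its edge *count* is computed without materialization for
  large sweeps.
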