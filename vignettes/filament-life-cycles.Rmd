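---
title: "Information-driven fragmentation of filamentous life cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-driven fragmentation of filamentous life cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filafrag)
```

## The model

`filafrag` simulates the simplest multicellular body plan: a
one-dimensional filament of cells, as in filamentous cyanobacteria. Cells
reproduce by binary fission and stay attached, so a filament grows
exponentially; it reproduces when one or more cell–cell connections are
severed. The scientific question the package addresses is how much
*intrinsic* information — cues generated by routine cellular activity, with
no environmental signal — can regulate two traits of such a life cycle:
the **adult size** (cells in the filament just before it fragments) and
the **reproduction mode** (the multiset of offspring sizes).

Every simulation starts from a single age-0 cell. Time advances in fixed
steps of `dt = 0.01`. Each cell's time to its next division is drawn from
a normal distribution with mean 1 and standard deviation 0.05, truncated
below at `dt` by resampling (draws that small occur with probability
~1e-89, so the truncation is inert but defined). A division replaces the
parent by two adjacent daughters: each daughter keeps the parent's outer
pole, the two facing poles are new at age 0, the connection between the
daughters starts at age 0, and the parent's compound is split equally.
After every fragmentation the simulation follows the largest viable
offspring (ties broken uniformly at random) and stops after a fixed number
of logged fragmentation events (default 100 per run).

### The information sources

Four deterministic cues, each thresholded by a parameter `theta` in the
cue's own units, plus two stochastic baselines:

* **Cell age** `a_i` — the mean of the two pole ages (binary fission
  leaves no single birth time, so pole age is the standard proxy). A cell
  with `a_i > theta` breaks its *older* adjacent connection. Terminal
  cells are the oldest, so this rule mostly sheds unicellular propagules.
* **Connection age** `c_j` — any connection with `c_j > theta` breaks.
  Near-synchronous divisions keep the oldest connection near the
  midpoint, so this rule produces equal binary splits.
* **Diffusible compound** `d_i` — every cell produces 1 unit per step;
  the compound exchanges between neighbours with a per-step fraction
  `D = 0.01` and drains across free ends into a zero-concentration
  environment. A cell with `d_i > theta` breaks the connection toward its
  higher-concentration neighbour (a terminal cell breaks its only
  connection).
* **Mechanical stress** `s_i = min(n_left, n_right)` — the smaller of the
  cell counts on the two sides, maximal at the midpoint. A cell with
  `s_i > theta` breaks the connection on its more populated side, so
  fragmentation is pinned to the centre and the adult size is a
  deterministic function of `theta` (the first size `N` with
  `floor((N-1)/2) > theta`).
* **Stochastic at division** — each connection created by a division
  breaks with probability `theta`, once, at creation.
* **Stochastic in time** — every connection breaks independently with
  probability `theta` at every step.

All triggers that fire in the same step belong to one fragmentation
event; that is the only way events with more than two offspring arise.
Exact ties in a severing policy (equal adjacent connection ages, equal
neighbour concentrations, a cell exactly at the midpoint) are resolved by
a fair coin; with continuous-valued ages such ties essentially occur only
for the stress rule's midpoint.

### Update order within a step

Each step applies, in order: (1) all pole and connection ages advance by
`dt`; (2) compound production and diffusion; (3) divisions whose scheduled
time has passed, processed left to right; (4) rule evaluation on the fresh
state; (5) fragment bookkeeping. One ordering decision matters enough to
call out: the stress cue and the at-division stochastic cue can only
*newly* fire when a division changes the filament, so they are evaluated
after **every single division** rather than once at the end of the step,
and a firing ends that step's division processing (the remaining due cells
divide in the next step, 0.01 time units later). With near-synchronous
division times, two divisions regularly fall in the same step; evaluating
only at step end would let a 32-cell filament jump to 34 cells before the
stress rule could react, giving it a spurious two-point adult-size
distribution. Per-division evaluation restores the exact determinism this
cue is capable of, and means an at-division break is resolved before a
second one can accumulate — which is why those two rules never produce
more than two offspring. The time-driven cues (ages, compound, per-step
stochastic, Boolean combinations) cannot be triggered by a division
(daughters are younger, have half the compound, and add an age-0
connection), so they keep the end-of-step evaluation.

### Diffusion scheme

The compound update is explicit Euler on the chain with unit cell spacing
and absorbing boundaries: with pre-update amounts `d`, cell `i` receives
`production + D * (d[i-1] + d[i+1] - 2 d[i])`, where out-of-range
neighbours count as 0, so a terminal cell loses `D * d_i` across its free
end. The scheme is stable and sign-preserving for `D <= 0.5`; per step the
total compound changes by exactly `N * production - D * (d_first +
d_last)`, which the tests verify against an independently summed flux
computation. "1 per time step" is read literally as one unit per
simulation step; because the whole compound field is linear in the
production rate, this choice only sets the scale of `theta` and is
absorbed by calibration. The per-step exchange fraction `D` is *not*
absorbed: it is the one shape parameter of the compound profile, and the
reproduction-mode mix of the compound rule is sensitive to it. The package
keeps the published default (`D = 0.01` per step) and exposes it as an
argument so users can probe that sensitivity with `simulate_batch()`.

### Death and aging variants

With `death = TRUE`, fragmentation acts by cell death: the triggering cell
(for cell-level cues) or a coin-chosen cell flanking each broken
connection (for connection-level cues) is removed and its connections
severed. An event whose only viable product is the filament minus a dead
end cell is a *shedding*, not a reproduction: it is excluded from the
event log and the event counter by default (`count_shedding` flips this),
because a dead singleton is not a viable offspring. This is why death
suppresses the unicellular-propagule mode: the oldest cells are the end
cells, and removing them sheds biomass without reproducing.

With `aging = TRUE`, a daughter's division interval is its normal draw
plus its current age (mean pole age at birth), so old cells divide ever
more slowly. Interior cells keep both poles young and settle near a fixed
point (age at division ≈ 2), while terminal lineages stagnate; the net
effect is strong desynchronisation of division timing. Thresholds for a
variant are calibrated *under that variant's dynamics*, since a variant
changes the mapping from threshold to adult size.

## Classification and combinatorics

Each event is classified from its parent size and viable offspring sizes,
in precedence order: complete dissociation (all singletons), unicellular
propagule (at least one singleton and one multicellular offspring), equal
binary split (exactly two offspring, each within the inclusive 40–60%
band of the parent), unequal binary split (any other two-offspring event),
and other. The precedence makes (1, 1) from a two-cell parent a
dissociation and (1, n−1) a propagule. `count_partitions(n, min_parts)`
puts these observations in context: a 10-cell group can allocate its
cells to offspring in 42 distinct ways, and a 32-cell adult has 8348
allocations into two or more groups, yet the simulated rules realise only
a handful of them. The two conventions (counting or not counting the
single-group partition) differ by exactly one and are both exposed
through `min_parts`.

## Calibration

`calibrate_threshold()` finds, for each rule, the threshold whose **mean
adult size** matches a target (default 32 cells): a coarse grid pass
followed by one refinement pass around the optimum, minimising
`(mean - target)^2` with ties to the smaller threshold. Matching the mean
— rather than minimising the full per-size mean squared error, which is
also recorded for every candidate — is what makes rules with wildly
different variances comparable at a common average adult size; a full-MSE
objective would park high-variance rules well below the target because
the variance term grows steeply with the threshold. Every candidate is
scored on a batch generated from the same master seed (common random
numbers), so the comparison is paired and reproducible; a candidate whose
rule never fires within the cell/step guards scores infinity. The default
grids per cue bracket thresholds spanning mean adult sizes from a few
cells to far past the target: linear grids for the age cues and the
compound, the integer range 1–30 for stress, and logarithmic grids for
the two probabilities.

`grid_scan()` applies the same machinery to Boolean combinations of two
cues (AND: one cell must satisfy both thresholds, severing by the first
rule's policy; OR: either rule fires, the first rule's policy winning
when both fire on one cell), recording the signed deviation of the mean
adult size and the L2 error per grid cell. AND is more restrictive, so it
tends to overshoot the target size; OR is more permissive and
undershoots. Threshold pairs that can never fire are reported as missing
rather than silently skipped. AND is restricted to cell-level cues
(cell age, compound, stress) because its per-cell semantics are undefined
for a connection-level cue; OR, which is a union of decisions, accepts
any pair of deterministic cues. The death variant is not combined with
Boolean rules.

## What the simulations do and do not emulate

The engine *is* the study system: there is no external data, and the
generator's defaults (step 0.01; division intervals N(1, 0.05) with 0.05
read as the standard deviation; production 1 per step; D = 0.01; 100
events per run; target adult size 32) are the study conditions. The
standard-deviation reading of N(1, 0.05) matters: a variance reading
(sd ≈ 0.22) desynchronises divisions so strongly that the connection-age
rule loses its near-deterministic adult size, contradicting the
near-synchrony the model's headline contrasts rest on. What the model
deliberately omits: 2-D/3-D geometries and budding topologies, cell
motility, nutrient limitation, compound degradation or active transport,
population-level competition between filaments, and evolving thresholds.
Passing tests therefore say nothing about real organisms beyond this
idealised information-flow question.

## Numerical and design choices

* Internal indexing is 0-based in the compiled engine; every reported
  position (cells, connections) is 1-based from the left end.
* Division replaces the parent in place, left daughter first. The model
  is left/right symmetric; mirroring a filament mirrors every update and
  decision (tie coins aside), which the tests check.
* Divisions are detected at the first step boundary at or after the
  scheduled time; sub-step timing is not interpolated.
* The division-time draw is truncated below at `dt` by resampling; the
  aging increment is added after truncation, so an aged cell's interval
  is always at least its age plus `dt`.
* Fragmentation events are applied simultaneously: all marked connections
  and cells in one step form one event. Parent size is the size just
  before severing, including any cell about to die.
* If every cell dies in one event (possible only under death variants on
  tiny filaments), the run restarts from a fresh age-0 founder and the
  extinction is counted in `n_extinct`.
* Unreachable thresholds are caught by two guards (`max_cells`, default
  4096, and `max_steps`) that raise informative errors; calibration
  treats such candidates as infinitely bad rather than failing.
* The engine is compiled (Rcpp) for speed but draws all randomness from
  R's RNG; `backend = "r"` runs a pure-R reference loop composed from the
  exported building blocks, and the test suite asserts the two produce
  bit-identical event logs under shared seeds.
* All randomness in a batch flows from one master seed via
  `sample.int()`-derived child seeds, so every table the package writes
  is reproducible from the seed recorded in its config snapshot.

## Problem sizes

The packaged defaults favour desk-scale runs: calibration scores 2,000
events per candidate threshold, summary batches use 10,000 events (100
runs of 100 events), and threshold scans default to 2,000 events per grid
cell. These sizes put the sampling error of a mode frequency near half a
percentage point, comparable to the printed precision of the quantities
the acceptance script recomputes; all of them scale up by changing one
argument.

## Known limitations

* The compound rule's mode mix depends on the per-step exchange fraction
  `D`, which the model treats as a primitive per-step quantity; mapping
  it onto a physical diffusivity would require committing to a cell
  length and a continuous-time limit the model does not define.
* For the stochastic-in-time rule, multi-offspring events require two
  break draws to land in the same `dt` window, so their share per event
  is approximately `(N - 1) * theta / 2` at adult size `N`; with the
  threshold calibrated to a mean adult size of 32 under `dt = 0.01`,
  that share is bounded near one percent — an intrinsic coupling between
  step size, threshold, and simultaneity for this rule.
* A stochastic rule calibrated to a mean adult size of 32 occasionally
  breaks a two-cell filament into two singletons (a complete
  dissociation), because every run is seeded from a single founder cell
  whose first connection is as breakable as any other.
* Aging interacts with the connection-age rule very nonlinearly: small
  threshold changes move the system between near-deterministic equal
  splits and strongly desynchronised unequal splits, so any single
  reported mode frequency for that variant is extremely sensitive to the
  calibrated threshold.
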