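---
title: "Graph-based Cellular Potts modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based Cellular Potts modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphcpm)
```

# The model

A Cellular Potts Model (CPM) discretizes tissue onto an integer lattice:
sites sharing a positive integer id form one cell, id 0 is medium. Dynamics
are stochastic id-copy updates scored by an energy

$$H \;=\; \sum_{\langle i,j\rangle} J_{\tau(\sigma_i)\,\tau(\sigma_j)}
\bigl(1-\delta_{\sigma_i \sigma_j}\bigr)
\;+\; \sum_c \lambda_v \,(v_c - V_c)^2
\;+\; \sum_c \lambda_p \,(p_c - P_c)^2
\;+\; H_{\text{act}} + H_{\text{chem}},$$

where the adhesion sum runs over *interaction-order* neighbor pairs, $\tau$
maps a cell id to its type (medium = type 0), $v_c$ and $p_c$ are the cell's
site count and heterotypic boundary edge count, and $V_c$, $P_c$ their
targets. A proposed flip copies a neighbor's id onto one site; it is accepted
with the Boltzmann probability $\min(1, e^{-\Delta H/T})$. One Monte Carlo
step (MCS) is `flips_per_mcs` attempts, by convention one per lattice site.

`graphcpm` stores the lattice as an undirected graph with **two adjacency
structures**: the *connectivity* order defines what a contiguous cell is
(default von Neumann, 4/6 neighbors), the *interaction* order defines which
pairs enter the adhesion and perimeter sums (default Moore, 8/26 neighbors).
Keeping them separate reflects common CPM practice — contiguity should be
strict while contact energies integrate over the wider neighborhood — and
each is independently configurable because published CPM variants differ
here. Periodic boundaries are ordinary edges joining opposite faces, and a
binary mask yields an arbitrary domain; every algorithm downstream sees only
a graph and is therefore geometry-agnostic.

## Proposal kernel

Proposals sample a uniformly random connectivity edge whose endpoints carry
different ids (direction uniform). Compared to sampling uniform lattice
sites, this concentrates work where updates are possible and makes the
uniformity of the kernel directly testable; it also means effective dynamics
per MCS do not slow down when most of the lattice is empty medium. This is a
kernel choice, not an approximation: acceptance statistics are tested against
the Boltzmann rule as specified.

## The fragmentation guard

Plain CPM dynamics notoriously let cells pinch off disconnected fragments;
lowering the temperature merely makes this rarer. Because cells are
subgraphs, the simulator instead refuses any flip that would disconnect the
losing cell:

1. **Local fast path.** Only the flipped site's neighborhood is examined. If
   the site has one same-cell connectivity neighbor it is a leaf (safe). If
   all of its same-cell connectivity neighbors are joined to one another
   through same-cell sites of the surrounding interaction ring, any path
   through the site reroutes locally (safe). A cell's last site is unsafe by
   decree — cells cannot vanish through flips, only through explicit death.
   Anything else is *inconclusive*.
2. **Exact fallback.** On inconclusive patterns, a breadth-first search over
   the cell's remaining sites decides connectivity exactly.

The fast path is sound by construction (it claims "safe" only when a local
rerouting exists), and the suite verifies it exhaustively against an
independent connectivity oracle over all 256 neighborhood occupancy patterns
(restricted to connected cells, the only states the dynamics can reach) plus
a thousand random blob shapes. Guard vetoes count as rejections whatever the
energy change; consequently the sampler is not exactly Boltzmann on the
constrained set (no reverse-move correction is attempted), which is the
standard trade-off for hard connectivity constraints. The guarantee — no cell
ever fragments, at any temperature — is audited during long runs at
temperatures spanning two orders of magnitude.

## Division as graph bipartition

A dividing cell's induced subgraph is split into two connected parts of
near-equal size: two far-apart seeds are found by a BFS double sweep, the
parts grow by alternating breadth-first accretion (the smaller part grows
first; a stuck part yields), and a refinement pass moves boundary sites from
the larger to the smaller part when the donor stays connected, preferring
moves that shrink the cut. If the gap still exceeds `max(1, 5%)` of the cell,
restarts with randomized seeds and growth order follow, and finally a random
spanning-tree-cut search: every connected bipartition of a graph equals some
spanning tree minus one edge, so tree cuts explore the entire space of valid
partitions and converge toward the attainable optimum.

A genuine limitation surfaced by this search: very thin, dendritic cells can
be trees (or nearly so), and a tree's connected bipartitions are exactly its
single-edge cuts — for some trees *no* split balances within `max(1, 5%)`.
For such shapes the partitioner returns the most balanced connected split
that exists (typically 2–4 sites off on 20–60-site cells). Daughter 1 keeps
the parent id; daughter 2 gets a fresh id and a table row inheriting type and
targets (unhalved by default, so a growing population keeps uniform cell
sizes; `halve_targets = TRUE` switches this). Each conserved custom property
$x$ splits as $f x$ and $x - f x$ with $f \sim U(0,1)$ drawn per property —
the second share is computed by subtraction so the total is conserved
exactly in floating point.

## Intracellular dynamics and events

Each cell may carry an ODE state advanced between MCS by `deSolve::lsodar`
(adaptive step-size control with root-finding). One MCS corresponds to
`mcs_duration` continuous time units (default 1). An event is a component
crossing a threshold in a stated direction; at the located root the action
fires — division with componentwise random apportioning of conserved
components, or death — the set of state vectors changes, and integration
resumes. Events whose condition already holds at an interval's start (e.g. a
division deferred because the cell was a single site) fire immediately, so
the grid and ODE layers never desynchronize. Default tolerances are
`rtol = 1e-8`, `atol = 1e-10`, chosen so located event times are accurate to
about $10^{-6}$ time units; both are configurable per model.

The demonstration model uses $dX/dt = \alpha X$ with $X(0) \sim U(0, 0.5)$
per founder and division at $X \ge 1$: exponential accumulation plus random
inheritance reproduces the asynchronous division staircase. The default
$\alpha = 0.05$ per MCS spaces division rounds $\ln 2/\alpha \approx 14$ MCS
apart — resolvable rounds, and a population that stays well below confluence
over a few hundred MCS (being exponential, it will crowd the grid eventually;
the dynamics remain well-defined, cells just compress below target).

## Recording and reproducibility

Histories store one full initial snapshot, per-MCS accepted flips
`(site, old id, new id)`, event records sufficient to replay table changes,
and optional periodic checkpoints (default every 100 MCS — a pure
speed/size trade-off for reconstruction). Replaying from the nearest
checkpoint reproduces any past grid and cell table bit-exactly; storage is
linear in accepted flips, so quiescent simulations cost a small fraction of
per-MCS snapshots (high-churn regimes — small cells at high temperature under
the boundary kernel — can approach snapshot cost; the advantage is regime
dependent). Histories and full model specifications serialize to versioned
single-file JSON containers; configurations are YAML with blocks `space`,
`cells`, `penalties`, `engine`, `ode`, `division`, `recording`. All
randomness — placement, sweeps, splits, ODE initial conditions — flows from
one seed through R's RNG (the compiled sweep draws from the same stream), so
`(configuration, seed)` fully determines a trajectory across the R and C++
paths.

# Fixtures: what the built-in models emulate

**Cell sorting** (`make_cell_sorting_model`): 50×50 periodic grid, 20 cells
per type at target volume 25, $T = 20$, $\lambda_v = 5$, contact energies
homotypic 4, heterotypic 11, cell–medium 8 — a documented differential-
adhesion regime. Cells start as a dense central aggregate with types assigned
to block positions *at random*: the heterotypic interface then starts at the
random-mixing level, which is the right baseline for both directions of the
test — under differential adhesion it collapses severalfold, while under a
type-symmetric control ($J$ heterotypic = homotypic) the types stay mixed and
the interface does not systematically shrink (it typically grows as
interfaces roughen). A deterministic checkerboard start would be *more* mixed
than random, so even neutral dynamics would relax it downward and the control
would be uninformative; random scatter, conversely, starts nearly unmixed and
cannot demonstrate sorting at all.

**Growing population** (`make_growing_population_model`): one founder type
under adhesion + volume penalties with the exponential protein model above.

**Random blobs** (`make_random_blob`): connected shapes grown by uniform
random accretion of boundary sites (Eden-type growth), which at 20–60 sites
yields irregular and frequently concave shapes — the stress cases for the
guard and the partitioner.

What passing tests on these fixtures show — and don't. They exercise the
algorithms on synthetic lattices with known energies and analytic ODEs; they
demonstrate algorithmic correctness (exact incremental energies, guaranteed
connectivity, conservation laws, bit-exact replay) and qualitative emergent
behavior (sorting, division staircases). They do not calibrate any parameter
against measured tissue, attach physical units, or model real-image domains
beyond binary masks.

# Numerical and design notes

* Incremental statistics (volumes, perimeters) are updated per accepted flip
  and audited against from-scratch recomputation; the two must agree exactly.
* Energy changes are computed locally from the flipped site's interaction
  neighborhood; the suite checks them against full-Hamiltonian recomputation
  to $10^{-9}$ on random states (adhesion, volume, perimeter) and against the
  defining local forms for migration and chemotaxis, whose standard CPM
  formulations (activity-memory geometric means; linear concentration
  difference applied to extensions) are adopted since only the behaviors,
  not formulas, are prescribed.
* Initial placement puts each cell down as the most-square block of exactly
  its target volume (anchored or rejection-sampled with a bounded retry
  budget, default 10,000), making $t = 0$ states deterministic given a seed.
* Medium has no table row and no targets; penalties treat type index 0
  specially. The volume/perimeter terms skip it, and the chemotaxis term
  applies to the gaining cell only (retractions are neutral), so a positive
  weight moves cells up-gradient.
* Degenerate inputs are rejected with typed conditions: dimensions outside
  2–3, periodic axes shorter than 2, empty masks, overlapping anchored
  cells, overcrowded domains, non-positive temperature, single-site
  division, unknown ids, type indices outside $J$, missing perimeter
  targets, malformed or version-mismatched files.
* The interpreted penalty/step path (used for user-defined penalties via the
  pure-`delta` + `after_accept` contract) and the compiled sweep implement
  the same contracts and are cross-audited; runs mixing custom penalties
  simply take the interpreted path.

## Problem sizes in the test suite

The suite runs the full study conditions: 1,000 random proposals per penalty
against brute-force energies; 10,000 acceptance trials at $\Delta H = T$;
three 1,000-MCS runs on 50×50 grids at $T \in \{10, 100, 1000\}$ audited
every 10 MCS; 256 exhaustive guard patterns plus 1,000 random blobs; 100
division blobs of 20–60 sites; 1,000 division apportionings; 20 random
reconstruction points against truncated reruns; five 2,000-MCS sorting runs
and five neutral controls; and a 1,000-MCS homeostasis run tracking every
cell's time-averaged volume. The whole suite completes in a few minutes on
one CPU.

# Known limitations

* Detailed balance is not exact under the connectivity constraint (guard
  vetoes are unidirectional); equilibrium statistics inherit a small bias
  common to all hard-constrained CPM samplers.
* The chemotaxis field is supplied per node and static; no
  reaction–diffusion solver is included.
* Balanced division is impossible for some tree-shaped cells (see above);
  the partitioner then returns the best existing split rather than failing.
* Hexagonal lattices, off-lattice space, dynamically growing domains, cell
  polarity, and oriented division are out of scope.
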