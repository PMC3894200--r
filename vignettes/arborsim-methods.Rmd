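---
title: "Growing cortical networks from stochastic neurite outgrowth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing cortical networks from stochastic neurite outgrowth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborsim)
```

`arborsim` grows three-dimensional networks of model cortical layer 2/3
pyramidal neurons, forms candidate synapses purely from the geometry of
crossing axonal and dendritic branches (Peters' rule), and quantifies the
emergent synapse distributions and neuron-level connectivity. This vignette
explains the models, the tunable parameters and their defaults, the design
choices made where the underlying literature is silent, and what the
simulated world does and does not establish.

## The outgrowth model

Each neurite arbor develops independently from a growth cone — the motile tip
agent — under two stochastic processes evaluated every time step
$\Delta t$ (default 200 s) over a developmental period of 18 simulated days.

**Branching.** A terminal segment $j$ with centrifugal order $\gamma_j$ in a
tree with $n(t)$ tips branches during $[t, t+\Delta t)$ with probability

$$p_j(t) = n(t)^{-E}\; C(t)\, 2^{-S\gamma_j}\; B_\infty
  \left[e^{-t/\tau} - e^{-(t+\Delta t)/\tau}\right], \qquad
  C(t) = \frac{n(t)}{\sum_i 2^{-S\gamma_i}},$$

the discrete-bin integral of an exponentially decaying baseline branching
rate. $B_\infty$ is the asymptotic expected number of branching events at a
tip for $E=0$ (the bin terms telescope to $B_\infty(1-e^{-T/\tau})$), $E$
modulates competition among tips, $S$ the order dependence, and $C(t)$
normalizes the order weighting so it redistributes — but does not change —
the tree's total branching rate. Probabilities are clamped to $[0,1]$ with a
warning, which only matters for parameter regimes far outside the defaults.
A branch event replaces the tip by two daughters of order $\gamma_j + 1$.

**Elongation.** Every new growth cone draws a fixed elongation rate from a
Gaussian with mean `eri_mn` and SD `eri_sd` (µm/s), which it keeps until it
branches. Negative draws are handled by *resampling*, i.e. the rate follows
a zero-truncated normal. This is a deliberate choice: for the axonal
parameter set the truncation is heavy, and the mean root-to-tip path length
equals (mean rate) × (total time) exactly, so the truncated-normal mean
(≈4.09e-4 µm/s, giving ≈636 µm) reproduces the reference axonal path length
of ≈618 µm, whereas clipping negatives to zero would give ≈448 µm.

**Turning.** Between branch events a neurite is discretized into
piecewise-linear elements: after every `turn_step_length` (default 5 µm) of
grown length the current piece is frozen and the direction receives an
isotropic Gaussian perturbation with per-component SD `turn_angle_sd`
(default 8°). Daughter directions at a branch event are symmetric about the
parent direction in a random plane, separated by an angle drawn from
N(72°, 20°). **These three knobs are not constrained by the reference
literature** (the original simulator's direction model is published without
numerical values); they are free parameters of this package, set once to
values a morphologist would call realistic, and all statistics that depend
on them should be read as shape-level, not point-level, reproductions (see
*Known limitations*).

Default parameter tables for the five arbor types (axon, basal dendrite,
apical main stem / tuft / obliques) are built into
`growth_params()` / `default_growth_params()`.

## The apical dendrite

The apical arbor is composite: an unbranched main stem (trunk) of length
drawn from N(80, 2) µm grown at the stem elongation rate; oblique subtrees
(count uniform on 2–5, a free choice — the literature gives none) attached
at uniform positions along the trunk; and a tuft grown from the trunk's
distal end. Each sub-unit runs on a local clock that starts when the trunk
reaches its attachment point (the trunk consumes length/rate seconds).

The tuft growth duration deserves emphasis. Running the tuft parameter
column ($B_\infty = 25$, $E = 0.3$) for the full 18 days produces runaway
arbors (on the order of a thousand tips and $10^5$ µm of cable), two orders
of magnitude beyond any real or reported apical dendrite — the published
parameter table is simply not usable verbatim for this sub-unit. The tuft
duration is therefore a package parameter, `tuft_time`, calibrated once so
that the mean total apical length matches the reported 2456 µm
(trunk 80 + obliques ≈555 + tuft ≈1820 µm ⇒ 220,000 s ≈ 2.5 days). The
calibration target is the printed total length because dendritic cable, not
tuft topology, is what drives geometry-based synapse formation. A side
effect is that the tuft is more compact in space than a real tuft.

The stem's nominal branching parameter ($B_\infty = 0.1$, about a 10% chance
of a single branch) is not honoured: how a branching stem interacts with
trunk-length targeting is unspecified, so the trunk is grown unbranched.

## Network assembly

250 somata are placed uniformly at random in a cylinder of radius 93 µm and
height 360 µm with a 20 µm minimum spacing (≈25,560 per mm³), by rejection
sampling. Each neuron gets one axon (initial direction −z), one apical
dendrite (+z) and a uniform 4–8 basal dendrites with initial directions
uniform on the sphere excluding 30° cones around ±z (a free choice; the
cones keep basal dendrites from duplicating the axon/apical directions).
Soma diameters (N(15, 1.5) µm) are used only for SWC output. Neurites may
grow outside the cylinder; no boundary confinement is applied. With a master
seed, every neuron is grown on its own deterministic RNG substream, so
morphologies are stable under changes in neuron count.

## Synapse formation

After growth, every (axonal piece, dendritic piece) pair of distinct neurons
is tested: the pair is a candidate synapse if the pieces *cross* — the
common perpendicular of their carrier lines touches both pieces strictly in
their interiors — and the length of that perpendicular is below the
threshold (default 4 µm, motivated by ≈2 µm neurite diameters plus ≈1 µm
filopodial reach). Parallel pieces and endpoint-proximal pairs never form
synapses; this strict-interior rule also prevents double counting at shared
vertices of consecutive pieces. Each qualifying pair yields exactly one
synapse; adjacent pieces may each qualify independently. Autapses are
excluded; only axon→dendrite contacts are formed. The synapse location is
the midpoint of the connector; the four distance measures (path and
Euclidean, to the pre- and postsynaptic soma) are measured from the contact
points on the centre lines, which keeps Euclidean ≤ path exactly.

Detection uses a uniform spatial grid (cell size = threshold + longest
piece, so qualifying pairs always sit in adjacent cells); an O(n²)
`method = "exhaustive"` scan is retained and the test suite asserts exact
set equality between the two on randomized networks.

## Connectivity analysis

A *connection* is an ordered pair (pre → post) with ≥ 1 synapse; its
*strength* is its synapse count. The reported **connection probability is
the density of the directed graph** (# connections / N(N−1)). This follows
the reference arithmetic — 48,743 synapses at a mean strength of 2.53 imply
19,266 connections, which is 0.31 of the 62,250 *ordered* pairs — rather
than the fraction of unordered pairs connected in either direction, which
would be ≈0.5 and inconsistent with the same source's other numbers.
Connections are classified basal/apical only when *all* their synapses are
on that dendrite kind; mixed connections belong to neither (again matching
the reference counts, whose kind totals fall short of the overall total).

Graph-theoretic measures (mean shortest path length over unordered pairs,
per-node clustering $2n_i/(k_i(k_i-1))$ with nodes of degree < 2 scoring 0)
operate on the undirected simple-graph view, via igraph, and are
cross-checked in the tests against hand-rolled Floyd–Warshall and
triangle-counting oracles. Small-worldness is $\gamma/\lambda$ with
$\gamma = C/C_{rand}$, $\lambda = L/L_{rand}$ against full
edge-redistribution randomizations (same node and edge count, simple,
redrawn until connected — not degree-preserving rewiring).

Note one structural fact: for any graph, the fraction of node pairs at
distance 1 is fixed by the edge count, so $L \ge 2 - \text{density}$, and an
edge-count-preserving randomization cannot yield $L_{rand} > L$ unless the
original graph has diameter > 2. A reported $\lambda < 1$ on a dense graph
is therefore not reproducible by this (or any faithful) implementation.

## Parameter fitting

`fit_growth_params()` fits the six outgrowth constants to target shape
statistics (means and SDs of the six characteristics, 12 measures) with a
genetic algorithm: rank-based selection, uniform crossover, per-gene
Gaussian mutation (SD annealed from 10% to 2.5% of the search range),
elitism of 2. The fitness is $\sum_i |t_i - \nu_i|/t_i$ (the reference's
functional form is not published; this relative-error sum is the package's
reconstruction). Three numerical choices matter in practice and are worth
stating:

* scale-like genes ($B_\infty$, $\tau$, eri-mn, eri-sd) are searched on a
  log₁₀ scale — uniform-scale search reliably misses the metrical measures;
* candidates are scored with common random numbers (one shared evaluation
  stream), so fitness comparisons reflect parameters, not simulation luck,
  and the best-of-run is re-scored on a fresh, 4× larger simulation to
  counter the winner's curse;
* $\tau$ is only identifiable up to a few multiples of the simulated
  duration (beyond that only $B_\infty/\tau$ matters); `gene_bounds` exists
  so short fitting problems can use an identifiable range.

At the reduced evaluation scale of 30 trees per candidate, 24 candidates and
40 generations, recovery of the basal parameter set reproduces the six
target means to within ≈9–15%.

## Morphometry

Shape statistics operate on *logical* segments — stretches between root,
branch points and tips — reconstructed from the piecewise representation, so
they are exactly invariant to refining the discretization (tested to 1e-9).
Population statistics follow the standard counting rules: per-tree n for
degree and total length; pooled segments for centrifugal order; pooled
intermediate / terminal segments for the respective length measures.

## What a green test establishes — and what it does not

The synthetic world is the stated one: the published parameter tables, the
stated volume and placement rules, and this package's documented free
choices (turning model, oblique attachment, tuft duration). Within that
world, the test suite verifies the machinery exactly (oracle equalities,
invariants, determinism) and the morphometric statistics that the branching
and elongation parameters actually pin down (axonal degree, centrifugal
order, path length).

Three classes of published values are **not** reproduced, and the acceptance
tests holding them are deliberately left failing rather than loosened:

1. *Internally over-constrained morphometry.* The reference axonal
   degree/path-length/total-length triplet is mutually inconsistent under
   the stated elongation model (path = rate × time forces the observed
   +19–28% total length once path length matches); the basal mean total
   length of 649 µm exceeds the hard bound
   eri-mn × E[degree] × T ≈ 595 µm implied by its own parameters. Some
   unreported mechanism (e.g. a daughter-segment initial length) must have
   contributed cable in the original simulator.
2. *Connectivity magnitudes.* With the free direction-change defaults, the
   simulated network is ≈2× more densely connected than reported (e.g. mean
   synapses per connection 5.4 vs 2.53; directed connection probability 0.53
   vs 0.301). The spatial spread of arbors — governed entirely by the
   unpublished turning model — controls these magnitudes; the *shapes*
   (distance-decaying connection probability, skewed distance distributions,
   basal connections shorter than apical, basal degrees exceeding apical)
   are reproduced.
3. *Small-world contrasts on a dense graph.* At density ≈0.5–0.8 the
   shortest-path contrast is structurally pinned near $L = 2 - q$ and
   clustering near $q$, compressing $\gamma/\lambda$ towards 1. (The
   reference's own $L = 1.470$ with $C_{rand} = 0.460$ violates the
   $L \ge 2 - q$ bound, so that pair is unreachable by construction.)

## Numerical and degenerate-input conventions

Coordinates are µm in a right-handed frame with +z pia-ward; time in
seconds. Zero growth time yields a degenerate two-node, zero-length tree.
Zero-length pieces are skipped by synapse detection with no warning cost;
`segment_pair_crossing()` warns and reports no crossing. Tip counts above
`tip_cap` (default 50,000) abort growth with a diagnostic. Randomized-graph
draws that come out disconnected are redrawn (bounded retries). All
stochastic entry points accept seeds; the full pipeline is byte-reproducible
under a fixed master seed.
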