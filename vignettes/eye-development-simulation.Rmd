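---
title: "Simulating arthropod eye development with ommatid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating arthropod eye development with ommatid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommatid)
```

## The model

Arthropod eyes — from the fly's compound eye of ~800 ommatidia to insect
ocelli and single-chamber larval stemmata — develop from a common plan: a
proliferative precursor epithelium, a differentiation wavefront (the
morphogenetic furrow), evenly spaced founder photoreceptors (R8 in the fly)
that each seed one eye unit, sequential recruitment of further photoreceptor
pairs (R2/R5, R3/R4, R1/R6), recruitment of pigment/support ("border")
cells, and apoptotic pruning of leftover undifferentiated cells. `ommatid`
implements this plan as an off-lattice agent-based simulation: cells are
circles with a position, radius, fate, and growth target; the furrow is a
vertical line sweeping right to left; every developmental event is a
distance-gated rule applied behind it. The claim embodied by the simulator
is that a handful of parameters — precursor pool size, founder exclusion
radius and edge margin, per-wave recruitment counts, border layers, and a
death hazard — suffice to produce qualitatively distinct eye layouts.

A simulation cycle executes, in order:

1. **Growth.** Every cell closes a fraction `cell_growth_rate` of the gap to
   its growth ceiling (`cell_max_size` for precursors, the fate-specific
   `target_radius` for specified cells). A precursor that reaches
   `cell_max_size` divides into two daughters of radius
   `cell_max_size / sqrt(2)` (area conserved), displaced along a random
   axis.
2. **Furrow advance** by `furrow_velocity` world units.
3. **Events**, in ascending offset order: founder selection (offset 0),
   the three recruitment waves, border recruitment, apoptosis.
4. **Relaxation**: a few iterations of pairwise spring repulsion so growing
   cells push their neighbours apart.

After the sweep, specified cells finish growing to their targets, and a
final relaxation lets the packing settle.

## Units and the distance-parameter convention

Cell coordinates, radii, furrow offsets and the furrow velocity share one
world unit. The cell-scale distance parameters — `exclusion_radius`,
`min_distance_from_edge`, and the waves' `max_distance_from_r8` — are
expressed in **average cell diameters** (`2 * avg_cell_size`). This single
convention is the one under which every bundled preset is geometrically
coherent: the fly's wave range of 2 reaches its contact ring (2 diameters =
32 world units at cell radius 8) and recruits the canonical pairs, the
expansion preset's exclusion radius of 40 (800 world units) blocks any
second founder inside its eligible interior, and the fusion preset's
exclusion of 0.8–1 places founders at just under or exactly one cell
diameter — touching, which is what fusion means here. Interpreting the wave
range in raw world units instead would make the fly's value 2 smaller than
a single cell radius, and no photoreceptor could ever be recruited.

## Growth law

`cell_growth_rate` is a dimensionless per-cycle fraction of the remaining
gap: `r <- r + rate * (ceiling - r)`. Two properties recommend this law
over a plain multiplicative one:

* At the preset rates (0.005–0.01) precursors approach `cell_max_size`
  asymptotically and never divide during a sweep. This matches the model
  family being simulated, in which the extra proliferation round during
  recruitment is explicitly left out; larger, user-raised rates do drive
  division, which is the documented meaning of the parameter.
* A multiplicative law at the same printed rates forces every precursor
  lineage through repeated divisions on long sweeps (the ocelli preset
  quintupled its cell count in trials), exploding the tissue and crushing
  the layouts.

Division remains a first-class, tested operation; it simply requires growth
rates above the bundled presets to trigger.

## Mechanics: repulsion, attraction, domain

Relaxation is Jacobi iteration of linear pair springs. Overlapping pairs
repel along the center line: each partner moves `0.5 * k_rep * depth`
(`k_rep = 0.5`). During initial sheet packing, near pairs with a gap above
`0.5 * avg_cell_size` also attract weakly (`k_att = 0.01`, acting on gaps
up to one `avg_cell_size`), which keeps the sheet cohesive. The attraction
constant was set so that the many-body equilibrium between attraction
chains and repulsion compresses pairs by less than the overlap tolerance
(5% of `avg_cell_size`); a stronger pull (e.g. 0.05) parks the packing at a
residual overlap above tolerance and the overlap invariant can never be
met. Cells are seeded on a jittered square grid at 2.1 diameters spacing —
5% looser than exact contact, because a jammed exact-contact grid inside
hard walls cannot relax its size jitter away.

The rectangular domain plays two roles. During generation it is a hard wall
(cells are clamped inside). During development it becomes a fixed
*reference frame*: founder edge margins and the furrow's start/finish are
measured against it, but cells are free to move past it, because
differentiated units growing toward radii 2–3× the precursor size must
expand the tissue (the fly preset's final eye needs roughly five times the
initial area; walls would crush it and violate founder spacing). Keeping
the frame fixed also keeps the sweep length, and thus the cycle count,
bounded and independent of how much the tissue billows.

After growth completes, the settle phase relaxes with a near-full overlap
projection (`k_rep = 0.9`) for up to 20,000 iterations, stopping early at
tolerance; decompression of a heavily over-packed tissue is
diffusion-limited, and the gentle in-cycle constant would need several
times more iterations.

## Event delivery semantics

Founder selection acts on the *band* of cells the offset-0 line swept this
cycle: each cell is considered for founding exactly once, as the furrow
passes it. Selection is greedy — among eligible cells (far enough from
every existing founder and from the frame edges) the one whose minimum
distance to the founder set is smallest is chosen first, ties to the lowest
cell id — so new units form as close to existing ones as the exclusion
radius allows, reproducing dense, roughly hexagonal packing at small
exclusion radii. The very first founder is the eligible cell nearest the
right (posterior) edge.

Waves and border events are delivered *per unit*: a unit's wave fires on
the first cycle the furrow has advanced `distance_from_furrow` past the
founder's position at founding. Triggering on the founding position rather
than the live cell makes delivery exactly-once and robust to cells drifting
across band boundaries during relaxation (with a band only as wide as the
furrow's per-cycle step, a unit jostled by one cell diameter could
otherwise miss its recruitment entirely — this was observed, not
hypothetical). When several units recruit in the same cycle, precursors in
range of more than one founder go to the nearest (ties to the lower unit
id).

Apoptosis is a per-cycle hazard: every precursor behind the death offset
dies with probability `death_chance/100` each cycle. A `one_shot` flag
switches to a single band-swept application per cell for users who read the
probability as one-time. Specified cells never die.

## Randomness

One root seed spawns independent child streams (epithelium generation,
division axes, death draws), so adding draws to one consumer never perturbs
another, and `(starting epithelium, parameters, seed)` determines the final
cell table byte for byte. Founder selection and recruitment are
deterministic given positions; the size jitter injected at generation is
what breaks ties between symmetric candidates.

## What the test fixtures emulate

The built-in fixtures (`make_fixture`) are exact hexagonal patches, strips
and rings of equal circles — idealized tissues in which contact graphs,
greedy selection traces and layer counts can be enumerated by hand or by
brute force. The synthetic epithelia from `generate_epithelium` add
normally distributed size jitter (truncated at 20% of the mean) on a
jittered grid. Neither reproduces real epithelial features such as
anisotropic cell shapes, apical constriction, adhesion-mediated
rearrangement, or signalling-driven proliferation gradients; passing tests
demonstrate the *rule set* behaves as specified on clean geometry, not that
the rules capture all of real eye disc mechanics.

## Problem sizes and tolerances in the tests

The acceptance suite generates one full fly-scale sheet (10,000 cells),
sweeps all seven presets at half-scale epithelia over three seeds for the
founder-spacing invariant, and runs the ocelli and twisted-wing censuses at
full scale; these sizes keep the whole suite within a coffee break on one
CPU while exercising every regime. Numerical tolerances: pairwise overlap
up to 5% of `avg_cell_size` is accepted as packed; the final-layout founder
spacing check allows 10% mechanical drift below the exclusion distance,
because after specification growing clusters jostle one another and the
model has no cell adhesion to pin cells in place (the same reason specified
cells visibly shift in delayed-death runs). The selection rule itself is
verified exactly against brute-force oracles.

## Known limitations

* **Unit counts at large exclusion radii are approximate.** The ocelli
  preset yields 3–7 units depending on scale and seed rather than exactly
  the insect triad; the greedy packer fills whatever interior the edge
  margin leaves.
* **Late-fusion mosaics are only partially interleaved.** With founders at
  one cell diameter, founders plus first-wave recruits exhaust the local
  pool; later waves draw on farther or replenished regions, so wave labels
  retain substantial spatial autocorrelation (Moran's I ≈ 0.7 rather than
  near zero) even though all types do appear within the fused retina. A
  per-unit full complement and a near-random mosaic are jointly
  unreachable at the fusion preset's parameters under this rule set, since
  each founder at contact spacing would need six recruits from a shared
  pool of fewer than one free precursor per founder.
* **No adhesion, no 3D, no gene dynamics.** Units drift a few percent after
  specification; R7/Semper-type cells above the photoreceptor plane and
  signalling networks are out of scope.
* The border of very crowded tissues can recruit through compressed
  contact chains; border layer counts are meaningful only in relaxed
  tissue.

## A worked run

```{r, eval = FALSE}
p <- load_preset("drosophila")
sim <- run_simulation(p, seed = 1)
summary(sim)
founder_spacing(sim)     # min pairwise distance >= ~2 cell diameters
plot(sim)                # the familiar dotted lattice of ommatidia
render_snapshot(sim, "fly.svg")
```
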