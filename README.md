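# ommatid

An off-lattice, agent-based simulator of arthropod eye development in R.

A virtual morphogenetic furrow sweeps a two-dimensional epithelium of
circular precursor cells from right (posterior) to left. Distance-gated
events fire behind it:

* **Founder selection** — undifferentiated cells become R8-like founders,
  greedily and as densely as an *exclusion radius* allows, each opening a
  new eye unit;
* **Photoreceptor waves** — three successive recruitment waves (the fly's
  R2/R5, R3/R4, R1/R6 pairs, generalized to arbitrary counts) claim the
  nearest precursors within a per-wave range of the founder;
* **Border cells** — concentric contact layers of precursors become
  pigment/support cells wrapping each unit;
* **Apoptosis** — remaining undifferentiated cells die with a per-cycle
  hazard.

Cells are circles with a position, radius, fate and growth target; packing
is maintained by linear-spring repulsion (with weak attraction during
initial sheet formation). Seven bundled presets reproduce qualitatively
different eye layouts from this single rule set: a fly-like compound eye,
the large spaced units of twisted-wing insects, spread-out larval stemmata,
clustered image-forming larval eyes, insect ocelli, and single-chamber
eyes arising either by *expansion* (one founder, concentric photoreceptor
shells) or by *fusion* (many contact-spaced founders merging into one
retina). It is aimed at developmental biologists exploring how few
parameters need to change to move between arthropod eye types.

Cell-scale distance parameters (exclusion radius, edge margin, wave
ranges) are expressed in average cell diameters; positions, radii, offsets
and velocity share one world unit. See the vignette
(`vignettes/eye-development-simulation.Rmd`) for the model, its
assumptions, and every numerical choice.

## A worked example

```r
library(ommatid)

p <- load_preset("drosophila")   # Min Cell Count 10,000; exclusion radius 2
sim <- run_simulation(p, seed = 1)
summary(sim)
#> Eye development simulation: 145 cycles, 1950 eye units
#>   cells: 10000 initial + 0 divisions - 206 deaths = 9794 final
#>   founder spacing: min 38.0, mean 1798.4 (nn cv 0.276)
#>   per-unit census (first units):
#>  unit_id n_wave1 n_wave2 n_wave3 n_border
#>        1       2       2       2        3
#>        2       2       2       2        3
#>        3       2       2       2        2
#>        ...

founder_spacing(sim)$min / (2 * p$avg_cell_size)
#> [1] 2.37
```

Reading the output: 1950 ommatidium-like units formed; each interior unit
recruited its three photoreceptor pairs (2/2/2) plus a thin border wrap;
the minimum center distance between any two founders is 38 world units =
2.37 cell diameters, above the exclusion radius of 2 — founders never
violate their spacing rule, and the surplus reflects units pushing apart
as their cells grow. `plot(sim)` draws the lattice (founders dark purple,
waves progressively paler pink, border cells green);
`render_snapshot(sim, "eye.svg")` writes the same picture as SVG.

Other entry points: `generate_epithelium()` /
`write_epithelium()` / `read_epithelium()` (reusable starting tissues, so
parameter sweeps share one epithelium), `census()`, `founder_spacing()`,
`wave_radial_profile()`, `wave_label_moran()` (layout metrics),
`write_event_log()` (JSON-lines replay log), and a shell front end:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ommatid.R", package = "ommatid"))') \
    run --preset ocelli --seed 1 --out out/
```

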