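# gelgraft

Quantification pipelines for hydrogel-mediated retinal ganglion cell
transplantation, with synthetic-data generators carrying known ground
truth.

Injectable gelatin/hyaluronic-acid interpenetrating networks (IPNs:
Gtn-HPA crosslinked with HA-Tyr) are used as vehicles to deliver human
retinal ganglion cells (hRGC) into the vitreous, where the gel attaches to
the inner limiting membrane (ILM) and releases cells onto the retina.
Characterising such a system requires a chain of bespoke quantifications —
none of which ship as reusable software.  `gelgraft` implements that chain
as tested R functions:

* **Passive microrheology** — mean square displacement (MSD) of tracked
  tracer beads, time-resolved power-law exponent from a log-log polynomial
  fit, conversion to the complex shear modulus via the generalized
  Stokes–Einstein relation
  \|G\*\|(1/τ) = k_B·T / (π·a·MSD₃D(τ)·Γ(1+α)),
  G′ = \|G\*\|cos(πα/2), G″ = \|G\*\|sin(πα/2), and the **gel point** as the
  earliest G′ = G″ crossover (α = 0.5).  Helpers for oscillatory-rheology
  plateau times, compression-test Young's moduli, and the GPC calibration
  log₁₀(Mn) = 10.2086 − 0.7604·Vp.
* **Selective enzymatic degradation** — saturating-exponential mass-loss
  fits m(t) = f∞(1 − e^(−kt)); collagenase degrades the gelatin fraction
  and hyaluronidase the HA fraction, so the two plateaus estimate the IPN
  composition; in vitro / in vivo curve comparison by R².
* **Live/dead viability** — Otsu-based segmentation with adaptive
  smoothing, border-object removal, hole filling, opening, a strict
  <10 px small-object rule, watershed splitting of touching cells,
  per-cell morphometry (area, Crofton perimeter, shape factor
  C = 4πA/P²), viability percentages and z-distribution profiles.
* **Engraftment** — dual-threshold (0.10/0.30) fusion segmentation with
  5-px border deletion, retinal-layer assignment by majority overlap,
  cell extent (max Feret diameter) and orientation relative to the
  annotated layer, size classes (round < 30 µm, medium 30–150 µm, long
  > 150 µm), and extrapolation to the percentage of the 5×10⁴ injected
  cells.
* **Co-localization** — Pearson r, Manders M1/M2, co-localized pixel
  fraction, block-permutation p-value; marker surface coverage.
* **Gel–ILM interface and OCT** — attachment percentage along the retina
  boundary in 200-µm segments with hole statistics and multi-slide heat
  maps; OCT stack registration (phase correlation), z-projection, and
  Otsu foreground-surplus gel-mass time series.

Because no raw images or track tables are publicly deposited for this
kind of study, every pipeline ships with a **synthetic generator**
(`simulate_*`, `render_*`) whose named presets (`"gtn_hpa"`, `"ipn75"`,
`"ipn50"`, `"pbs"`) encode the study conditions as ground truth, so each
pipeline can be scored end-to-end on data with a known answer.

## Worked example: gel point of the fast-gelling formulation

```r
library(gelgraft)

preset <- gelation_preset("gtn_hpa")   # gel point 42 s, 15 beads, 0.1 s frames
sim    <- simulate_gelation_tracks(preset, seed = 1)
fit    <- gel_point_pipeline(sim$tracks,
                             gser_params(preset$bead_radius,
                                         preset$temperature))
round(fit$gel_point, 1)
#> [1] 40.1
```

The bead tracks diffuse like a liquid (MSD ~ τ^0.9) early on and become
subdiffusive (τ^0.1) as the network forms; the pipeline recovers the
G′ = G″ crossover within ~5% of the preset's 42 s gel point (the 20-seed median in the
acceptance run lands within 1%).

Composition of a 75/25 IPN from selective degradation:

```r
p    <- degradation_preset("ipn75", noise_sd = 0.02)
coll <- simulate_degradation(p, "collagenase",   seed = 41)
hyal <- simulate_degradation(p, "hyaluronidase", seed = 42)
est  <- infer_composition(coll, hyal)
round(c(gtn = est$f_gtn, ha = est$f_ha), 3)
#>   gtn    ha
#> 0.756 0.276
```

Engraftment of injected cells in an annotated retina field:

```r
rp  <- retina_preset("ipn50")          # 40% GCL occupancy, 56% engraftment
rs  <- render_retina_sections(rp, n_fields = 10, seed = 7)
tab <- lapply(rs$fields, function(f)
  analyze_retina_field(f$channels, f$layer_mask))
s   <- summarize_engraftment(tab, injected_total = rp$injected_total,
                             fields_per_retina_scale =
                               rp$fields_per_retina_scale)
round(s$per_layer_percent, 1)
#> vitreous      GCL      IPL      INL      ONL
#>      3.4     40.2     36.8     13.8      5.7
```

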