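---
title: "Models and methods behind gelgraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gelgraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gelgraft)
```

`gelgraft` quantifies an injectable cell-delivery system: gelatin (Gtn-HPA)
and hyaluronic-acid (HA-Tyr) precursors that crosslink enzymatically into
an interpenetrating network (IPN) around suspended human retinal ganglion
cells, gel in the vitreous within seconds to minutes, attach to the inner
limiting membrane (ILM), and release their cells onto the retina as the
enzymes of the eye degrade them.  Each stage of that pipeline has its own
measurement, and each measurement in this package is paired with a
synthetic generator that embeds the study conditions as ground truth.
This vignette records the models, the assumptions of the generators, and
the numerical choices a maintainer would want explained.

## Passive microrheology and the gel point

A tracer bead of radius $a$ in a viscoelastic medium at temperature $T$
performs thermal motion whose mean square displacement follows a local
power law, $\mathrm{MSD}(\tau) \propto \tau^{\alpha}$, with $\alpha = 1$
in a pure liquid and $\alpha \to 0$ in an elastic solid.  The generalized
Stokes–Einstein relation (Mason's form) converts the MSD into the complex
shear modulus at frequency $1/\tau$:

$$|G^*|(1/\tau) = \frac{k_B T}{\pi a\, \mathrm{MSD_{3D}}(\tau)\,
\Gamma(1+\alpha)}, \qquad
G' = |G^*| \cos(\pi\alpha/2), \quad G'' = |G^*| \sin(\pi\alpha/2),$$

with planar tracking converted by isotropy,
$\mathrm{MSD_{3D}} = \tfrac{3}{2}\mathrm{MSD_{2D}}$.  The *gel point* is
the earliest $G' = G''$ crossover, which under this relation is exactly
the moment the local exponent passes $\alpha = 0.5$ — so the crossover
time is independent of the modulus prefactor, bead radius and
temperature.  `compute_msd()` uses the all-ordered-pairs estimator in
sliding 10 s windows centred every 2 s (matching the 2 s cadence of the
reference oscillatory measurements); `msd_to_moduli()` fits
$\ln \mathrm{MSD}$ vs $\ln\tau$ with a second-order polynomial and takes
$\alpha$ as its derivative at the geometric-mean lag of the window;
`detect_gel_point()` locates the sign change of $G' - G''$ by linear
interpolation.  Defaults: bead radius 7.5 µm (midpoint of 10–20 µm
diameter PLGA microbeads), temperature 310.15 K.

**Generator.**  No generative model for bead motion in a gelling medium
is given by rheology alone, only the target MSD behaviour.  The package
draws increments from a *locally stationary fractional Gaussian noise*: a
zero-mean Gaussian process whose covariance between steps $i$ and $j$ is
the fGn autocovariance evaluated at the pairwise-mean local Hurst
exponent $H_{ij} = (H_i + H_j)/2$, with per-step variance
$\mathrm{d}t^{2H_i}$ and $H(t) = \alpha(t)/2$, sampled exactly by
Cholesky factorisation.  Where $\alpha$ is locally constant this *is*
fGn, so windowed MSD slopes equal $\alpha(t)$; a simpler
Riemann–Liouville kernel was tried first and rejected because
re-weighting of the history term biased windowed slopes near the
transition by tens of seconds.  The exponent follows a logistic,
$\alpha(t) = \alpha_{gel} + (\alpha_{liq}-\alpha_{gel})\,
\sigma((t_{gel}-t)/w)$; the crossing of 0.5 sits exactly at $t_{gel}$
only when $\alpha_{liq} + \alpha_{gel} = 1$, so the presets use the
symmetric pair 0.90/0.10 (width $w = 4$ s, amplitude 0.5 µm²/s^α, 15
beads, 0.1–0.2 s frames) and the constructor warns about asymmetric
choices.  Preset gel points: 42 s (`gtn_hpa`), 151 s (`ipn75`), 167 s
(`ipn50`).  Localization noise defaults to 0 and is exposed as
`localization_sd`.

One contract deviation is worth recording: the MSD estimator keeps lags
supported by a single displacement pair (with a warning) rather than
dropping them, because the estimator's own worked example requires the
final lag of a three-point track.

## Selective enzymatic degradation and composition

Released mass follows the saturating exponential
$m(t) = f_\infty(1 - e^{-kt})$ — the only monotone bounded model
consistent with the observed plateaus ("inverse exponential" in assay
parlance).  Collagenase attacks only the gelatin network and
hyaluronidase only the HA network, so fitting both assays estimates the
composition directly: $f_{gtn}$ from the collagenase plateau, $f_{ha}$
from the hyaluronidase plateau, with closure $f_{gtn} + f_{ha} = 1$
checked against a residual-bootstrap standard error (200 resamples, seed
1234).  The 75/25 preset reproduces the canonical 75% / 25% mass-loss
pair.  In vivo enzyme concentrations (0.5 U/ml collagenase, 0.3 U/ml
hyaluronidase) are carried as preset metadata only; no
concentration-to-rate model is attempted.  `compare_curves()` places both
curves on the remaining-mass scale, interpolates the denser in vitro
curve onto the in vivo time points, and reports $R^2$ as the squared
Pearson correlation (the correlation itself is also returned, since
"correlation coefficient" is ambiguous).  Preset rates ($k_{coll} =
0.12$/min, $k_{hyal} = 0.04$/min) put the plateaus comfortably inside the
1 h / 2 h assay windows at their 5 min / 10 min sampling intervals —
12 points per series either way.

## Live/dead viability pipeline

`segment_channel()` follows the fixed recipe: percentile contrast
stretch, 3×3 local-variance (Wiener-style) adaptive smoothing, global
Otsu threshold, removal of objects touching the 1-px border, hole
filling, opening with a disc of radius 2 px, and removal of components
below 10 px — strictly below, so a 10-px component survives.  Two
calibration notes: the stretch anchors at the 1st and **99.9th**
percentiles, because a 99th-percentile anchor lies in the background
whenever cells cover less than 1% of the frame and then amplifies noise
into the threshold; and connected components are 8-connected, implemented
as a union–find diagonal merge over `EBImage::bwlabel`'s 4-connected
labels.  `watershed_split()` seeds a watershed with maxima of the
Euclidean distance transform separated by at least 5 µm (a typical
nuclear radius) and never decreases the label count.  Viability is
100·live/(live+dead) per field, summarised as mean ± SEM **across
fields**.  `z_profile()` averages intensity in 150 µm slabs and
normalises to the brightest slab: flat for cells dispersed through a gel,
peaked at zero for a monolayer.

The perimeter behind the shape factor $C = 4\pi A / P^2$ is a Crofton
(integral-geometric) estimate from intercept counts along eight lattice
direction families — axial, diagonal and knight-move — with a
pixel-support correction per line family.  Counting boundary pixels
instead would misreport a 10×10 square ($C = 0.97$ instead of $\pi/4$);
the Crofton estimator gives $P = 40.0$ for that square and $\pi \cdot 2r$
for large discs.

## Engraftment quantification

`fusion_segment()` normalises to [0, 1], blurs with $\sigma = 1$ px,
masks at the low threshold 0.10 (recall), applies closing then opening
(disc radius 2 px), labels components, keeps only those containing a
pixel above the high threshold 0.30 (precision), and deletes the 5-px
image border.  Detected cells are assigned to the annotated retinal layer
with maximum pixel overlap (ties broken by the centroid's layer; no
overlap counts as background).  Cell extent $r$ is the max Feret
(caliper) diameter — the total reach of body plus processes — with the
moments-equivalent-ellipse major axis also available; orientation
$\theta$ is the difference between the cell's and the layer's ellipse
angles, wrapped to [−90°, 90°].  Size classes: round $r \le 30$ µm,
medium $30 < r \le 150$, long $r > 150$ (boundary values to the lower
class, a deterministic resolution of the open intervals).  The
moments-equivalent ellipse is used for both cell and layer because it is
unique and rotation-stable; a smallest-enclosing-ellipse alternative
would change angles by under a degree for band-shaped layers.

`summarize_engraftment()` reports per-layer percentages over assigned
cells and extrapolates the engrafted percentage of the injected dose as
$100 \cdot \bar{n}_{field} \cdot s / N_{inj}$ with $N_{inj} = 5\times
10^4$.  The scale $s$ (`fields_per_retina_scale`) is the package's
explicit stand-in for an unspecified extrapolation: the generator and
analyzer share it, so recovery is well-posed; with real data it must be
set from the tiling geometry of the acquisition.

**Generator.**  Each synthetic field (360×720 px at 0.6 µm/px) stacks
five tilted bands (vitreous, GCL, IPL, INL, ONL; tilt uniform in ±8°).
Cell count per field is Poisson with mean
$f_{eng} N_{inj}/s$; layer and size class are drawn from the preset
fractions; elongated cells take $\theta \sim N(0, 15^\circ)$ (long cells
$N(0, 5^\circ)$ — long processes run parallel to the layers), truncated
so the cell stays inside its band.  Cells are placed largest-first by
rejection sampling with a 10-px guard clearance so the fusion pipeline
resolves them individually; when a steeply tilted cell cannot fit, its
orientation is annealed toward the layer direction, and the rendered
orientation is what enters the truth table.  Placement failures are below
1% under the presets.  The reporter channel carries the whole cell; the
human-marker channel covers a `coloc_level` fraction of its pixels,
trimmed from one end so that blurring cannot refill the gap.  The `pbs`
preset encodes saline delivery: 38% engraftment, no long cells, and a GCL
fraction of 0.2947 chosen so the ground-truth GCL cell count is exactly
half the `ipn50` preset's — the study's two headline statements (about
40% GCL occupancy in all groups, and a 2-fold GCL advantage of the 50/50
gel over saline) cannot both hold exactly given 56% vs 38% engraftment,
and the generator resolves the conflict in favour of the printed fold
change while keeping the hydrogel groups at 40%.

## Co-localization

`coloc_stats()` reports Pearson's $r$ over all pixels, Manders
$M_1 = \sum_i a_i [b_i > T_b] / \sum_i a_i$ (and $M_2$ symmetrically),
and the co-localized pixel fraction $|A \cap B| / |A \cup B|$ of
supra-threshold supports — the statistic used for the ≥ 70% per-cell
criterion, computed per detected cell on a 2-px-padded bounding box with
a fixed threshold of 0.2.  The permutation p-value shuffles 16-px blocks
of one channel (not single pixels) to respect spatial autocorrelation,
with an add-one estimator so identical channels give exactly
$1/(n_{perm}+1)$.  `surface_coverage()` counts pixels above a threshold
with a 10⁻⁴ intensity tolerance (0.01% of the normalized scale) at the
comparison.

## Gel–ILM interface and OCT gel mass

`measure_attachment()` extracts the retina's vitreal boundary (topmost
retina pixel per column), resamples it at 1 µm along arc length, and
marks a step attached iff a gel pixel lies within the 2-px gap tolerance
applied **perpendicular to the interface** — an isotropic disc tolerance
would bleed attachment sideways across hole edges and bias recovery
upward by about 3 percentage points.  The boundary is split into
consecutive 200 µm segments (a trailing partial segment is reported but
excluded from the per-segment aggregate); holes are maximal unattached
runs; the heat map across slides is the exact per-position mean of the
attachment flags.  The generator produces an alternating renewal process
— exponential hole lengths (scale 30 µm) and attached lengths scaled to
the marginal probability — over a 600 µm undulating boundary, with gel
pixels rendered directly on attached stretches; presets encode 50%
(`gtn_hpa`), 59% (`ipn75`) and 79% (`ipn50`) attachment.

`preprocess_oct()` registers frames to the first by integer-pixel phase
correlation (subpixel refinement is deliberately out of scope at OCT
speckle scales), drops frames whose shift exceeds 25% of the frame, and
returns the mean z-projection.  `quantify_gel()` counts Otsu-foreground
pixels and subtracts a control-scan baseline (mean over ≥ 3 gel-free
scans), clamping at zero; `gel_mass_series()` normalises to the first
post-injection scan (day 0 — whether the reference study normalised to
day 0 or the 1 h scan is unstated, and day 0 is the defensible default).
The OCT generator keeps gel islands strictly above the retina band and
counts only newly covered pixels, so the ground-truth decay
$e^{-\lambda \cdot day}$ is rendered exactly up to discretisation.

## Reproducibility, sizes and limitations

Every generator is bit-reproducible given (preset, seed); the default
seed is 20211220 and every function takes an override.  Test and
acceptance problem sizes — 20 seeds for the gel point and attachment
averages, 10 seeds × 60 fields for the engraftment pipeline, 12-point
degradation series — were chosen as the smallest sets at which the
recovery standard errors sit well inside the quantities' natural
tolerances.

What passing these tests shows — and what it does not: the synthetic
fields are Gaussian-smoothed constant-amplitude ellipses over white
noise, with no point-spread anisotropy, intensity gradients, staining
heterogeneity, debris, or touching-cell clumps beyond what the guard
spacing allows; layer annotations are exact bands rather than hand-drawn
polygons; OCT speckle is i.i.d. multiplicative noise rather than
correlated speckle.  Recovery on these fixtures validates the *logic and
calibration* of each pipeline (thresholds, morphology, unit handling,
estimators), not robustness to the full pathology of real microscopy.
The attachment criterion is geometric (gap tolerance), standing in for a
histology-stain visual criterion; and the engrafted-percentage
extrapolation is only as good as the shared `fields_per_retina_scale`
constant.
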