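# Named presets encoding the study conditions for every synthetic generator.
# Each constructor validates its fields and supports per-call overrides, so
# tests and scripts can reference conditions by name ("gtn_hpa", "ipn75",
# "ipn50", "pbs") and only vary what they need (typically the seed).

new_preset <- function(fields, class) {
  structure(fields, class = c(class, "gelgraft_preset", "list"))
}

#' @export
print.gelgraft_preset <- function(x, ...) {
  cat("<", class(x)[1], "> preset '", x$name, "'\n", sep = "")
  for (f in setdiff(names(x), "name"))
    cat("  ", f, ": ", paste(format(x[[f]]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- gelation (passive microrheology) ---------------------------------------

.gelation_presets <- list(
  # t_gel values are the microrheology gel points of the three injectable
  # formulations; alpha_liquid/alpha_gel bracket the critical exponent 0.5
  gtn_hpa = list(t_gel = 42,  frame_interval = 0.1, duration = 120),
  ipn75   = list(t_gel = 151, frame_interval = 0.2, duration = 240),
  ipn50   = list(t_gel = 167, frame_interval = 0.2, duration = 240)
)

#' Gelation preset for the bead-track generator
#'
#' Encodes a gelling medium in which the anomalous-diffusion exponent
#' \eqn{\alpha(t)} of embedded tracer beads decays from `alpha_liquid` to
#' `alpha_gel` through a logistic transition centred at the gel point
#' `t_gel` (where \eqn{\alpha = 0.5}, the storage/loss modulus crossover).
#'
#' Named presets: `"gtn_hpa"` (gel point 42 s), `"ipn75"` (151 s),
#' `"ipn50"` (167 s).
#'
#' @param name preset name, or any label when all fields are given explicitly.
#' @param ... field overrides: `t_gel`, `alpha_liquid`, `alpha_gel`,
#'   `transition_width` (s), `msd_amplitude` (um^2/s^alpha), `n_beads`,
#'   `frame_interval` (s), `duration` (s), `bead_radius` (um),
#'   `temperature` (K), `localization_sd` (um), `seed`.
#' @return a `gelation_preset` object.
#' @export
gelation_preset <- function(name = "gtn_hpa", ...) {
  base <- .gelation_presets[[name]] %||% list()
  p <- modifyList(list(
    name = name, t_gel = 60, alpha_liquid = 0.90, alpha_gel = 0.10,
    transition_width = 4, msd_amplitude = 0.5, n_beads = 15L,
    frame_interval = 0.1, duration = 240, bead_radius = 7.5,
    temperature = 310.15, localization_sd = 0, seed = .default_seed
  ), modifyList(base, list(...)))
  check_number(p$t_gel, "t_gel", lower = 0, closed_lower = FALSE)
  check_number(p$alpha_liquid, "alpha_liquid", 0.5, 1, closed_lower = FALSE)
  check_number(p$alpha_gel, "alpha_gel", 0, 0.5, closed_upper = FALSE)
  check_number(p$transition_width, "transition_width", 0, closed_lower = FALSE)
  check_number(p$msd_amplitude, "msd_amplitude", 0)
  check_number(p$n_beads, "n_beads", 1)
  check_number(p$frame_interval, "frame_interval", 0, closed_lower = FALSE)
  check_number(p$duration, "duration", 0, closed_lower = FALSE)
  check_number(p$bead_radius, "bead_radius", 0, closed_lower = FALSE)
  check_number(p$temperature, "temperature", 0, closed_lower = FALSE)
  check_number(p$localization_sd, "localization_sd", 0)
  if (p$duration <= p$t_gel)
    stopf("gelation preset: duration (%g) must exceed t_gel (%g)",
          p$duration, p$t_gel)
  if (abs(p$alpha_liquid + p$alpha_gel - 1) > 1e-9)
    warnf(paste("alpha_liquid + alpha_gel != 1: the exponent crosses 0.5",
                "slightly away from t_gel"))
  new_preset(p, "gelation_preset")
}

# ---- degradation ------------------------------------------------------------

.degradation_presets <- list(
  gtn_hpa = list(f_gtn = 1.00),
  ipn75   = list(f_gtn = 0.75),
  ipn50   = list(f_gtn = 0.50),
  ipn25   = list(f_gtn = 0.25),
  ha_tyr  = list(f_gtn = 0.00)
)

#' Degradation-assay preset
#'
#' Encodes an IPN composition (`f_gtn` gelatin fraction, `f_ha = 1 - f_gtn`
#' hyaluronic-acid fraction) and first-order enzymatic release rates.
#' Collagenase assays are sampled every `sampling_interval` minutes over
#' `duration` minutes; hyaluronidase assays at twice the interval over twice
#' the duration (the slower assay), giving the same number of time points.
#'
#' Named presets: `"gtn_hpa"`, `"ipn75"`, `"ipn50"`, `"ipn25"`, `"ha_tyr"`.
#'
#' In vivo vitreal enzyme concentrations (metadata only, no kinetics model):
#' collagenase 0.5 U/ml, hyaluronidase 0.3 U/ml.
#'
#' @param name preset name.
#' @param ... overrides: `f_gtn`, `k_coll` (1/min), `k_hyal` (1/min),
#'   `noise_sd`, `sampling_interval` (min), `duration` (min), `seed`.
#' @return a `degradation_preset` object (with derived field `f_ha`).
#' @export
degradation_preset <- function(name = "ipn75", ...) {
  base <- .degradation_presets[[name]] %||% list()
  p <- modifyList(list(
    name = name, f_gtn = 0.75, k_coll = 0.12, k_hyal = 0.04,
    noise_sd = 0.02, sampling_interval = 5, duration = 60,
    in_vivo_enzymes = c(collagenase_U_ml = 0.5, hyaluronidase_U_ml = 0.3),
    seed = .default_seed
  ), modifyList(base, list(...)))
  check_number(p$f_gtn, "f_gtn", 0, 1)
  p$f_ha <- 1 - p$f_gtn
  check_number(p$k_coll, "k_coll", 0, closed_lower = FALSE)
  check_number(p$k_hyal, "k_hyal", 0, closed_lower = FALSE)
  check_number(p$noise_sd, "noise_sd", 0)
  check_number(p$sampling_interval, "sampling_interval", 0, closed_lower = FALSE)
  check_number(p$duration, "duration", 0, closed_lower = FALSE)
  new_preset(p, "degradation_preset")
}

# ---- live/dead fields -------------------------------------------------------

.field_presets <- list(
  # 70% viable: the encapsulated-cell viability fixture
  default = list(n_live = 28L, n_dead = 12L),
  sparse  = list(n_live = 8L, n_dead = 2L)
)

#' Live/dead fluorescence field preset
#'
#' Conditions for rendering a two-channel (live/dead) field of
#' disc-to-ellipse cells over noisy background at a stated SNR.
#'
#' @param name preset name (`"default"`: 28 live / 12 dead, 70% viable).
#' @param ... overrides: `image_shape` (H, W px), `pixel_size` (um/px),
#'   `n_live`, `n_dead`, `cell_radius_range` (um, length 2),
#'   `elongation_fraction`, `snr`, `seed`.
#' @return a `field_preset` object.
#' @export
field_preset <- function(name = "default", ...) {
  base <- .field_presets[[name]] %||% list()
  p <- modifyList(list(
    name = name, image_shape = c(384L, 384L), pixel_size = 0.8,
    n_live = 28L, n_dead = 12L, cell_radius_range = c(3, 6),
    elongation_fraction = 0.2, snr = 12, seed = .default_seed
  ), modifyList(base, list(...)))
  check_number(p$n_live, "n_live", 0)
  check_number(p$n_dead, "n_dead", 0)
  check_number(p$snr, "snr", 0, closed_lower = FALSE)
  check_number(p$pixel_size, "pixel_size", 0, closed_lower = FALSE)
  if (length(p$image_shape) != 2L || any(p$image_shape < 16))
    stopf("image_shape must be (H, W) with both >= 16")
  if (length(p$cell_radius_range) != 2L || any(p$cell_radius_range <= 0))
    stopf("cell_radius_range must be two positive radii (um)")
  new_preset(p, "field_preset")
}

# ---- retina cross-sections --------------------------------------------------

.retina_layers <- c("vitreous", "GCL", "IPL", "INL", "ONL")

.retina_presets <- list(
  ipn50 = list(
    layer_fractions = c(vitreous = 0.03, GCL = 0.40, IPL = 0.30,
                        INL = 0.24, ONL = 0.03),
    engraft_fraction = 0.56,
    size_class_mix = c(round = 0.55, medium = 0.35, long = 0.10)),
  ipn75 = list(
    layer_fractions = c(vitreous = 0.03, GCL = 0.40, IPL = 0.30,
                        INL = 0.24, ONL = 0.03),
    engraft_fraction = 0.53,
    size_class_mix = c(round = 0.60, medium = 0.32, long = 0.08)),
  gtn_hpa = list(
    layer_fractions = c(vitreous = 0.03, GCL = 0.40, IPL = 0.30,
                        INL = 0.24, ONL = 0.03),
    engraft_fraction = 0.52,
    size_class_mix = c(round = 0.60, medium = 0.30, long = 0.10)),
  # GCL fraction chosen so the ground-truth GCL cell count is exactly half
  # of the ipn50 preset's (the reported 2-fold difference); saline delivery
  # yields no long-process cells.
  pbs = list(
    layer_fractions = c(vitreous = 0.0253, GCL = 0.2947, IPL = 0.33,
                        INL = 0.32, ONL = 0.03),
    engraft_fraction = 0.38,
    size_class_mix = c(round = 0.80, medium = 0.20, long = 0))
)

#' Retina cross-section preset
#'
#' Conditions for rendering annotated retina fields containing engrafted
#' cells: per-layer occupancy, size-class mix (round r < 30 um, medium
#' 30-150 um, long > 150 um), orientation spread relative to the layer, and
#' channel co-localization level. The expected number of cells per field is
#' `engraft_fraction * injected_total / fields_per_retina_scale`, so the
#' engrafted percentage of the injected dose is recoverable from per-field
#' counts with the same scale constant.
#'
#' Named presets: `"ipn50"`, `"ipn75"`, `"gtn_hpa"`, `"pbs"`.
#'
#' @param name preset name.
#' @param ... overrides: `layer_order`, `layer_fractions` (named, sums to 1),
#'   `n_fields`, `size_class_mix` (round/medium/long, sums to 1),
#'   `orientation_sd` (degrees), `coloc_level`, `injected_total`,
#'   `engraft_fraction`, `fields_per_retina_scale`, `image_shape`,
#'   `pixel_size` (um/px), `snr`, `seed`.
#' @return a `retina_preset` object.
#' @export
retina_preset <- function(name = "ipn50", ...) {
  base <- .retina_presets[[name]] %||% list()
  p <- modifyList(list(
    name = name, layer_order = .retina_layers,
    layer_fractions = c(vitreous = 0.03, GCL = 0.40, IPL = 0.30,
                        INL = 0.24, ONL = 0.03),
    n_fields = 60L,
    size_class_mix = c(round = 0.55, medium = 0.35, long = 0.10),
    orientation_sd = 15, coloc_level = 0.9,
    injected_total = 5e4, engraft_fraction = 0.56,
    fields_per_retina_scale = 2800,
    image_shape = c(360L, 720L), pixel_size = 0.6, snr = 12,
    seed = .default_seed
  ), modifyList(base, list(...)))
  if (abs(sum(p$layer_fractions) - 1) > 1e-9)
    stopf("layer_fractions must sum to 1 (got %.10f)", sum(p$layer_fractions))
  if (!all(names(p$layer_fractions) %in% p$layer_order))
    stopf("unknown layer name in layer_fractions: %s",
          paste(setdiff(names(p$layer_fractions), p$layer_order),
                collapse = ", "))
  if (abs(sum(p$size_class_mix) - 1) > 1e-9)
    stopf("size_class_mix must sum to 1")
  check_number(p$coloc_level, "coloc_level", 0, 1)
  check_number(p$engraft_fraction, "engraft_fraction", 0, 1)
  check_number(p$orientation_sd, "orientation_sd", 0)
  p$cells_per_field <-
    p$engraft_fraction * p$injected_total / p$fields_per_retina_scale
  new_preset(p, "retina_preset")
}

# ---- gel-ILM interface ------------------------------------------------------

.interface_presets <- list(
  gtn_hpa = list(attach_prob = 0.50),
  ipn75   = list(attach_prob = 0.59),
  ipn50   = list(attach_prob = 0.79)
)

#' Gel-ILM interface preset
#'
#' Attachment of a hydrogel to the inner limiting membrane along a retina
#' boundary: a correlated binary attachment process with marginal
#' probability `attach_prob` and exponentially distributed hole lengths.
#'
#' Named presets encode the measured attachment of the three formulations:
#' `"gtn_hpa"` 50%, `"ipn75"` 59%, `"ipn50"` 79%.
#'
#' @param name preset name.
#' @param ... overrides: `boundary_length` (um), `attach_prob`,
#'   `hole_length_scale` (um), `n_slides`, `pixel_size` (um/px), `seed`.
#' @return an `interface_preset` object.
#' @export
interface_preset <- function(name = "ipn50", ...) {
  base <- .interface_presets[[name]] %||% list()
  p <- modifyList(list(
    name = name, boundary_length = 600, attach_prob = 0.79,
    hole_length_scale = 30, n_slides = 10L, pixel_size = 1.0,
    seed = .default_seed
  ), modifyList(base, list(...)))
  check_number(p$attach_prob, "attach_prob", 0, 1)
  check_number(p$boundary_length, "boundary_length", 200)
  check_number(p$hole_length_scale, "hole_length_scale", 0,
               closed_lower = FALSE)
  check_number(p$n_slides, "n_slides", 1)
  new_preset(p, "interface_preset")
}

# ---- OCT series -------------------------------------------------------------

.oct_presets <- list(
  ipn50   = list(decay_rate = 0.35, n_days = 10L),
  ipn75   = list(decay_rate = 0.55, n_days = 8L),
  gtn_hpa = list(decay_rate = 0.45, n_days = 9L)
)

#' OCT B-scan series preset
#'
#' Per-day OCT stacks: a fixed bright curved retina band plus gel islands
#' whose total above-threshold pixel count decays as
#' `gel_px_day0 * exp(-decay_rate * day)`, with per-frame multiplicative
#' speckle and small random translations (to exercise registration).
#'
#' @param name preset name (`"ipn50"`, `"ipn75"`, `"gtn_hpa"`).
#' @param ... overrides: `image_shape`, `retina_foreground_px`,
#'   `gel_px_day0`, `decay_rate` (1/day), `n_days`, `speckle_sd`,
#'   `n_frames`, `max_shift_px`, `seed`.
#' @return an `oct_preset` object.
#' @export
oct_preset <- function(name = "ipn50", ...) {
  base <- .oct_presets[[name]] %||% list()
  p <- modifyList(list(
    name = name, image_shape = c(256L, 256L),
    retina_foreground_px = 12000L, gel_px_day0 = 3000L,
    decay_rate = 0.35, n_days = 10L, speckle_sd = 0.10,
    n_frames = 5L, max_shift_px = 4L, seed = .default_seed
  ), modifyList(base, list(...)))
  check_number(p$n_days, "n_days", 1)
  check_number(p$decay_rate, "decay_rate", 0)
  check_number(p$speckle_sd, "speckle_sd", 0)
  check_number(p$gel_px_day0, "gel_px_day0", 0)
  new_preset(p, "oct_preset")
}
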