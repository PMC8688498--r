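# In vivo engraftment quantification: layer annotation handling,
# cell orientation relative to its layer, layer assignment, size-class
# polar analysis, and engrafted-percentage extrapolation.

#' Retinal layer annotation
#'
#' Wraps an integer layer mask (values index `layers`, 0 = unannotated
#' background) with per-layer moments-equivalent ellipse orientations,
#' used as the reference angle when measuring cell orientation.
#'
#' @param mask integer matrix; value k marks pixels of `layers[k]`.
#' @param layers ordered layer names (vitreous to outer retina).
#' @param pixel_size um per pixel.
#' @return a `layer_annotation` object: `mask`, `layers`, `angles` (named,
#'   degrees), `pixel_size`.
#' @export
layer_annotation <- function(mask, layers, pixel_size) {
  storage.mode(mask) <- "integer"
  if (max(mask) > length(layers)) stopf("mask value exceeds layer count")
  angles <- vapply(seq_along(layers), function(k) {
    px <- which(mask == k, arr.ind = TRUE)
    if (nrow(px) < 2L) return(NA_real_)
    moments_ellipse(px)$angle
  }, numeric(1))
  names(angles) <- layers
  structure(list(mask = mask, layers = layers, angles = angles,
                 pixel_size = pixel_size), class = "layer_annotation")
}

#' Assign a cell to a retinal layer
#'
#' The layer with maximum pixel overlap wins; exact ties are broken by the
#' layer containing the cell centroid; zero overlap with any annotated
#' layer yields `"background"`.
#'
#' @param px 2-column matrix of cell pixel coordinates (`row`, `col`).
#' @param annotation a [layer_annotation()].
#' @return layer name (character).
#' @export
assign_layer <- function(px, annotation) {
  stopifnot(inherits(annotation, "layer_annotation"))
  vals <- annotation$mask[px]
  vals <- vals[vals > 0]
  if (!length(vals)) return("background")
  counts <- tabulate(vals, nbins = length(annotation$layers))
  best <- which(counts == max(counts))
  if (length(best) > 1L) {
    ctr <- round(colMeans(px))
    ctr_layer <- annotation$mask[ctr[1], ctr[2]]
    if (ctr_layer %in% best) best <- ctr_layer else best <- best[1]
  }
  annotation$layers[best[1]]
}

#' Cell extent and orientation relative to its layer
#'
#' The cell angle is the major-axis angle of the moments-equivalent
#' ellipse of the pixel set; the orientation is the difference to the
#' layer's ellipse angle, wrapped to \[-90, 90\] degrees.  The extent r is
#' the maximum Feret (caliper) diameter in um — the total reach of the
#' cell body plus processes.
#'
#' @param px 2-column matrix of cell pixel coordinates (>= 5 px).
#' @param annotation a [layer_annotation()].
#' @param layer the layer the cell is assigned to (see [assign_layer()]).
#' @return list: `r_um`, `theta_deg`, `cell_angle_deg`, `degenerate`.
#' @export
fit_orientation <- function(px, annotation, layer) {
  if (nrow(px) < 5L) stopf("cell needs >= 5 pixels")
  me <- moments_ellipse(px)
  layer_angle <- annotation$angles[layer]
  if (is.na(layer_angle)) layer_angle <- 0
  list(r_um = feret_diameter(px) * annotation$pixel_size,
       theta_deg = unname(wrap_angle(me$angle - layer_angle)),
       cell_angle_deg = me$angle,
       degenerate = me$degenerate)
}

#' Size class of a cell from its Feret extent
#'
#' Round (undifferentiated) r <= 30 um, medium process extension
#' 30 < r <= 150 um, long process extension r > 150 um; the boundary
#' values are assigned to the lower class.
#'
#' @param r_um Feret extent, um (vectorized).
#' @return factor with levels round, medium, long.
#' @export
size_class <- function(r_um) {
  cut(r_um, breaks = c(-Inf, 30, 150, Inf),
      labels = c("round", "medium", "long"))
}

#' Analyze one annotated retina field
#'
#' Segments the reporter channel with [fusion_segment()], assigns every
#' detected cell to a layer and measures its Feret extent, orientation
#' relative to the layer, and size class.
#'
#' @param channels named list with at least a `reporter` matrix (and
#'   typically `human`).
#' @param annotation a [layer_annotation()].
#' @param low,high fusion-segmentation thresholds.
#' @param min_cell_px cells smaller than this are dropped (same rationale
#'   as the viability pipeline's small-object rule).
#' @return data.frame: `label`, `layer`, `r_um`, `theta_deg`,
#'   `size_class`, `area_px`.
#' @export
analyze_retina_field <- function(channels, annotation, low = 0.10,
                                 high = 0.30, min_cell_px = 10L) {
  seg <- fusion_segment(channels$reporter,
                        pixel_size = annotation$pixel_size,
                        low = low, high = high)
  if (seg$n_objects == 0L)
    return(data.frame(label = integer(0), layer = character(0),
                      r_um = numeric(0), theta_deg = numeric(0),
                      size_class = character(0), area_px = integer(0)))
  idx <- which(seg$labels > 0, arr.ind = TRUE)
  lab <- seg$labels[seg$labels > 0]
  rows <- lapply(seq_len(seg$n_objects), function(k) {
    px <- idx[lab == k, , drop = FALSE]
    if (nrow(px) < min_cell_px) return(NULL)
    layer <- assign_layer(px, annotation)
    fo <- fit_orientation(px, annotation,
                          if (layer == "background") annotation$layers[1]
                          else layer)
    data.frame(label = k, layer = layer, r_um = fo$r_um,
               theta_deg = fo$theta_deg,
               size_class = as.character(size_class(fo$r_um)),
               area_px = nrow(px))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(0), layer = character(0),
                      r_um = numeric(0), theta_deg = numeric(0),
                      size_class = character(0), area_px = integer(0))
  out
}

#' Summarize engraftment across fields
#'
#' Per-layer percentages over all assigned cells, the engrafted
#' percentage of the injected dose (mean per-field count scaled by
#' `fields_per_retina_scale`, divided by `injected_total`), and the polar
#' (r, theta) table per size class.
#'
#' @param cell_tables list of per-field cell tables from
#'   [analyze_retina_field()].
#' @param injected_total number of injected cells (default 5e4).
#' @param fields_per_retina_scale scale constant converting a mean
#'   per-field count into a whole-retina count; must match the assumption
#'   under which the fields sample the injection region.
#' @param layers layer-name order for the percentage table.
#' @return list: `per_layer_percent` (named), `layer_counts`,
#'   `percent_engrafted_of_injected`, `n_fields`, `n_cells`,
#'   `mean_cells_per_field`, `polar` (data.frame `size_class`, `r_um`,
#'   `theta_deg`).
#' @export
summarize_engraftment <- function(cell_tables, injected_total = 5e4,
                                  fields_per_retina_scale = 1,
                                  layers = c("vitreous", "GCL", "IPL",
                                             "INL", "ONL")) {
  if (!length(cell_tables)) stopf("need >= 1 field")
  all_cells <- do.call(rbind, cell_tables)
  n_per_field <- vapply(cell_tables, nrow, integer(1))
  if (is.null(all_cells) || nrow(all_cells) == 0L) {
    warnf("zero cells across all fields")
    pl <- setNames(rep(0, length(layers)), layers)
    return(list(per_layer_percent = pl, layer_counts = pl,
                percent_engrafted_of_injected = 0,
                n_fields = length(cell_tables), n_cells = 0L,
                mean_cells_per_field = 0,
                polar = data.frame(size_class = character(0),
                                   r_um = numeric(0),
                                   theta_deg = numeric(0))))
  }
  counts <- vapply(layers, function(l) sum(all_cells$layer == l), numeric(1))
  assigned <- sum(counts)
  per_layer <- if (assigned > 0) 100 * counts / assigned else counts
  list(per_layer_percent = per_layer,
       layer_counts = counts,
       percent_engrafted_of_injected =
         100 * mean(n_per_field) * fields_per_retina_scale / injected_total,
       n_fields = length(cell_tables),
       n_cells = nrow(all_cells),
       mean_cells_per_field = mean(n_per_field),
       polar = all_cells[, c("size_class", "r_um", "theta_deg")])
}
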