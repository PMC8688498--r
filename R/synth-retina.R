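# Synthetic annotated retina cross-sections with engrafted cells.
#
# Each field is a stack of tilted layer bands (vitreous, GCL, IPL, INL,
# ONL) with engrafted cells drawn per preset: layer from layer_fractions,
# size class from size_class_mix (round < 30 um, medium 30-150 um, long
# > 150 um Feret extent), orientation relative to the layer from
# N(0, orientation_sd) for elongated cells.  Cells appear in the reporter
# channel in full and in the human-marker channel over a coloc_level
# fraction of their pixels (trimmed from one end, so blurring cannot fill
# the gap back in).  The expected cell count per field is
# engraft_fraction * injected_total / fields_per_retina_scale.

wrap_angle <- function(x) {
  w <- ((x + 90) %% 180) - 90
  ifelse(w == -90 & x > 0, 90, w)
}

# band thicknesses (px) for a 300-px-high section; rescaled for other sizes
.layer_thickness <- c(vitreous = 50, GCL = 60, IPL = 60, INL = 70, ONL = 60)

make_layer_bands <- function(dim, tilt_deg, layer_order) {
  th <- .layer_thickness[layer_order]
  th <- th / sum(th) * dim[1]
  cuts <- cumsum(th)
  slope <- tan(tilt_deg * pi / 180)
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  u <- rows - slope * (cols - dim[2] / 2)
  mask <- matrix(findInterval(u, c(-Inf, cuts[-length(cuts)])), dim[1])
  storage.mode(mask) <- "integer"
  mask
}

# Rejection-samples a position for one cell inside its layer band.  If a
# steeply-tilted elongated cell cannot be placed (its perpendicular reach
# pins it to a mid-band strip already occupied), the orientation is
# annealed toward the layer direction and retried; the returned theta is
# the one actually rendered.
place_one_cell <- function(dim, band_u, slope, L_px, W_px, theta_rel,
                           tilt_deg, occ, border = 9L) {
  for (round in 1:6) {
    ang_abs <- tilt_deg + theta_rel
    half_h <- L_px / 2 * abs(sin(theta_rel * pi / 180)) + W_px / 2
    half_w <- L_px / 2 * abs(cos(ang_abs * pi / 180)) + W_px / 2
    u_lo <- band_u[1] + half_h + 2
    u_hi <- band_u[2] - half_h - 2
    if (u_lo > u_hi) { u_lo <- u_hi <- mean(band_u) }
    c_lo <- border + half_w
    c_hi <- dim[2] - border - half_w
    for (try in 1:120) {
      cc <- if (c_lo < c_hi) runif(1, c_lo, c_hi) else dim[2] / 2
      uu <- runif(1, u_lo, u_hi)
      rr <- uu + slope * (cc - dim[2] / 2)
      px <- ellipse_pixels(dim, c(rr, cc), L_px / 2, W_px / 2, ang_abs)
      if (nrow(px) == 0L) next
      if (any(px[, 1] <= border) || any(px[, 1] > dim[1] - border) ||
          any(px[, 2] <= border) || any(px[, 2] > dim[2] - border)) next
      guard <- ellipse_pixels(dim, c(rr, cc), L_px / 2 + 10, W_px / 2 + 10,
                              ang_abs)
      if (any(occ[px_index(dim, guard)])) next
      return(list(px = px, guard = guard, center = c(rr, cc),
                  angle_abs = ang_abs, theta_rel = theta_rel))
    }
    theta_rel <- theta_rel * 0.5
  }
  NULL
}

#' Render synthetic annotated retina sections
#'
#' Generates `n_fields` two-channel fields (human marker + reporter) with
#' layer-annotation masks and a ground-truth cell table, under the layer
#' occupancy, size-class mix, orientation spread, co-localization level and
#' engraftment fraction of the preset.
#'
#' @param preset a [retina_preset()].
#' @param n_fields optional override of the preset field count.
#' @param seed optional override of the preset seed.
#' @return list: `fields` (each with `channels` = list(`human`,
#'   `reporter`), `layer_mask` (a [layer_annotation()]), `truth`
#'   data.frame), `truth` (all fields combined), `pixel_size`, `preset`.
#' @export
render_retina_sections <- function(preset, n_fields = NULL, seed = NULL) {
  stopifnot(inherits(preset, "retina_preset"))
  nf <- as.integer(n_fields %||% preset$n_fields)
  dim <- as.integer(preset$image_shape)
  ps <- preset$pixel_size
  layers <- preset$layer_order
  lf <- preset$layer_fractions[layers]
  lf[is.na(lf)] <- 0
  mix <- preset$size_class_mix

  with_seed(seed %||% preset$seed, {
    fields <- vector("list", nf)
    for (f in seq_len(nf)) {
      tilt <- runif(1, -8, 8)
      slope <- tan(tilt * pi / 180)
      mask <- make_layer_bands(dim, tilt, layers)
      th <- .layer_thickness[layers] / sum(.layer_thickness[layers]) * dim[1]
      cuts <- c(0, cumsum(th))
      occ <- matrix(FALSE, dim[1], dim[2])
      reporter <- matrix(0, dim[1], dim[2])
      human <- matrix(0, dim[1], dim[2])
      n_cells <- rpois(1, preset$cells_per_field)
      truth <- NULL
      # draw all cell specs first, then place largest-first so long
      # processes find room before the field fills up
      cls_all <- sample(names(mix), n_cells, replace = TRUE, prob = mix)
      L_all <- vapply(cls_all, function(cl) switch(cl,
        round = runif(1, 8, 22), medium = runif(1, 38, 105),
        long = runif(1, 153, 170)), numeric(1))
      ord <- order(L_all, decreasing = TRUE)
      for (i in ord) {
        layer <- sample(layers, 1, prob = lf)
        band_u <- cuts[match(layer, layers) + c(0, 1)]
        cls <- cls_all[i]
        L_um <- L_all[i]
        if (cls == "round") {
          W_um <- L_um * runif(1, 0.8, 1)
          theta <- runif(1, -90, 90)
        } else if (cls == "medium") {
          W_um <- runif(1, 7, 12)
          theta <- rnorm(1, 0, preset$orientation_sd)
        } else {
          W_um <- runif(1, 7, 12)
          theta <- rnorm(1, 0, min(preset$orientation_sd, 5))
        }
        # containment: elongated cells cannot protrude from their band
        if (cls != "round") {
          band_half <- diff(band_u) / 2 - W_um / ps / 2 - 4
          smax <- clamp(band_half / (L_um / ps / 2), 0.05, 1)
          tmax <- asin(smax) * 180 / pi
          theta <- clamp(theta, -tmax, tmax)
        }
        pl <- place_one_cell(dim, band_u, slope, L_um / ps, W_um / ps,
                             theta, tilt, occ)
        if (is.null(pl)) next  # packing failure: cell dropped from truth too
        occ[px_index(dim, pl$guard)] <- TRUE
        reporter[px_index(dim, pl$px)] <- 0.7
        # human channel covers coloc_level of the cell, trimmed at one end
        proj <- (pl$px[, 2] - pl$center[2]) * cos(pl$angle_abs * pi / 180) +
                (pl$px[, 1] - pl$center[1]) * sin(pl$angle_abs * pi / 180)
        keep <- proj <= quantile(proj, preset$coloc_level, names = FALSE)
        human[px_index(dim, pl$px[keep, , drop = FALSE])] <- 0.7
        truth <- rbind(truth, data.frame(
          field = f, id = i, layer = layer, size_class = cls,
          r_um = L_um, theta_deg = pl$theta_rel, angle_abs = pl$angle_abs,
          row = pl$center[1], col = pl$center[2], area_px = nrow(pl$px)))
      }
      if (is.null(truth))
        truth <- data.frame(field = integer(0), id = integer(0),
                            layer = character(0), size_class = character(0),
                            r_um = numeric(0), theta_deg = numeric(0),
                            angle_abs = numeric(0), row = numeric(0),
                            col = numeric(0), area_px = integer(0))
      fields[[f]] <- list(
        channels = list(human = finish_channel(human, preset$snr),
                        reporter = finish_channel(reporter, preset$snr)),
        layer_mask = layer_annotation(mask, layers, ps),
        truth = truth,
        tilt_deg = tilt)
    }
    list(fields = fields,
         truth = do.call(rbind, lapply(fields, `[[`, "truth")),
         pixel_size = ps, preset = preset)
  })
}
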