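#' Render a synthetic live/dead fluorescence field
#'
#' Draws `n_live` cells in the "live" channel and `n_dead` in the "dead"
#' channel as Gaussian-smoothed discs or ellipses over a noisy background
#' at the preset SNR, with the ground-truth object table alongside.  Cells
#' are placed by rejection sampling with a minimum separation so that, at
#' high SNR, the segmentation pipeline can recover the exact counts.
#'
#' @param preset a [field_preset()].
#' @param seed optional override of the preset seed.
#' @return list: `channels` (named list of matrices `live`, `dead`),
#'   `truth` (data.frame: `id`, `channel`, `row`, `col`, `x_um`, `y_um`,
#'   `radius_um`, `elongated`, `area_px`), `pixel_size`, `preset`.
#' @export
render_field <- function(preset, seed = NULL) {
  stopifnot(inherits(preset, "field_preset"))
  dim <- as.integer(preset$image_shape)
  ps <- preset$pixel_size
  r_px <- preset$cell_radius_range / ps
  margin <- ceiling(max(r_px) * 2.5) + 2L
  if (margin * 2 >= min(dim))
    stopf("cells too large for the image")
  n_total <- preset$n_live + preset$n_dead
  # packing bound: total footprint must stay below ~30% of the frame
  if (n_total * pi * mean(r_px)^2 > 0.3 * prod(dim))
    stopf("cell count too high to place without exceeding the packing bound")

  with_seed(seed %||% preset$seed, {
    canvas <- list(live = matrix(0, dim[1], dim[2]),
                   dead = matrix(0, dim[1], dim[2]))
    chan <- rep(c("live", "dead"), c(preset$n_live, preset$n_dead))
    truth <- NULL
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    gap_px <- 6
    for (i in seq_len(n_total)) {
      rad <- runif(1, r_px[1], r_px[2])
      elong <- runif(1) < preset$elongation_fraction
      reach <- if (elong) rad * 1.8 else rad
      placed <- FALSE
      for (try in 1:500) {
        ctr <- c(runif(1, margin, dim[1] - margin),
                 runif(1, margin, dim[2] - margin))
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - ctr[1])^2 +
                     (centers[, 2] - ctr[2])^2) >=
                radii + reach + gap_px)) {
          placed <- TRUE; break
        }
      }
      if (!placed) stopf("failed to place cell %d without overlap", i)
      centers <- rbind(centers, ctr)
      radii <- c(radii, reach)
      a <- if (elong) rad * 1.8 else rad
      b <- if (elong) rad * 0.7 else rad
      ang <- runif(1, -90, 90)
      px <- ellipse_pixels(dim, ctr, a, b, ang)
      canvas[[chan[i]]][px_index(dim, px)] <- 0.7
      truth <- rbind(truth, data.frame(
        id = i, channel = chan[i], row = ctr[1], col = ctr[2],
        x_um = (ctr[2] - 1) * ps, y_um = (ctr[1] - 1) * ps,
        radius_um = rad * ps, elongated = elong, area_px = nrow(px)))
    }
    channels <- lapply(canvas, finish_channel, snr = preset$snr)
    if (is.null(truth))
      truth <- data.frame(id = integer(0), channel = character(0),
                          row = numeric(0), col = numeric(0),
                          x_um = numeric(0), y_um = numeric(0),
                          radius_um = numeric(0), elongated = logical(0),
                          area_px = integer(0))
    list(channels = channels, truth = truth, pixel_size = ps,
         preset = preset)
  })
}
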