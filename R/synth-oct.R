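#' Render a synthetic per-day OCT B-scan series
#'
#' Each day's stack shares a fixed bright curved retina band (close to
#' `retina_foreground_px` above-threshold pixels) plus bright gel islands
#' totalling `gel_px_day0 * exp(-decay_rate * day)` pixels, with
#' multiplicative speckle and a small random integer translation per frame
#' (the first frame of each day is unshifted) to exercise registration.
#'
#' @param preset an [oct_preset()].
#' @param seed optional override.
#' @return list: `stacks` (list over days of 3D arrays row x col x frame),
#'   `truth` (data.frame `day`, `gel_px`, `normalized_mass`),
#'   `control` (a gel-free stack for baseline estimation), `preset`.
#' @export
render_oct_series <- function(preset, seed = NULL) {
  stopifnot(inherits(preset, "oct_preset"))
  d <- as.integer(preset$image_shape)
  days <- 0:(preset$n_days - 1L)

  with_seed(seed %||% preset$seed, {
    # retina: curved band, thickness set by the target foreground count
    x <- seq_len(d[2])
    mid <- round(d[1] * 0.6 - d[1] * 0.12 *
                   sin(pi * x / d[2]))       # gentle upward bow
    half <- max(1L, round(preset$retina_foreground_px / d[2] / 2))
    retina <- matrix(0, d[1], d[2])
    for (cx in x) {
      rr <- clamp((mid[cx] - half):(mid[cx] + half - 1L), 1L, d[1])
      retina[rr, cx] <- 0.85
    }

    gel_canvas <- function(target_px) {
      g <- matrix(0, d[1], d[2])
      placed <- 0
      guard <- 0L
      top_limit <- min(mid) - half - 3  # islands stay above the retina
      while (placed < target_px && guard < 200L) {
        guard <- guard + 1L
        a <- runif(1, 4, 14)
        b <- runif(1, 3, min(9, max(3, (top_limit - 8) / 2)))
        cx <- runif(1, 16, d[2] - 16)
        cy <- runif(1, b + 4, max(b + 5, top_limit - b))
        px <- ellipse_pixels(d, c(cy, cx), a, b, runif(1, -20, 20))
        if (!nrow(px)) next
        px <- px[px[, 1] < top_limit, , drop = FALSE]
        idx <- px_index(d, px)
        idx <- idx[g[idx] == 0]  # count only newly covered pixels
        if (!length(idx)) next
        take <- min(length(idx), target_px - placed)
        g[idx[seq_len(take)]] <- 0.8
        placed <- placed + take
      }
      g
    }

    render_stack <- function(gel) {
      base <- clamp(retina + gel + 0.04, 0, 1)
      frames <- array(0, c(d, preset$n_frames))
      for (k in seq_len(preset$n_frames)) {
        sh <- if (k == 1L) c(0L, 0L) else
          sample(seq(-preset$max_shift_px, preset$max_shift_px), 2,
                 replace = TRUE)
        img <- matrix(0, d[1], d[2])
        src_r <- seq_len(d[1]) - sh[1]; src_c <- seq_len(d[2]) - sh[2]
        vr <- src_r >= 1 & src_r <= d[1]; vc <- src_c >= 1 & src_c <= d[2]
        img[vr, vc] <- base[src_r[vr], src_c[vc]]
        speck <- matrix(rnorm(prod(d), 1, preset$speckle_sd), d[1])
        frames[, , k] <- clamp(img * speck, 0, 1)
      }
      frames
    }

    truth_px <- round(preset$gel_px_day0 * exp(-preset$decay_rate * days))
    stacks <- lapply(truth_px, function(px) render_stack(gel_canvas(px)))
    control <- render_stack(matrix(0, d[1], d[2]))
    list(stacks = stacks,
         truth = data.frame(
           day = days, gel_px = truth_px,
           normalized_mass = if (truth_px[1] > 0) truth_px / truth_px[1]
                             else rep(0, length(days))),
         control = control, preset = preset)
  })
}
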