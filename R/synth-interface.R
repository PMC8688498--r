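#' Render synthetic gel-ILM interface slides
#'
#' Generates, per slide, a gently curved retina boundary with a correlated
#' binary attachment process along its arc length: attached stretches and
#' holes alternate with exponentially distributed lengths, the hole scale
#' set by `hole_length_scale` and the attached scale chosen so the marginal
#' attachment probability equals `attach_prob`.  The 2D masks place gel
#' pixels touching the boundary exactly where the flags are true.
#'
#' @param preset an [interface_preset()].
#' @param n_slides optional override.
#' @param seed optional override.
#' @return list: `slides` (each with `gel_mask`, `retina_mask`, logical
#'   matrices; `flags`, the ground-truth per-um attachment flags;
#'   `boundary_row` per column), `pixel_size`, `preset`.
#' @export
render_interface <- function(preset, n_slides = NULL, seed = NULL) {
  stopifnot(inherits(preset, "interface_preset"))
  ns <- as.integer(n_slides %||% preset$n_slides)
  ps <- preset$pixel_size
  W <- ceiling(preset$boundary_length / ps)
  H <- max(60L, ceiling(W / 4))
  p <- preset$attach_prob
  attach_scale <- if (p >= 1) Inf else preset$hole_length_scale * p / (1 - p)

  with_seed(seed %||% preset$seed, {
    slides <- lapply(seq_len(ns), function(s) {
      # boundary: gentle sinusoidal undulation around mid-height
      x <- seq_len(W)
      phase <- runif(1, 0, 2 * pi)
      amp <- runif(1, 2, H / 10)
      boundary <- round(H / 2 + amp * sin(2 * pi * x / W + phase))
      boundary <- clamp(boundary, 6L, H - 2L)
      # alternating attached/hole runs along the arc (um scale)
      n_steps <- ceiling(W * ps)
      flags <- logical(0)
      state <- runif(1) < p
      while (length(flags) < n_steps) {
        len <- if (state) {
          if (!is.finite(attach_scale)) n_steps else
            max(1L, round(rexp(1, 1 / attach_scale)))
        } else max(1L, round(rexp(1, 1 / preset$hole_length_scale)))
        if (p == 0) { state <- FALSE; len <- n_steps }
        if (p == 1) { state <- TRUE; len <- n_steps }
        flags <- c(flags, rep(state, len))
        state <- !state
      }
      flags <- flags[seq_len(n_steps)]
      retina <- matrix(FALSE, H, W)
      gel <- matrix(FALSE, H, W)
      for (cx in seq_len(W)) {
        retina[boundary[cx]:H, cx] <- TRUE
        # flag governing this column, by arc position in um
        fl <- flags[clamp(ceiling(cx * ps), 1, n_steps)]
        if (fl) gel[max(1, boundary[cx] - 3):(boundary[cx] - 1), cx] <- TRUE
      }
      list(gel_mask = gel, retina_mask = retina, flags = flags,
           boundary_row = boundary)
    })
    list(slides = slides, pixel_size = ps, preset = preset)
  })
}
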