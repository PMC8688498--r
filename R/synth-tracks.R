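# Synthetic bead tracks in a gelling medium.
#
# The tracer increments are drawn from a locally-stationary fractional
# Gaussian noise: a zero-mean Gaussian process whose covariance between
# steps i and j is the fGn autocovariance evaluated at the pairwise-mean
# local Hurst exponent H_ij = (H_i + H_j)/2, with per-step variance
# dt^(2 H_i).  Where the exponent is locally constant this is exactly fGn,
# so the windowed MSD scales as tau^alpha(t) with alpha(t) = 2 H(t), and
# alpha(t) = 0.5 corresponds to the storage/loss modulus crossover under
# the generalized Stokes-Einstein relation.

# fGn autocovariance at integer lag k for Hurst exponent h (unit variance)
fgn_autocov <- function(k, h) {
  k <- abs(k)
  p <- function(x) ifelse(x <= 0, 0, exp((2 * h) * log(pmax(x, 1e-300))))
  0.5 * (p(k + 1) - 2 * p(k) + p(k - 1))
}

#' Simulate tracer-bead tracks in a gelling medium
#'
#' Generates 2D Brownian-to-subdiffusive bead trajectories whose local
#' anomalous-diffusion exponent follows
#' \deqn{\alpha(t) = \alpha_{gel} + (\alpha_{liq} - \alpha_{gel})\,
#'       \mathrm{logistic}((t_{gel} - t)/w),}
#' crossing the critical value 0.5 exactly at the preset gel point.  Within
#' any short window centred at wall time t the windowed MSD scales as
#' \eqn{\tau^{\alpha(t)}}, so the microrheology pipeline's gel-point
#' estimate can be scored against `t_gel`.
#'
#' @param preset a [gelation_preset()].
#' @param seed optional override of the preset seed.
#' @return list with components `tracks` (data.frame: `particle`, `t_s`,
#'   `x_um`, `y_um`), `alpha` (data.frame: `t`, `alpha`, the ground-truth
#'   exponent curve) and `preset`.
#' @examples
#' sim <- simulate_gelation_tracks(gelation_preset("gtn_hpa", duration = 60,
#'                                                 t_gel = 30, n_beads = 3))
#' head(sim$tracks)
#' @export
simulate_gelation_tracks <- function(preset, seed = NULL) {
  stopifnot(inherits(preset, "gelation_preset"))
  dt <- preset$frame_interval
  if (preset$duration <= 2 * dt)
    stopf("invalid preset: duration must exceed 2 * frame_interval")
  n <- round(preset$duration / dt)
  tt <- (1:n) * dt
  alpha <- preset$alpha_gel + (preset$alpha_liquid - preset$alpha_gel) *
    logistic((preset$t_gel - tt) / preset$transition_width)
  H <- alpha / 2
  nb <- as.integer(preset$n_beads)

  X <- with_seed(seed %||% preset$seed, {
    if (preset$msd_amplitude == 0) {
      matrix(0, n, 2L * nb)
    } else {
      K <- abs(outer(seq_len(n), seq_len(n), "-"))
      Hm <- outer(H, H, "+") / 2
      G <- fgn_autocov(K, Hm)
      diag(G) <- 1
      C <- G * exp((2 * Hm) * log(dt))
      R <- tryCatch(chol(C),
                    error = function(e) chol(C + diag(1e-9, n)))
      Z <- matrix(rnorm(n * 2L * nb), n, 2L * nb)
      # per-axis variance amp/2 so the 2D MSD amplitude equals msd_amplitude
      dX <- crossprod(R, Z) * sqrt(preset$msd_amplitude / 2)
      X <- apply(dX, 2, cumsum)
      if (preset$localization_sd > 0)
        X <- X + matrix(rnorm(length(X), sd = preset$localization_sd),
                        nrow = n)
      X
    }
  })

  tracks <- data.frame(
    particle = rep(seq_len(nb), each = n),
    t_s = rep(tt, nb),
    x_um = as.vector(X[, seq(1L, 2L * nb, by = 2L)]),
    y_um = as.vector(X[, seq(2L, 2L * nb, by = 2L)])
  )
  list(tracks = tracks,
       alpha = data.frame(t = tt, alpha = alpha),
       preset = preset)
}
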