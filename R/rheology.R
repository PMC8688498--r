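# Passive microrheology and oscillatory-rheology analysis.
#
# Pipeline: bead tracks -> (windowed) mean square displacement -> local
# power-law exponent and modulus via the generalized Stokes-Einstein
# relation (Mason form) -> storage/loss moduli -> gel point at the G'=G''
# crossover (equivalently alpha = 0.5).

#' GSER parameters
#'
#' Bead radius, temperature and tracking dimensionality used to convert an
#' MSD into a complex shear modulus.  Defaults: 7.5 um bead radius (10-20 um
#' diameter PLGA microbeads, midpoint) and 310.15 K (37 C).
#'
#' @param bead_radius bead radius, um.
#' @param temperature absolute temperature, K.
#' @param dimensionality 2 for planar tracking (MSD converted to 3D by the
#'   isotropy factor 3/2) or 3 for volumetric MSD.
#' @return a `gser_params` object.
#' @export
gser_params <- function(bead_radius = 7.5, temperature = 310.15,
                        dimensionality = 2) {
  check_number(bead_radius, "bead_radius", 0, closed_lower = FALSE)
  check_number(temperature, "temperature", 0, closed_lower = FALSE)
  if (!dimensionality %in% c(2, 3))
    stopf("dimensionality must be 2 or 3")
  structure(list(bead_radius = bead_radius, temperature = temperature,
                 dimensionality = dimensionality), class = "gser_params")
}

validate_tracks <- function(tracks) {
  need <- c("particle", "t_s", "x_um", "y_um")
  if (!all(need %in% names(tracks)))
    stopf("tracks must have columns %s", paste(need, collapse = ", "))
  sp <- split(tracks, tracks$particle)
  dts <- unlist(lapply(sp, function(d) diff(d$t_s)))
  if (any(vapply(sp, nrow, 1L) < 3L))
    stopf("each track needs >= 3 samples")
  if (any(dts <= 0)) stopf("track times must be strictly increasing")
  dt <- median(dts)
  if (any(abs(dts - dt) > 0.01 * dt))
    stopf("tracks must share a uniform frame interval (within 1%%)")
  dt
}

#' Mean square displacement from particle tracks
#'
#' All-ordered-pairs MSD estimator, averaged over particles:
#' \eqn{MSD(\tau) = \langle |r(t+\tau) - r(t)|^2 \rangle}.  With `window`
#' set, the MSD is computed per sliding window of that width, centred every
#' `every` seconds, for time-resolved microrheology of an evolving medium.
#'
#' @param tracks data.frame with columns `particle`, `t_s`, `x_um`, `y_um`;
#'   all tracks must share a uniform frame interval.
#' @param max_lag largest lag time to evaluate, s.
#' @param window optional sliding-window width, s.
#' @param every spacing of window centres, s (default 2, the sampling
#'   cadence of the oscillatory-rheology reference measurements).
#' @return With `window = NULL`: a data.frame (`lag`, `msd`, `n_pairs`).
#'   Otherwise a list of such data.frames, each with a `window_center`
#'   attribute (also exposed as a `window_center` column).
#' @examples
#' tr <- data.frame(particle = 1, t_s = 0:2,
#'                  x_um = c(0, 1, 1), y_um = c(0, 0, 1))
#' compute_msd(tr, max_lag = 2)  # MSD(1) = 1, MSD(2) = 2
#' @export
compute_msd <- function(tracks, max_lag, window = NULL, every = 2) {
  dt <- validate_tracks(tracks)
  sp <- split(tracks, tracks$particle)
  n <- min(vapply(sp, nrow, 1L))
  X <- vapply(sp, function(d) d$x_um[seq_len(n)], numeric(n))
  Y <- vapply(sp, function(d) d$y_um[seq_len(n)], numeric(n))
  tt <- sp[[1]]$t_s[seq_len(n)]
  L <- min(floor(max_lag / dt), n - 1L)
  if (L < 1L) stopf("max_lag below one frame interval")

  # per-start-time squared displacement at each lag, averaged over beads
  d2 <- vector("list", L)
  for (l in seq_len(L)) {
    dx <- X[(1 + l):n, , drop = FALSE] - X[1:(n - l), , drop = FALSE]
    dy <- Y[(1 + l):n, , drop = FALSE] - Y[1:(n - l), , drop = FALSE]
    d2[[l]] <- rowMeans(dx^2 + dy^2)
  }

  msd_over <- function(idx_fun) {
    lag <- (seq_len(L)) * dt
    msd <- n_pairs <- numeric(L)
    for (l in seq_len(L)) {
      idx <- idx_fun(l)
      n_pairs[l] <- length(idx) * ncol(X)
      msd[l] <- if (length(idx)) mean(d2[[l]][idx]) else NA_real_
    }
    keep <- n_pairs >= 1
    if (any(n_pairs < 2))
      warnf("%d lag(s) have fewer than 2 pairs", sum(n_pairs < 2))
    if (!all(keep))
      warnf("dropping %d lag(s) with no pairs", sum(!keep))
    data.frame(lag = lag[keep], msd = msd[keep], n_pairs = n_pairs[keep])
  }

  if (is.null(window))
    return(msd_over(function(l) seq_len(n - l)))

  centers <- seq(tt[1] + window / 2, tt[n] - window / 2, by = every)
  if (!length(centers)) stopf("window wider than the track duration")
  lapply(centers, function(tc) {
    out <- msd_over(function(l) {
      which(tt[seq_len(n - l)] >= tc - window / 2 &
            tt[seq_len(n - l) + l] <= tc + window / 2)
    })
    out$window_center <- tc
    attr(out, "window_center") <- tc
    out
  })
}

#' Double-exponential decay fit
#'
#' Least-squares fit of \eqn{y(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + c}
#' with non-negative amplitudes, using log-spaced multi-start initialisation
#' of the two time constants.  Returned in canonical order
#' \eqn{\tau_1 \le \tau_2}; ties between starts broken by lowest RSS, then
#' lowest \eqn{\tau_1}.
#'
#' @param t,y numeric vectors (>= 6 points, y >= 0).
#' @param n_starts number of log-spaced starting values per time constant.
#' @return list: `a1`, `a2`, `tau1`, `tau2`, `c`, `rss`.
#' @export
fit_double_exponential <- function(t, y, n_starts = 6) {
  stopifnot(length(t) == length(y))
  if (length(t) < 6L) stopf("need >= 6 points")
  if (any(y < 0)) stopf("y must be non-negative")
  if (sd(y) == 0)
    return(list(a1 = 0, a2 = 0, tau1 = diff(range(t)) %||% 1,
                tau2 = diff(range(t)), c = y[1], rss = 0))
  dt <- min(diff(sort(unique(t))))
  span <- diff(range(t))
  taus <- exp(seq(log(max(dt, 1e-6)), log(span), length.out = n_starts))
  best <- NULL
  for (tau1 in taus) for (tau2 in taus) {
    if (tau2 < tau1) next
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + c,
        start = list(a1 = max(y) / 2, a2 = max(y) / 2,
                     tau1 = tau1, tau2 = tau2, c = min(y)),
        lower = c(0, 0, dt / 100, dt / 100, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    cf <- as.list(coef(fit))
    if (cf$tau1 > cf$tau2) {
      cf <- list(a1 = cf$a2, a2 = cf$a1, tau1 = cf$tau2, tau2 = cf$tau1,
                 c = cf$c)
    }
    cand <- c(cf, rss = rss)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && cf$tau1 < best$tau1))
      best <- cand
  }
  if (is.null(best))
    stopf("double-exponential fit failed to converge from any start")
  best
}

#' MSD to complex moduli via the generalized Stokes-Einstein relation
#'
#' Fits \eqn{\ln MSD} vs \eqn{\ln \tau} with a second-order polynomial; the
#' local power-law exponent \eqn{\alpha} is its first derivative at the
#' evaluation lag (the geometric mean of the curve's lag range), clamped to
#' \[0, 1\].  The modulus magnitude at frequency \eqn{1/\tau} is
#' \deqn{|G^*| = \frac{d\, k_B T}{3 \pi a\, MSD(\tau)\, \Gamma(1+\alpha)}}
#' with d the dimensionality factor (for planar tracking, d = 2 with the 2D
#' MSD — equivalent to the Mason form on the 3D MSD \eqn{= 3/2 \times} 2D).
#' Then \eqn{G' = |G^*| \cos(\pi\alpha/2)}, \eqn{G'' = |G^*| \sin(\pi\alpha/2)};
#' the gel point is the crossover, at \eqn{\alpha = 0.5}.
#'
#' @param msd_curve data.frame (`lag` s, `msd` um^2), >= 5 lags, msd > 0.
#' @param params a [gser_params()].
#' @return list: `g_prime`, `g_double_prime` (Pa), `alpha`, `g_star` (Pa),
#'   `tau` (evaluation lag, s), `unreliable` (TRUE when the raw exponent
#'   fell outside \[-0.1, 1.1\] before clamping).
#' @export
msd_to_moduli <- function(msd_curve, params = gser_params()) {
  ok <- is.finite(msd_curve$msd) & msd_curve$msd > 0
  lag <- msd_curve$lag[ok]
  msd <- msd_curve$msd[ok]
  if (length(lag) < 5L) stopf("need >= 5 positive-MSD lags")
  ll <- log(lag); lm_ <- log(msd)
  fit <- lm(lm_ ~ ll + I(ll^2))
  tau <- exp(mean(range(ll)))
  a_raw <- unname(coef(fit)[2] + 2 * coef(fit)[3] * log(tau))
  unreliable <- a_raw < -0.1 || a_raw > 1.1
  alpha <- clamp(a_raw, 0, 1)
  msd_tau <- exp(unname(predict(fit, data.frame(ll = log(tau)))))  # um^2
  d <- params$dimensionality
  g_star <- (d * .kB * params$temperature) /
    (3 * pi * (params$bead_radius * 1e-6) * (msd_tau * 1e-12) *
       gamma(1 + alpha))
  list(g_prime = g_star * cos(pi * alpha / 2),
       g_double_prime = g_star * sin(pi * alpha / 2),
       alpha = alpha, g_star = g_star, tau = tau, unreliable = unreliable)
}

#' Gel point from a storage/loss modulus trace
#'
#' The gel point is the earliest time at which G' crosses G'', located by
#' linear interpolation of G' - G'' between the bracketing samples.
#'
#' @param trace data.frame with columns `t`, `g_prime`, `g_double_prime`.
#' @return gel-point time (s), with attribute `n_crossings`.
#' @examples
#' tr <- data.frame(t = c(0, 10, 20), g_prime = c(1, 2, 4),
#'                  g_double_prime = c(3, 3, 3))
#' detect_gel_point(tr)  # 15
#' @export
detect_gel_point <- function(trace) {
  stopifnot(all(c("t", "g_prime", "g_double_prime") %in% names(trace)))
  d <- trace$g_prime - trace$g_double_prime
  s <- sign(d)
  cross <- which(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0)
  zero <- which(s == 0)
  if (!length(cross) && !length(zero))
    stopf("no G' = G'' crossing in trace")
  t_cross <- if (length(cross)) {
    i <- cross
    trace$t[i] + (0 - d[i]) * (trace$t[i + 1] - trace$t[i]) /
      (d[i + 1] - d[i])
  } else numeric(0)
  t_all <- sort(c(t_cross, trace$t[zero]))
  structure(t_all[1], n_crossings = length(t_all))
}

#' Full microrheology gel-point pipeline
#'
#' Windowed MSD, log-log polynomial slope, GSER conversion, and G' = G''
#' crossover detection, in one call.
#'
#' @param tracks track data.frame (see [compute_msd()]).
#' @param params a [gser_params()].
#' @param window window width, s.
#' @param every window-centre spacing, s.
#' @param max_lag largest lag evaluated inside each window, s.
#' @return list: `gel_point` (s), `trace` (data.frame `t`, `g_prime`,
#'   `g_double_prime`, `alpha`).
#' @export
gel_point_pipeline <- function(tracks, params = gser_params(),
                               window = 10, every = 2, max_lag = 2.5) {
  wm <- compute_msd(tracks, max_lag = max_lag, window = window,
                    every = every)
  rows <- lapply(wm, function(curve) {
    m <- msd_to_moduli(curve, params)
    data.frame(t = attr(curve, "window_center"), g_prime = m$g_prime,
               g_double_prime = m$g_double_prime, alpha = m$alpha)
  })
  trace <- do.call(rbind, rows)
  list(gel_point = as.numeric(detect_gel_point(trace)), trace = trace)
}

#' Time for the storage modulus to reach its plateau
#'
#' The plateau value is the mean of the final 10% of G'; returns the
#' earliest time from which G' stays within a relative band
#' `epsilon` of the plateau for at least `hold` seconds.
#'
#' @param trace data.frame with columns `t` and `g_prime`.
#' @param epsilon relative band half-width (default 0.02).
#' @param hold minimum dwell time inside the band, s.
#' @return plateau-entry time, s, with attribute `plateau` (Pa).
#' @export
time_to_plateau <- function(trace, epsilon = 0.02, hold = 20) {
  stopifnot(all(c("t", "g_prime") %in% names(trace)))
  tt <- trace$t; g <- trace$g_prime
  if (diff(range(tt)) < hold) stopf("trace shorter than hold time")
  n10 <- max(1L, ceiling(0.1 * length(g)))
  plateau <- mean(tail(g, n10))
  inband <- abs(g - plateau) <= epsilon * abs(plateau)
  r <- rle(inband)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    if (tt[ends[j]] - tt[starts[j]] >= hold ||
        (ends[j] == length(tt) && inband[length(tt)] &&
         tt[ends[j]] - tt[starts[j]] >= hold))
      return(structure(tt[starts[j]], plateau = plateau))
  }
  stopf("G' never stays within the plateau band for %g s", hold)
}

#' Young's modulus from a stress-strain curve
#'
#' Ordinary least-squares slope of true stress vs strain restricted to the
#' linear regime (default 0-7% strain).
#'
#' @param strain strain fractions.
#' @param stress stresses, Pa.
#' @param strain_range inclusive strain window used for the fit.
#' @return modulus, Pa.
#' @export
young_modulus <- function(strain, stress, strain_range = c(0, 0.07)) {
  stopifnot(length(strain) == length(stress))
  keep <- strain >= strain_range[1] & strain <= strain_range[2]
  if (sum(keep) < 3L) stopf("fewer than 3 points in the strain range")
  unname(coef(lm(stress[keep] ~ strain[keep]))[2])
}

#' Molecular weight from GPC elution volume
#'
#' Calibration \eqn{\log_{10}(M_n) = A_0 + A_1 V_p} against polyethylene
#' glycol standards.
#'
#' @param vp elution volume.
#' @param a0,a1 calibration constants.
#' @return molecular weight, g/mol.
#' @export
gpc_molecular_weight <- function(vp, a0 = 10.2086, a1 = -0.7604) {
  10^(a0 + a1 * vp)
}
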