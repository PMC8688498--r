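# Degradation-assay analysis: saturating-exponential mass-loss fits, IPN
# composition inference from selective enzymatic degradation, and in
# vitro / in vivo curve comparison.

validate_degradation_series <- function(series) {
  if (!all(c("t", "released_fraction") %in% names(series)))
    stopf("series needs columns 't' and 'released_fraction'")
  if (nrow(series) < 4L) stopf("series needs >= 4 samples")
  if (any(series$t < 0)) stopf("t must be >= 0")
  if (is.unsorted(series$t, strictly = FALSE)) stopf("t must be increasing")
  if (any(series$released_fraction < 0 | series$released_fraction > 1.05))
    stopf("released_fraction must lie in [0, 1.05]")
  invisible(series)
}

fit_release <- function(t, m) {
  if (all(m == 0))
    return(list(f_inf = 0, k = NA_real_, rss = 0,
                k_unidentifiable = TRUE))
  f0 <- clamp(max(m), 0.01, 1)
  # crude rate start from the earliest point at half plateau
  i <- which(m >= f0 / 2)[1]
  k0 <- if (is.na(i) || t[i] == 0) 1 / max(t) else log(2) / t[i]
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ f * (1 - exp(-k * t)),
                      start = list(f = f0, k = k0),
                      lower = c(0, 1e-8), upper = c(1, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stopf("degradation fit failed: %s", conditionMessage(e)))
  cf <- coef(fit)
  list(f_inf = unname(cf["f"]), k = unname(cf["k"]),
       rss = sum(residuals(fit)^2), k_unidentifiable = FALSE)
}

#' Fit a saturating-exponential degradation model
#'
#' Least-squares fit of the released mass fraction
#' \eqn{m(t) = f_\infty (1 - e^{-k t})}, with the plateau constrained to
#' \[0, 1\] and the rate positive.  An all-zero series returns
#' \eqn{f_\infty = 0} with the rate flagged unidentifiable.
#'
#' @param series a degradation series: data.frame with columns `t`
#'   (minutes in vitro, days in vivo) and `released_fraction`.
#' @return list: `f_inf`, `k`, `rss`, `k_unidentifiable`.
#' @examples
#' s <- simulate_degradation(degradation_preset("ipn75", noise_sd = 0),
#'                           "collagenase")
#' fit_degradation(s)$f_inf  # ~0.75
#' @export
fit_degradation <- function(series) {
  validate_degradation_series(series)
  fit_release(series$t, series$released_fraction)
}

#' Infer IPN composition from selective enzymatic degradation
#'
#' Collagenase degrades the gelatin network and hyaluronidase the
#' hyaluronic-acid network, so the two fitted plateaus estimate the two
#' composition fractions directly.  Standard errors come from a residual
#' bootstrap of each fit; `se_f` is the standard error of the sum
#' \eqn{f_{gtn} + f_{ha}} (the two assays are independent), against which
#' the closure \eqn{f_{gtn} + f_{ha} = 1} can be checked.
#'
#' @param coll degradation series measured under collagenase.
#' @param hyal degradation series measured under hyaluronidase.
#' @param n_boot bootstrap resamples (default 200).
#' @param seed bootstrap seed.
#' @return list: `f_gtn`, `f_ha`, `se_f`, `se_f_gtn`, `se_f_ha`.
#' @export
infer_composition <- function(coll, hyal, n_boot = 200, seed = 1234) {
  validate_degradation_series(coll)
  validate_degradation_series(hyal)
  f1 <- fit_degradation(coll)
  f2 <- fit_degradation(hyal)
  boot_se <- function(series, fit) {
    if (fit$k_unidentifiable) return(0)
    pred <- fit$f_inf * (1 - exp(-fit$k * series$t))
    res <- series$released_fraction - pred
    fs <- vapply(seq_len(n_boot), function(b) {
      m <- clamp(pred + sample(res, length(res), replace = TRUE), 0, 1.05)
      tryCatch(fit_release(series$t, m)$f_inf, error = function(e) NA_real_)
    }, numeric(1))
    sd(fs, na.rm = TRUE)
  }
  ses <- with_seed(seed, c(boot_se(coll, f1), boot_se(hyal, f2)))
  list(f_gtn = f1$f_inf, f_ha = f2$f_inf,
       se_f = sqrt(sum(ses^2)), se_f_gtn = ses[1], se_f_ha = ses[2])
}

#' Compare in vitro and in vivo degradation curves
#'
#' Both series are placed on the remaining-mass scale
#' (\eqn{1 -} released fraction); the denser in vitro curve is linearly
#' interpolated onto the in vivo time points and the coefficient of
#' determination is computed as the squared Pearson correlation (the
#' plain correlation is also returned).
#'
#' @param in_vitro,in_vivo degradation series (columns `t`,
#'   `released_fraction`) with overlapping time ranges.
#' @return list: `r_squared`, `pearson_r`, `n` (overlapping points).
#' @export
compare_curves <- function(in_vitro, in_vivo) {
  validate_degradation_series(in_vitro)
  validate_degradation_series(in_vivo)
  lo <- max(min(in_vitro$t), min(in_vivo$t))
  hi <- min(max(in_vitro$t), max(in_vivo$t))
  keep <- in_vivo$t >= lo & in_vivo$t <= hi
  if (sum(keep) < 3L) stopf("fewer than 3 overlapping time points")
  rem_vitro <- stats::approx(in_vitro$t, 1 - in_vitro$released_fraction,
                             xout = in_vivo$t[keep])$y
  rem_vivo <- 1 - in_vivo$released_fraction[keep]
  r <- cor(rem_vivo, rem_vitro)
  list(r_squared = r^2, pearson_r = r, n = sum(keep))
}

#' Convert a gel-mass time series to a degradation series
#'
#' Re-expresses an OCT-derived normalized gel-mass series on the
#' released-fraction scale so it can be compared with an in vitro assay
#' via [compare_curves()].
#'
#' @param mass_series data.frame with columns `day` and `normalized_mass`.
#' @return degradation-series data.frame (`t` in days, `released_fraction`,
#'   `condition = "in_vivo"`).
#' @export
as_degradation_series <- function(mass_series) {
  stopifnot(all(c("day", "normalized_mass") %in% names(mass_series)))
  data.frame(t = mass_series$day,
             released_fraction = clamp(1 - mass_series$normalized_mass,
                                       0, 1.05),
             condition = "in_vivo")
}
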