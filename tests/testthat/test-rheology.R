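test_that("MSD matches hand enumeration on the three-point track", {
  tr <- data.frame(particle = 1, t_s = 0:2,
                   x_um = c(0, 1, 1), y_um = c(0, 0, 1))
  expect_warning(msd <- compute_msd(tr, max_lag = 2), "fewer than 2")
  expect_equal(msd$msd, c(1, 2))
  expect_equal(msd$lag, c(1, 2))
})

test_that("MSD equals the brute-force all-pairs oracle on short tracks", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      n <- sample(8:20, 1)
      tr <- do.call(rbind, lapply(1:3, function(p)
        data.frame(particle = p, t_s = seq_len(n) - 1,
                   x_um = cumsum(rnorm(n)), y_um = cumsum(rnorm(n)))))
      msd <- compute_msd(tr, max_lag = 5)
      for (l in msd$lag)
        expect_equal(msd$msd[msd$lag == l], brute_msd(tr, l))
    }
  })
})

test_that("constant tracks give identically zero MSD", {
  tr <- data.frame(particle = 1, t_s = 0:9, x_um = 2, y_um = -1)
  expect_true(all(compute_msd(tr, max_lag = 3)$msd == 0))
})

test_that("2D Brownian MSD is ~4 D tau within 3 SE over 100 beads", {
  D <- 0.3; dt <- 0.1; n <- 200
  withr::with_seed(11, {
    tr <- do.call(rbind, lapply(1:100, function(p)
      data.frame(particle = p, t_s = (seq_len(n) - 1) * dt,
                 x_um = cumsum(rnorm(n, sd = sqrt(2 * D * dt))),
                 y_um = cumsum(rnorm(n, sd = sqrt(2 * D * dt))))))
  })
  msd <- compute_msd(tr, max_lag = 1)
  for (i in seq_len(nrow(msd))) {
    expected <- 4 * D * msd$lag[i]
    se <- expected * sqrt(2 / msd$n_pairs[i]) * 3  # generous 3-SE band
    expect_lt(abs(msd$msd[i] - expected), 3 * se + 0.05 * expected)
  }
})

test_that("double-exponential fit handles constant and exact curves", {
  cst <- fit_double_exponential(0:9, rep(3, 10))
  expect_equal(cst$c, 3)
  expect_equal(cst$rss, 0)
  expect_equal(cst$a1 + cst$a2, 0)

  t <- seq(0, 200, by = 2)
  y <- 2 * exp(-t / 5) + 1 * exp(-t / 50) + 0.1
  fit <- fit_double_exponential(t, y)
  expect_equal(fit$tau1, 5, tolerance = 1e-4)
  expect_equal(fit$tau2, 50, tolerance = 1e-4)
  expect_equal(fit$a1, 2, tolerance = 1e-4)
  expect_equal(fit$a2, 1, tolerance = 1e-4)
  expect_equal(fit$c, 0.1, tolerance = 1e-3)
  expect_lte(fit$tau1, fit$tau2)

  # single-exponential data: degenerate second component, near-zero RSS
  y1 <- 3 * exp(-t / 20)
  fit1 <- fit_double_exponential(t, y1)
  expect_lt(fit1$rss, 1e-8)
  expect_true(min(fit1$a1, fit1$a2) < 1e-3 ||
                abs(fit1$tau1 - fit1$tau2) < 1e-2 * fit1$tau2)
})

test_that("GSER limits: alpha 0, 0.5, 1 give the expected moduli", {
  lags <- exp(seq(log(0.1), log(1), length.out = 8))
  params <- gser_params()
  # alpha = 1 (viscous): G' = 0
  m1 <- msd_to_moduli(data.frame(lag = lags, msd = 0.4 * lags), params)
  expect_equal(m1$alpha, 1)
  expect_equal(m1$g_prime, 0)
  expect_gt(m1$g_double_prime, 0)
  # alpha = 0 (elastic): G'' = 0
  m0 <- msd_to_moduli(data.frame(lag = lags, msd = rep(0.2, 8)), params)
  expect_equal(m0$alpha, 0)
  expect_equal(m0$g_double_prime, 0)
  expect_gt(m0$g_prime, 0)
  # alpha = 0.5: G' = G'' (the gel-point condition)
  mh <- msd_to_moduli(data.frame(lag = lags, msd = 0.3 * sqrt(lags)), params)
  expect_equal(mh$alpha, 0.5, tolerance = 1e-10)
  expect_equal(mh$g_prime, mh$g_double_prime)
})

test_that("gel point is interpolated at the earliest crossing", {
  tr <- data.frame(t = c(0, 10, 20), g_prime = c(1, 2, 4),
                   g_double_prime = c(3, 3, 3))
  expect_equal(as.numeric(detect_gel_point(tr)), 15)
  # invariant under uniform positive rescaling of both moduli
  tr2 <- tr; tr2$g_prime <- 7 * tr2$g_prime
  tr2$g_double_prime <- 7 * tr2$g_double_prime
  expect_equal(as.numeric(detect_gel_point(tr2)), 15)
  # no crossing
  expect_error(detect_gel_point(data.frame(
    t = 0:2, g_prime = c(5, 6, 7), g_double_prime = c(1, 1, 1))),
    "no G")
  # multiple crossings: earliest returned, count reported
  tr3 <- data.frame(t = 0:3, g_prime = c(0, 2, 0, 2),
                    g_double_prime = c(1, 1, 1, 1))
  gp <- detect_gel_point(tr3)
  expect_equal(as.numeric(gp), 0.5)
  expect_equal(attr(gp, "n_crossings"), 3)
})

test_that("time to plateau matches the analytic crossing", {
  tr <- data.frame(t = 0:100, g_prime = rep(5, 101))
  expect_equal(as.numeric(time_to_plateau(tr)), 0)

  tau <- 10; P <- 100
  t <- seq(0, 200, by = 0.5)
  tr2 <- data.frame(t = t, g_prime = P * (1 - exp(-t / tau)))
  tp <- time_to_plateau(tr2, epsilon = 0.02, hold = 20)
  # plateau estimate: mean of final 10% (essentially P); band entry at
  # t = -tau*log(epsilon * plateau/P) ~ 39.1 s
  expect_equal(as.numeric(tp), -tau * log(0.02), tolerance = 0.05)

  ramp <- data.frame(t = 0:100, g_prime = (0:100)^2)
  expect_error(time_to_plateau(ramp), "plateau")
})

test_that("Young's modulus is the OLS slope in the linear regime", {
  strain <- seq(0, 0.07, by = 0.005)
  expect_equal(young_modulus(strain, 5 * strain), 5)
  withr::with_seed(3, {
    stress <- 2532 * strain + rnorm(length(strain), sd = 10)
    fit <- lm(stress ~ strain)
    se <- summary(fit)$coefficients["strain", "Std. Error"]
    expect_lt(abs(young_modulus(strain, stress) - 2532), 3 * se)
  })
  expect_error(young_modulus(c(0.2, 0.3, 0.4), c(1, 2, 3)), "fewer than 3")
})

test_that("GPC calibration evaluates the printed power law", {
  expect_equal(gpc_molecular_weight(0), 10^10.2086)
  expect_equal(gpc_molecular_weight(10.2086 / 0.7604), 1, tolerance = 1e-12)
  expect_equal(gpc_molecular_weight(10), 10^(10.2086 - 7.604))
})

test_that("track validation enforces uniform sampling and length", {
  expect_error(compute_msd(data.frame(
    particle = 1, t_s = c(0, 1), x_um = c(0, 1), y_um = c(0, 0)),
    max_lag = 1), ">= 3")
  expect_error(compute_msd(data.frame(
    particle = 1, t_s = c(0, 1, 3), x_um = 0:2, y_um = 0:2),
    max_lag = 1), "uniform")
})
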