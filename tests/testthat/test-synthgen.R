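test_that("preset validation enforces the documented invariants", {
  expect_error(gelation_preset(alpha_liquid = 0.4), "alpha_liquid")
  expect_error(gelation_preset(alpha_gel = 0.6), "alpha_gel")
  expect_error(gelation_preset(t_gel = 300, duration = 200), "exceed")
  expect_error(degradation_preset(f_gtn = 1.2), "f_gtn")
  expect_error(retina_preset(layer_fractions = c(GCL = 0.5, IPL = 0.4)),
               "sum to 1")
  expect_error(retina_preset(layer_fractions = c(GCL = 0.5, nerve = 0.5)),
               "unknown layer")
  expect_error(interface_preset(boundary_length = 100), "boundary_length")
  expect_equal(degradation_preset("ipn75")$f_ha, 0.25)
})

test_that("generators are bit-identical given the same preset and seed", {
  p <- gelation_preset("gtn_hpa", duration = 50, t_gel = 30, n_beads = 2)
  expect_identical(simulate_gelation_tracks(p, seed = 5),
                   simulate_gelation_tracks(p, seed = 5))
  d <- degradation_preset("ipn50")
  expect_identical(simulate_degradation(d, "both", seed = 9),
                   simulate_degradation(d, "both", seed = 9))
  f <- field_preset("sparse")
  expect_identical(render_field(f, seed = 3), render_field(f, seed = 3))
  r <- retina_preset("ipn50")
  expect_identical(render_retina_sections(r, n_fields = 1, seed = 2),
                   render_retina_sections(r, n_fields = 1, seed = 2))
  i <- interface_preset("ipn75", n_slides = 2)
  expect_identical(render_interface(i, seed = 7), render_interface(i, seed = 7))
  o <- oct_preset("ipn50", n_days = 2, n_frames = 2,
                  image_shape = c(96L, 96L))
  expect_identical(render_oct_series(o, seed = 4), render_oct_series(o, seed = 4))
})

test_that("ground-truth exponent crosses 0.5 exactly at the gel point", {
  for (nm in c("gtn_hpa", "ipn75", "ipn50")) {
    p <- gelation_preset(nm, n_beads = 1L)
    sim <- simulate_gelation_tracks(p)
    a <- sim$alpha
    i <- which(a$alpha[-1] < 0.5 & a$alpha[-nrow(a)] >= 0.5)[1]
    t_cross <- a$t[i] + (0.5 - a$alpha[i]) *
      (a$t[i + 1] - a$t[i]) / (a$alpha[i + 1] - a$alpha[i])
    expect_equal(t_cross, p$t_gel, tolerance = 1e-3)
  }
})

test_that("zero-amplitude and near-diffusive limits behave as expected", {
  p0 <- gelation_preset("gtn_hpa", msd_amplitude = 0, n_beads = 2L,
                        duration = 50, t_gel = 30)
  sim0 <- simulate_gelation_tracks(p0)
  expect_true(all(sim0$tracks$x_um == 0) && all(sim0$tracks$y_um == 0))

  # alpha ~ 1 everywhere before the (late) transition: early MSD slope ~ 1
  p1 <- suppressWarnings(
    gelation_preset("liquid", alpha_liquid = 1, alpha_gel = 0.45,
                    t_gel = 55, transition_width = 0.5, duration = 60,
                    n_beads = 10L, frame_interval = 0.1))
  sim1 <- simulate_gelation_tracks(p1, seed = 31)
  early <- sim1$tracks[sim1$tracks$t_s <= 40, ]
  msd <- compute_msd(early, max_lag = 2)
  slope <- coef(lm(log(msd$msd) ~ log(msd$lag)))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("degradation plateaus encode the susceptible fraction", {
  p <- degradation_preset("ipn75", noise_sd = 0)
  coll <- simulate_degradation(p, "collagenase")
  hyal <- simulate_degradation(p, "hyaluronidase")
  both <- simulate_degradation(p, "both")
  expect_equal(attr(coll, "truth")$f_target, 0.75)
  expect_equal(attr(hyal, "truth")$f_target, 0.25)
  expect_equal(attr(both, "truth")$f_target, 1)
  # homopolymer under its enzyme: released fraction approaches 1
  g <- degradation_preset("gtn_hpa", noise_sd = 0, duration = 300)
  s <- simulate_degradation(g, "collagenase")
  expect_gt(tail(s$released_fraction, 1), 0.99)
  # hyaluronidase schedule: twice the interval and duration
  expect_equal(hyal$t[1], 2 * coll$t[1])
  expect_equal(nrow(hyal), nrow(coll))
})

test_that("field truth table matches the preset composition", {
  fl <- render_field(field_preset("sparse"), seed = 11)
  expect_equal(sum(fl$truth$channel == "live"), 8L)
  expect_equal(sum(fl$truth$channel == "dead"), 2L)
  expect_equal(nrow(fl$truth), 10L)

  blank <- render_field(field_preset("empty", n_live = 0L, n_dead = 0L))
  expect_equal(nrow(blank$truth), 0L)

  expect_error(render_field(field_preset("packed", n_live = 3000L,
                                         n_dead = 3000L)),
               "packing")
})

test_that("retina truth respects degenerate layer and class settings", {
  p <- retina_preset("ipn50",
                     layer_fractions = c(vitreous = 0, GCL = 1, IPL = 0,
                                         INL = 0, ONL = 0))
  rs <- render_retina_sections(p, n_fields = 2, seed = 5)
  expect_true(all(rs$truth$layer == "GCL"))
  expect_true(all(rs$truth$r_um <= 170))
})

test_that("interface flags hit the trivial extremes exactly", {
  p1 <- render_interface(interface_preset("full", attach_prob = 1,
                                          n_slides = 2), seed = 3)
  expect_true(all(unlist(lapply(p1$slides, `[[`, "flags"))))
  p0 <- render_interface(interface_preset("none", attach_prob = 0,
                                          n_slides = 2), seed = 3)
  expect_false(any(unlist(lapply(p0$slides, `[[`, "flags"))))
})

test_that("interface attachment marginal matches the preset probability", {
  # 30 seeds x 10 slides; binomial-style 3-SE band around 0.79
  est <- vapply(1:30, function(s) {
    ri <- render_interface(interface_preset("ipn50"), seed = 7000 + s)
    mean(unlist(lapply(ri$slides, `[[`, "flags")))
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.79), 3 * se + 0.005)
})

test_that("OCT truth decays as the preset exponential", {
  p <- oct_preset("ipn50", n_days = 3, decay_rate = log(2),
                  image_shape = c(96L, 96L), gel_px_day0 = 400L,
                  retina_foreground_px = 2000L, n_frames = 2L)
  ro <- render_oct_series(p, seed = 8)
  expect_equal(ro$truth$normalized_mass,
               c(1, 0.5, 0.25), tolerance = 0.01)
  expect_true(all(diff(ro$truth$gel_px) <= 0))
})
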