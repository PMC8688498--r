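# straight-boundary fixture: retina occupies rows >= 40, gel touches the
# boundary over chosen column ranges (pixel_size 1 um/px)
flat_slide <- function(W = 620, gel_cols = integer(0)) {
  retina <- matrix(FALSE, 80, W); retina[40:80, ] <- TRUE
  gel <- matrix(FALSE, 80, W)
  if (length(gel_cols)) gel[37:39, gel_cols] <- TRUE
  list(gel_mask = gel, retina_mask = retina)
}

test_that("attachment segments match the hand-built half-covered boundary", {
  sl <- flat_slide(W = 601, gel_cols = 1:301)  # first 300 um attached
  res <- measure_attachment(sl$gel_mask, sl$retina_mask, pixel_size = 1)
  expect_equal(res$overall_percent, 100 * mean(res$attached))
  full <- res$segments[!res$segments$partial, ]
  expect_equal(nrow(full), 3L)
  expect_equal(full$percent_attached[1], 100)
  expect_equal(full$percent_attached[2], 50, tolerance = 1)
  expect_equal(full$percent_attached[3], 0)
  expect_equal(res$overall_percent, 50, tolerance = 1)
})

test_that("no gel yields zero attachment and one spanning hole", {
  sl <- flat_slide(W = 400)
  res <- measure_attachment(sl$gel_mask, sl$retina_mask, pixel_size = 1)
  expect_equal(res$overall_percent, 0)
  expect_equal(nrow(res$holes), 1L)
  expect_equal(res$holes$length_um, length(res$attached))
})

test_that("attachment equals brute-force per-step evaluation", {
  withr::with_seed(42, {
    cols <- sort(sample(1:280, 120))
  })
  sl <- flat_slide(W = 280, gel_cols = cols)
  res <- measure_attachment(sl$gel_mask, sl$retina_mask, pixel_size = 1,
                            gap_tolerance_px = 2)
  # oracle: step at column c is attached iff gel within +-2 rows of the
  # boundary pixel in that column
  oracle <- vapply(seq_along(res$attached), function(s) {
    cx <- min(s, 280)
    any(sl$gel_mask[38:42, cx])
  }, logical(1))
  expect_equal(res$attached, oracle)
})

test_that("heat map equals the per-position mean of slide flags", {
  slides <- list(flat_slide(W = 300, gel_cols = 1:300),
                 flat_slide(W = 300, gel_cols = 1:150),
                 flat_slide(W = 300))
  agg <- aggregate_attachment(slides, pixel_size = 1)
  expect_true(all(agg$heatmap[1:140] == 2 / 3))
  expect_true(all(agg$heatmap[160:290] == 1 / 3))
  flags <- vapply(agg$results, function(r)
    r$attached[seq_along(agg$heatmap)], logical(length(agg$heatmap)))
  expect_equal(agg$heatmap, rowMeans(flags))
})

test_that("interface recovery tracks the preset probability (3 SE)", {
  est <- vapply(1:30, function(s) {
    ri <- render_interface(interface_preset("ipn50"), seed = 880 + s)
    aggregate_attachment(ri$slides, ri$pixel_size)$overall_percent
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 79), 3 * se + 0.5)
})

test_that("OCT registration recovers known integer shifts", {
  withr::with_seed(6, {
    base <- matrix(0, 64, 64)
    base <- put_block(base, 20, 20, 12, 18, 0.9)
    base <- base + matrix(runif(64 * 64, 0, 0.05), 64)
  })
  shift_img <- function(img, sr, sc) {
    out <- matrix(0, nrow(img), ncol(img))
    src_r <- seq_len(nrow(img)) - sr; src_c <- seq_len(ncol(img)) - sc
    vr <- src_r >= 1 & src_r <= nrow(img)
    vc <- src_c >= 1 & src_c <= ncol(img)
    out[vr, vc] <- img[src_r[vr], src_c[vc]]
    out
  }
  frames <- simplify2array(list(base, shift_img(base, 3, -2),
                                shift_img(base, -4, 5)))
  out <- preprocess_oct(frames)
  expect_equal(attr(out, "shifts")[2, ], c(3, -2))
  expect_equal(attr(out, "shifts")[3, ], c(-4, 5))
  inner <- 10:50
  expect_lt(max(abs(out[inner, inner] - base[inner, inner])), 0.06)

  # identical frames: projection equals the frame
  same <- simplify2array(list(base, base))
  expect_equal(preprocess_oct(same), base, ignore_attr = TRUE)
  # single frame passthrough
  expect_equal(preprocess_oct(array(base, c(64, 64, 1))), base,
               ignore_attr = TRUE)
})

test_that("excessive registration shifts drop the frame", {
  base <- matrix(0, 40, 40)
  base <- put_block(base, 5, 5, 6, 6, 1)
  shifted <- matrix(0, 40, 40)
  shifted <- put_block(shifted, 30, 30, 6, 6, 1)  # ~25 px apart
  expect_warning(out <- preprocess_oct(simplify2array(list(base, shifted))),
                 "exceeds 25")
  expect_equal(out, base, ignore_attr = TRUE)
})

test_that("gel surplus is foreground minus baseline, clamped at zero", {
  img <- matrix(0.05, 100, 100)
  img <- put_block(img, 10, 10, 30, 50, 0.9)  # 1500 bright px
  expect_equal(quantify_gel(img, 1000), 500)
  expect_equal(quantify_gel(img, 2000), 0)
})

test_that("gel-mass series normalizes to day 0 and flags empty day 0", {
  p <- oct_preset("flat", decay_rate = 0, n_days = 3, speckle_sd = 0,
                  max_shift_px = 0L, image_shape = c(96L, 96L),
                  gel_px_day0 = 400L, retina_foreground_px = 2000L,
                  n_frames = 2L)
  ro <- render_oct_series(p, seed = 12)
  bl <- baseline_foreground(list(preprocess_oct(ro$control)))
  gm <- gel_mass_series(ro$stacks, bl)
  expect_equal(gm$normalized_mass, rep(1, 3), tolerance = 0.1)

  p0 <- oct_preset("none", gel_px_day0 = 0L, n_days = 2,
                   image_shape = c(96L, 96L), retina_foreground_px = 2000L,
                   n_frames = 2L)
  ro0 <- render_oct_series(p0, seed = 13)
  bl0 <- baseline_foreground(list(preprocess_oct(ro0$control)))
  expect_error(gel_mass_series(ro0$stacks, bl0), "day-0")
})

test_that("half-life decay is recovered from rendered OCT stacks", {
  p <- oct_preset("halflife", decay_rate = log(2), n_days = 2,
                  image_shape = c(128L, 128L), gel_px_day0 = 800L,
                  retina_foreground_px = 4000L, n_frames = 3L)
  ro <- render_oct_series(p, seed = 21)
  ctrl <- lapply(seq_len(dim(ro$control)[3]),
                 function(k) ro$control[, , k])
  bl <- baseline_foreground(ctrl)
  gm <- gel_mass_series(ro$stacks, bl)
  expect_lt(abs(gm$normalized_mass[2] - 0.5), 0.1)
})
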