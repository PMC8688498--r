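# helpers: horizontal three-band annotation and rasterized ellipse cells
make_bands <- function(H = 120, W = 200,
                       layers = c("vitreous", "GCL", "IPL")) {
  mask <- matrix(0L, H, W)
  cuts <- round(seq(0, H, length.out = length(layers) + 1))
  for (k in seq_along(layers))
    mask[(cuts[k] + 1):cuts[k + 1], ] <- k
  layer_annotation(mask, layers, pixel_size = 1)
}

cell_px <- function(dim, center, L, W, angle)
  gelgraft:::ellipse_pixels(dim, center, L / 2, W / 2, angle)

test_that("orientation is the wrapped difference to the layer angle", {
  ann <- make_bands()
  # a 30-degree bar in a 0-degree layer
  px <- cell_px(c(120, 200), c(60, 100), 60, 8, 30)
  fo <- fit_orientation(px, ann, "GCL")
  expect_equal(fo$theta_deg, 30, tolerance = 2)
  # cell at 100 degrees absolute: wrapped to -80
  px2 <- cell_px(c(120, 200), c(60, 100), 60, 8, 100)
  fo2 <- fit_orientation(px2, ann, "GCL")
  expect_equal(fo2$theta_deg, -80, tolerance = 2)
})

test_that("horizontal 5x60 bar has Feret ~60 um, class medium", {
  bar <- as.matrix(expand.grid(row = 58:62, col = 71:130))
  colnames(bar) <- c("row", "col")
  ann <- make_bands()
  fo <- fit_orientation(bar, ann, "GCL")
  expect_equal(fo$r_um, 60, tolerance = 2)
  expect_equal(as.character(size_class(fo$r_um)), "medium")
})

test_that("size-class boundaries are assigned to the lower class", {
  expect_equal(as.character(size_class(c(29, 30, 31, 150, 151))),
               c("round", "round", "medium", "medium", "long"))
})

test_that("layer assignment follows majority with centroid tie-break", {
  ann <- make_bands(H = 120)
  # fully inside GCL (rows 41-80)
  px <- as.matrix(expand.grid(row = 50:60, col = 20:40))
  colnames(px) <- c("row", "col")
  expect_equal(assign_layer(px, ann), "GCL")
  # 60% GCL / 40% IPL
  px2 <- as.matrix(expand.grid(row = 75:84, col = 20:40))  # 6 rows GCL
  colnames(px2) <- c("row", "col")
  expect_equal(assign_layer(px2, ann), "GCL")
  # exact 50/50 split blocks with the centroid strictly inside IPL
  px3 <- rbind(as.matrix(expand.grid(row = 75:76, col = 20:23)),
               as.matrix(expand.grid(row = 88:89, col = 20:23)))
  colnames(px3) <- c("row", "col")
  expect_equal(assign_layer(px3, ann), "IPL")
  # zero overlap with annotation
  ann0 <- ann; ann0$mask[] <- 0L
  expect_equal(assign_layer(px, ann0), "background")
})

test_that("theta is invariant under joint rotation of cell and layers", {
  dims <- c(360L, 720L)
  layers <- c("vitreous", "GCL", "IPL", "INL", "ONL")
  theta_true <- 12
  for (tilt in seq(-30, 30, by = 15)) {
    mask <- gelgraft:::make_layer_bands(dims, tilt, layers)
    ann <- layer_annotation(mask, layers, pixel_size = 1)
    px <- cell_px(dims, c(180, 360), 80, 10, tilt + theta_true)
    lay <- assign_layer(px, ann)
    fo <- fit_orientation(px, ann, lay)
    expect_equal(fo$theta_deg, theta_true, tolerance = 3)
  }
})

test_that("engraftment summary aggregates layers and the injected dose", {
  tabs <- list(
    data.frame(label = 1:3, layer = c("GCL", "GCL", "GCL"),
               r_um = c(10, 40, 160), theta_deg = c(0, 5, -5),
               size_class = c("round", "medium", "long"), area_px = 50L),
    data.frame(label = 1:2, layer = c("GCL", "GCL"),
               r_um = c(12, 14), theta_deg = c(1, 2),
               size_class = c("round", "round"), area_px = 40L))
  s <- summarize_engraftment(tabs, injected_total = 5e4,
                             fields_per_retina_scale = 2800)
  expect_equal(unname(s$per_layer_percent["GCL"]), 100)
  expect_equal(sum(s$per_layer_percent), 100)
  expect_equal(s$percent_engrafted_of_injected, 100 * 2.5 * 2800 / 5e4)
  expect_equal(nrow(s$polar), 5L)

  expect_warning(s0 <- summarize_engraftment(list(
    analyze_retina_field(list(reporter = matrix(0, 40, 40)),
                         make_bands(40, 40)))),
    "zero cells")
  expect_equal(s0$percent_engrafted_of_injected, 0)
})

test_that("size class and layer are recovered per cell on rendered fields", {
  rs <- render_retina_sections(retina_preset("ipn50"), n_fields = 5,
                               seed = 71)
  n_match <- 0L; n_cells <- 0L; class_ok <- 0L; layer_ok <- 0L
  for (f in rs$fields) {
    tab <- analyze_retina_field(f$channels, f$layer_mask)
    seg <- fusion_segment(f$channels$reporter, rs$pixel_size)
    idx <- which(seg$labels > 0, arr.ind = TRUE)
    lab <- seg$labels[seg$labels > 0]
    for (k in seq_len(nrow(tab))) {
      ctr <- colMeans(idx[lab == tab$label[k], , drop = FALSE])
      d <- sqrt((f$truth$row - ctr[1])^2 + (f$truth$col - ctr[2])^2)
      j <- which.min(d)
      if (length(j) && d[j] < 15) {
        n_match <- n_match + 1L
        class_ok <- class_ok + (tab$size_class[k] == f$truth$size_class[j])
        layer_ok <- layer_ok + (tab$layer[k] == f$truth$layer[j])
      }
    }
    n_cells <- n_cells + nrow(f$truth)
  }
  expect_gte(n_match / n_cells, 0.95)
  expect_gte(class_ok / n_match, 0.90)
  expect_gte(layer_ok / n_match, 0.90)
})
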