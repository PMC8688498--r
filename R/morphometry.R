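# Per-object morphometry: area, Crofton perimeter, shape factor,
# Feret diameter, and moments-equivalent ellipse orientation.

#' Crofton perimeter of a pixel set
#'
#' Integral-geometric perimeter estimate from intercept counts along eight
#' lattice direction families (axial, diagonal, and knight-move), with a
#' pixel-support correction per line family.  Calibrated so a digitized
#' disc of radius 100 px and an axis-aligned 10x10 square both land within
#' a few percent of their ideal perimeters (the boundary-pixel count
#' estimator fails the square by ~25%).
#'
#' @param px 2-column matrix of pixel coordinates (`row`, `col`).
#' @return perimeter in pixel units.
#' @export
crofton_perimeter <- function(px) {
  if (nrow(px) == 0L) return(0)
  dirs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1),
                c(1, 2), c(2, 1), c(2, -1), c(1, -2))
  W <- numeric(nrow(dirs))
  for (i in seq_len(nrow(dirs))) {
    p <- dirs[i, 1]; q <- dirs[i, 2]
    s2 <- p * p + q * q; s <- sqrt(s2)
    key <- q * px[, 1] - p * px[, 2]
    proj <- p * px[, 1] + q * px[, 2]
    runs <- sum(vapply(split(proj, key), function(v) {
      v <- sort(v); 1L + sum(diff(v) != s2)
    }, integer(1)))
    ks <- sort(unique(key))
    clusters <- 1L + sum(diff(ks) != 1L)
    W[i] <- (runs + clusters * (abs(p) + abs(q) - 1)) / s
  }
  pi * mean(W)
}

#' Maximum Feret (caliper) diameter of a pixel set
#'
#' Largest pairwise distance across the object's convex hull, plus one
#' pixel of support, in pixel units.
#'
#' @param px 2-column matrix of pixel coordinates (`row`, `col`).
#' @return Feret diameter, px.
#' @export
feret_diameter <- function(px) {
  if (nrow(px) == 0L) return(0)
  if (nrow(px) == 1L) return(1)
  hull <- px[grDevices::chull(px[, 1], px[, 2]), , drop = FALSE]
  d2 <- outer(hull[, 1], hull[, 1], "-")^2 + outer(hull[, 2], hull[, 2], "-")^2
  sqrt(max(d2)) + 1
}

# Orientation (degrees in [-90, 90)) of the moments-equivalent ellipse
# major axis, measured from the +col (x) axis; image rows increase
# downward, so positive angles point down-right.  Returns list with
# angle, major/minor axis lengths (4*sqrt(eigenvalue), the equivalent
# ellipse full axes) and centroid.
moments_ellipse <- function(px) {
  n <- nrow(px)
  ctr <- colMeans(px)
  if (n < 2L)
    return(list(angle = 0, major = 1, minor = 1, centroid = ctr,
                degenerate = TRUE))
  dr <- px[, 1] - ctr[1]
  dc <- px[, 2] - ctr[2]
  cov <- matrix(c(mean(dc^2), mean(dc * dr),
                  mean(dc * dr), mean(dr^2)), 2)
  e <- eigen(cov, symmetric = TRUE)
  v <- e$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang >= 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  list(angle = ang,
       major = 4 * sqrt(max(e$values[1], 0)),
       minor = 4 * sqrt(max(e$values[2], 0)),
       centroid = ctr,
       degenerate = e$values[2] <= .Machine$double.eps * e$values[1])
}

#' Measure per-cell morphometry of a labelled image
#'
#' For every labelled object: area (pixel count times pixel area),
#' perimeter by the multi-direction Crofton estimator, shape factor
#' \eqn{C = 4\pi A / P^2} (1 for a perfect circle), centroid, Feret
#' diameter and moments-ellipse orientation.  Objects smaller than 5 px
#' have their shape factor flagged unreliable.
#'
#' @param labeled a `labeled_image`.
#' @param channel_name channel label recorded in each row (e.g. `"live"`).
#' @return data.frame: `label`, `channel`, `area_um2`, `perimeter_um`,
#'   `shape_factor`, `x_um`, `y_um`, `feret_um`, `orientation_deg`,
#'   `area_px`, `unreliable`.
#' @export
measure_cells <- function(labeled, channel_name = "live") {
  stopifnot(inherits(labeled, "labeled_image"))
  ps <- labeled$pixel_size
  n <- labeled$n_objects
  if (n == 0L)
    return(data.frame(label = integer(0), channel = character(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      shape_factor = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), feret_um = numeric(0),
                      orientation_deg = numeric(0), area_px = integer(0),
                      unreliable = logical(0)))
  idx <- which(labeled$labels > 0, arr.ind = TRUE)
  lab <- labeled$labels[labeled$labels > 0]
  rows <- lapply(seq_len(n), function(k) {
    px <- idx[lab == k, , drop = FALSE]
    a_px <- nrow(px)
    P <- crofton_perimeter(px)
    me <- moments_ellipse(px)
    data.frame(label = k, channel = channel_name,
               area_um2 = a_px * ps^2, perimeter_um = P * ps,
               shape_factor = 4 * pi * a_px / P^2,
               x_um = (me$centroid[2] - 1) * ps,
               y_um = (me$centroid[1] - 1) * ps,
               feret_um = feret_diameter(px) * ps,
               orientation_deg = me$angle,
               area_px = a_px, unreliable = a_px < 5L)
  })
  do.call(rbind, rows)
}
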