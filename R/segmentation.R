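# Segmentation pipelines.
#
# Two distinct procedures are implemented:
#  * segment_channel(): the in vitro live/dead viability pipeline
#    (contrast stretch, adaptive smoothing, Otsu, border-object removal,
#    hole filling, opening, small-object removal), plus watershed_split()
#    for touching cells;
#  * fusion_segment(): the in vivo engraftment pipeline (dual low/high
#    threshold fusion with a 5-px border deletion).

otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) stopf("degenerate threshold: constant image")
  EBImage::otsu(EBImage::Image(img), range = rng)
}

# 3x3 local-variance (Wiener-style) adaptive smoothing: pixels in flat
# neighbourhoods are replaced by the local mean, pixels near edges kept.
wiener_filter <- function(img, w = 3) {
  box <- matrix(1 / w^2, w, w)
  mu <- as.matrix(EBImage::filter2(img, box, boundary = "replicate"))
  mu2 <- as.matrix(EBImage::filter2(img^2, box, boundary = "replicate"))
  v <- pmax(mu2 - mu^2, 0)
  nu <- mean(v)
  mu + pmax(v - nu, 0) / pmax(v, nu) * (img - mu)
}

# drop labelled components touching the outermost `frame` pixels
remove_border_objects <- function(labels, frame = 1L) {
  d <- dim(labels)
  border <- unique(c(labels[seq_len(frame), ], labels[(d[1] - frame + 1):d[1], ],
                     labels[, seq_len(frame)], labels[, (d[2] - frame + 1):d[2]]))
  labels[labels %in% setdiff(border, 0L)] <- 0L
  labels
}

# 8-connected component labelling: 4-connected pass (EBImage bwlabel),
# then union of labels that touch diagonally
label_components_8 <- function(mask) {
  labels <- as.matrix(EBImage::bwlabel(mask))
  n <- max(labels)
  if (n < 2L) return(labels)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  d <- dim(labels)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    r0 <- seq_len(d[1] - 1L)
    c0 <- if (sh[2] > 0) seq_len(d[2] - 1L) else 2:d[2]
    a <- labels[r0, c0]
    b <- labels[r0 + 1L, c0 + sh[2]]
    pairs <- unique(cbind(a[a > 0 & b > 0], b[a > 0 & b > 0]))
    if (length(pairs))
      for (k in seq_len(nrow(pairs))) union_(pairs[k, 1], pairs[k, 2])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels[labels > 0] <- roots[labels[labels > 0]]
  relabel(labels)
}

relabel <- function(labels) {
  u <- sort(setdiff(unique(as.vector(labels)), 0L))
  out <- matrix(match(as.vector(labels), u, nomatch = 0L), nrow(labels))
  storage.mode(out) <- "integer"
  out
}

labeled_image <- function(labels, pixel_size, channels = NULL) {
  structure(list(labels = labels, pixel_size = pixel_size,
                 channels = channels,
                 n_objects = max(0L, max(labels))),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat("<labeled_image> ", paste(dim(x$labels), collapse = " x "),
      " px, ", x$n_objects, " object(s), pixel_size ",
      x$pixel_size, " um/px\n", sep = "")
  invisible(x)
}

#' Segment one fluorescence channel (viability pipeline)
#'
#' Applies, in order: percentile contrast stretch (1st-99.9th, so the
#' upper anchor reaches cells that cover well under 1% of the frame), 3x3
#' local-variance adaptive smoothing, global Otsu thresholding,
#' border-touching-object removal (1-px frame), hole filling, morphological
#' opening (disc radius 2 px), and removal of connected components smaller
#' than `min_object_px` pixels (strict: components of exactly
#' `min_object_px` pixels are kept).
#'
#' @param image 2D numeric matrix in \[0, 1\]; must not be constant.
#' @param pixel_size um per pixel.
#' @param min_object_px small-object cutoff (default 10 px).
#' @param opening_radius disc radius of the opening kernel, px.
#' @return a `labeled_image` (integer label matrix, 0 = background,
#'   labels consecutive from 1).
#' @export
segment_channel <- function(image, pixel_size = 0.5, min_object_px = 10L,
                            opening_radius = 2L) {
  if (is.null(dim(image)) || length(dim(image)) != 2L)
    stopf("image must be a 2D array")
  # stretch to the 1st-99.9th percentiles: the upper anchor must reach
  # into the cells even when they cover well under 1% of the frame
  qs <- quantile(image, c(0.01, 0.999), names = FALSE)
  if (diff(qs) == 0) stopf("degenerate threshold: constant image")
  img <- clamp((image - qs[1]) / (qs[2] - qs[1]), 0, 1)
  img <- wiener_filter(img)
  mask <- img > otsu_threshold(img)
  labels <- label_components_8(mask)
  labels <- remove_border_objects(labels, 1L)
  mask <- EBImage::fillHull(labels > 0)
  brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
  mask <- EBImage::opening(mask, brush)
  labels <- label_components_8(as.matrix(mask) > 0)
  sizes <- tabulate(labels[labels > 0])
  drop <- which(sizes < min_object_px)
  labels[labels %in% drop] <- 0L
  labeled_image(relabel(labels), pixel_size, channels = list(image))
}

#' Split touching cells by marker-based watershed
#'
#' Interior maxima of the Euclidean distance transform (peaks separated by
#' at least the minimum expected cell radius) seed a watershed that splits
#' touching cells; components with a single maximum pass through unchanged,
#' so the label count never decreases.
#'
#' @param labeled a `labeled_image`.
#' @param min_separation_um minimum peak separation, um (default 5, a
#'   typical nuclear radius).
#' @return a `labeled_image` with split components.
#' @export
watershed_split <- function(labeled, min_separation_um = 5) {
  stopifnot(inherits(labeled, "labeled_image"))
  mask <- labeled$labels > 0
  if (!any(mask)) return(labeled)
  ext <- max(1L, round(min_separation_um / labeled$pixel_size / 2))
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = ext)
  out <- labeled_image(relabel(as.matrix(ws)), labeled$pixel_size,
                       labeled$channels)
  if (out$n_objects < labeled$n_objects) labeled else out
}

#' Dual-threshold fusion segmentation (engraftment pipeline)
#'
#' Normalizes intensities to \[0, 1\], applies a small Gaussian blur, masks
#' at a low threshold (default 0.10) to capture dim cells, runs a closing
#' then an opening (disc radius 2 px), labels connected components, and
#' keeps only components containing at least one pixel above the high
#' threshold (default 0.30) — high recall from the low mask, high
#' precision from the high mask.  Finally all pixels within `border_px`
#' of the image border are deleted and emptied labels dropped.
#'
#' @param image 2D numeric matrix.
#' @param pixel_size um per pixel.
#' @param low,high the two intensity thresholds on the normalized scale.
#' @param sigma Gaussian blur standard deviation, px.
#' @param radius disc radius for closing/opening, px.
#' @param border_px border frame deleted at the end (default 5).
#' @return a `labeled_image`; a constant image yields zero labels (not an
#'   error).
#' @export
fusion_segment <- function(image, pixel_size = 0.6, low = 0.10, high = 0.30,
                           sigma = 1, radius = 2L, border_px = 5L) {
  if (is.null(dim(image)) || length(dim(image)) != 2L)
    stopf("image must be a 2D array")
  rng <- range(image)
  empty <- function() labeled_image(
    matrix(0L, nrow(image), ncol(image)), pixel_size, list(image))
  if (diff(rng) == 0) return(empty())
  img <- (image - rng[1]) / (rng[2] - rng[1])
  img <- as.matrix(EBImage::gblur(img, sigma = sigma))
  low_mask <- img > low
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  low_mask <- EBImage::opening(EBImage::closing(low_mask, brush), brush)
  labels <- label_components_8(as.matrix(low_mask) > 0)
  if (max(labels) == 0L) return(empty())
  high_mask <- img > high
  keep <- sort(unique(labels[labels > 0 & high_mask]))
  labels[!(labels %in% keep)] <- 0L
  d <- dim(labels)
  if (border_px > 0) {
    labels[c(seq_len(border_px), (d[1] - border_px + 1):d[1]), ] <- 0L
    labels[, c(seq_len(border_px), (d[2] - border_px + 1):d[2])] <- 0L
  }
  labeled_image(relabel(labels), pixel_size, list(image))
}
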