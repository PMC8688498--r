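# Internal raster helpers shared by the synthetic-image generators.
# Images are plain numeric matrices in [0, 1], indexed [row, col] with the
# origin at the top-left; physical scale comes from a pixel_size (um/px).

# Logical mask of a filled, rotated ellipse.  a, b: semi-axes (px);
# angle in degrees, measured from the +col axis toward +row (y down).
ellipse_mask <- function(dim, center, a, b, angle_deg = 0) {
  th <- angle_deg * pi / 180
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  dr <- rows - center[1]
  dc <- cols - center[2]
  u <- dc * cos(th) + dr * sin(th)
  v <- -dc * sin(th) + dr * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# Pixel coordinates (row, col) of a filled rotated ellipse, restricted to
# the image; computed on the bounding box only.
ellipse_pixels <- function(dim, center, a, b, angle_deg = 0) {
  ext <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, floor(center[1] - ext)); r1 <- min(dim[1], ceiling(center[1] + ext))
  c0 <- max(1L, floor(center[2] - ext)); c1 <- min(dim[2], ceiling(center[2] + ext))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  rr <- r0:r1; cc <- c0:c1
  th <- angle_deg * pi / 180
  dr <- matrix(rr - center[1], length(rr), length(cc))
  dc <- matrix(cc - center[2], length(rr), length(cc), byrow = TRUE)
  u <- dc * cos(th) + dr * sin(th)
  v <- -dc * sin(th) + dr * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
}

px_index <- function(dim, px) (px[, "col"] - 1L) * dim[1] + px[, "row"]

# Render cells (amplitude `amp`), Gaussian-smooth, then add background and
# Gaussian noise scaled so that amp / noise_sd = snr.  Clipped to [0, 1].
finish_channel <- function(canvas, snr, amp = 0.7, background = 0.02,
                           sigma = 1) {
  img <- EBImage::gblur(canvas, sigma = sigma)
  img <- img + background +
    matrix(rnorm(length(canvas), sd = amp / snr), nrow(canvas))
  clamp(as.matrix(img), 0, 1)
}
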