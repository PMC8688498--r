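# Independent brute-force oracles and small fixture builders used across
# the suite.  These re-derive quantities by direct enumeration and must
# stay independent of the package's implementation paths.

# 8-connected component count by breadth-first search over a logical mask
cc_count_8 <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    n <- n + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb$dr[k]; c <- p[2] + nb$dc[k]
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  n
}

# all-ordered-pairs MSD by direct double loop over one or more tracks
brute_msd <- function(tracks, lag_frames) {
  sp <- split(tracks, tracks$particle)
  vals <- unlist(lapply(sp, function(d) {
    n <- nrow(d)
    out <- c()
    for (i in seq_len(n - lag_frames))
      out <- c(out, (d$x_um[i + lag_frames] - d$x_um[i])^2 +
                    (d$y_um[i + lag_frames] - d$y_um[i])^2)
    out
  }))
  mean(vals)
}

# pixel set of a disc of radius r centred in a (2r+pad) square
disc_pixels <- function(r, pad = 10) {
  n <- 2 * r + pad
  ctr <- n / 2
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2),
               arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  idx
}

# labeled_image wrapper around an integer matrix (test construction)
as_labeled <- function(labels, pixel_size = 1) {
  structure(list(labels = labels, pixel_size = pixel_size,
                 channels = NULL, n_objects = max(0L, max(labels))),
            class = "labeled_image")
}

# rectangular blob helper: set a block of a matrix to a value
put_block <- function(m, r0, c0, h, w, value = 1) {
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- value
  m
}
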