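# Two-channel co-localization statistics and single-marker surface
# coverage.

#' Co-localization statistics for two channels
#'
#' Computes the Pearson correlation over all pixels, the Manders
#' coefficients (M1: fraction of channel-A intensity lying where channel B
#' is above its threshold; M2 symmetric), the co-localized pixel fraction
#' \eqn{|A \cap B| / |A \cup B|} of supra-threshold supports, and an
#' optional block-permutation p-value for the Pearson correlation
#' (16-px blocks of one channel are shuffled, preserving local spatial
#' autocorrelation; add-one estimator, so identical channels give
#' \eqn{p = 1/(n_{perm}+1)}).
#'
#' @param ch_a,ch_b numeric matrices of equal dimensions, values in \[0,1\].
#' @param threshold_mode `"otsu"` (per-channel Otsu threshold) or
#'   `"fixed"`.
#' @param thresholds length-2 numeric, used when `threshold_mode="fixed"`.
#' @param n_perm permutations for the p-value (0 disables it).
#' @param block permutation block size, px.
#' @param seed permutation seed.
#' @return list: `pearson_r`, `m1`, `m2`, `coloc_fraction`, `p_value`,
#'   `thresholds` (named). A channel with no supra-threshold pixels yields
#'   `NA` for its Manders coefficient.
#' @export
coloc_stats <- function(ch_a, ch_b, threshold_mode = c("otsu", "fixed"),
                        thresholds = c(0.1, 0.1), n_perm = 500,
                        block = 16L, seed = 1234) {
  threshold_mode <- match.arg(threshold_mode)
  if (!identical(dim(ch_a), dim(ch_b)))
    stopf("channels must have identical dimensions")
  th <- if (threshold_mode == "otsu") {
    c(otsu_threshold(ch_a), otsu_threshold(ch_b))
  } else thresholds
  a_up <- ch_a > th[1]
  b_up <- ch_b > th[2]
  r <- if (sd(ch_a) == 0 || sd(ch_b) == 0) NA_real_
       else cor(as.vector(ch_a), as.vector(ch_b))
  m1 <- if (any(b_up)) sum(ch_a[b_up]) / sum(ch_a) else NA_real_
  m2 <- if (any(a_up)) sum(ch_b[a_up]) / sum(ch_b) else NA_real_
  either <- sum(a_up | b_up)
  coloc <- if (either > 0) sum(a_up & b_up) / either else NA_real_
  p <- NA_real_
  if (n_perm > 0 && is.finite(r)) {
    p <- with_seed(seed, {
      nbc <- ceiling(ncol(ch_b) / block)
      bi <- (seq_len(nrow(ch_b)) - 1L) %/% block
      bj <- (seq_len(ncol(ch_b)) - 1L) %/% block
      blk <- outer(bi, bj, function(x, y) x * nbc + y)
      grp <- split(seq_along(blk), as.vector(blk))
      # permute only among blocks of equal pixel count (edge blocks are
      # smaller and shuffle within their own size group)
      sizes <- lengths(grp)
      av <- as.vector(ch_b)
      hits <- 0L
      for (k in seq_len(n_perm)) {
        bperm <- av
        for (sz in unique(sizes)) {
          g <- grp[sizes == sz]
          if (length(g) < 2L) next
          pg <- sample(length(g))
          bperm[unlist(g, use.names = FALSE)] <-
            av[unlist(g[pg], use.names = FALSE)]
        }
        if (cor(as.vector(ch_a), bperm) >= r) hits <- hits + 1L
      }
      (1 + hits) / (n_perm + 1)
    })
  }
  list(pearson_r = r, m1 = m1, m2 = m2, coloc_fraction = coloc,
       p_value = p, thresholds = setNames(th, c("a", "b")))
}

#' Surface coverage of a single marker
#'
#' Percentage of pixels whose intensity exceeds the threshold, counted
#' with a small intensity tolerance at the comparison (a pixel within
#' `tolerance` below the threshold still counts).
#'
#' @param channel 2D numeric matrix.
#' @param threshold intensity threshold on the \[0, 1\] scale.
#' @param tolerance intensity tolerance (default 1e-4, i.e. 0.01%).
#' @return list: `colored_px`, `total_px`, `coverage` (percent).
#' @export
surface_coverage <- function(channel, threshold, tolerance = 1e-4) {
  if (is.null(dim(channel)) || length(dim(channel)) != 2L)
    stopf("channel must be a 2D array")
  colored <- sum(channel > threshold - tolerance)
  list(colored_px = colored, total_px = length(channel),
       coverage = 100 * colored / length(channel))
}

#' Per-cell co-localization over a segmented field
#'
#' For each labelled cell, computes [coloc_stats()] on the two channels
#' restricted to the cell's bounding box (padded by 2 px), with fixed
#' thresholds.
#'
#' @param labeled a `labeled_image` (e.g. from [fusion_segment()]).
#' @param ch_a,ch_b the two channel matrices.
#' @param threshold fixed intensity threshold applied to both channels.
#' @param n_perm permutations per cell (default 0: statistics only).
#' @return data.frame: `label`, `pearson_r`, `m1`, `m2`, `coloc_fraction`.
#' @export
coloc_per_cell <- function(labeled, ch_a, ch_b, threshold = 0.2,
                           n_perm = 0) {
  stopifnot(inherits(labeled, "labeled_image"))
  if (labeled$n_objects == 0L)
    return(data.frame(label = integer(0), pearson_r = numeric(0),
                      m1 = numeric(0), m2 = numeric(0),
                      coloc_fraction = numeric(0)))
  idx <- which(labeled$labels > 0, arr.ind = TRUE)
  lab <- labeled$labels[labeled$labels > 0]
  d <- dim(labeled$labels)
  rows <- lapply(seq_len(labeled$n_objects), function(k) {
    px <- idx[lab == k, , drop = FALSE]
    r0 <- max(1L, min(px[, 1]) - 2L); r1 <- min(d[1], max(px[, 1]) + 2L)
    c0 <- max(1L, min(px[, 2]) - 2L); c1 <- min(d[2], max(px[, 2]) + 2L)
    cs <- coloc_stats(ch_a[r0:r1, c0:c1], ch_b[r0:r1, c0:c1],
                      threshold_mode = "fixed",
                      thresholds = c(threshold, threshold), n_perm = n_perm)
    data.frame(label = k, pearson_r = cs$pearson_r, m1 = cs$m1,
               m2 = cs$m2, coloc_fraction = cs$coloc_fraction)
  })
  do.call(rbind, rows)
}
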