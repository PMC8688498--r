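# Gel-ILM interface attachment quantification and OCT gel-mass analysis.

#' Measure gel attachment along the retina boundary
#'
#' Extracts the retina's vitreal (top) boundary as an ordered curve,
#' resamples it at 1-um steps, marks a step attached iff a gel pixel lies
#' within `gap_tolerance_px` of the boundary point, splits the arc into
#' consecutive 200-um segments, and reports per-segment and overall
#' attachment percentages plus the maximal unattached runs (holes).  A
#' final partial segment is reported but excluded from the per-segment
#' aggregate.
#'
#' @param gel_mask,retina_mask logical matrices of equal size.
#' @param pixel_size um per pixel.
#' @param gap_tolerance_px attachment gap tolerance, px (default 2).
#' @param segment_um segment length, um (default 200).
#' @return list: `attached` (logical per 1-um step), `overall_percent`,
#'   `segments` (data.frame `segment`, `start_um`, `length_um`,
#'   `percent_attached`, `partial`), `holes` (data.frame `start_um`,
#'   `length_um`).
#' @export
measure_attachment <- function(gel_mask, retina_mask, pixel_size = 1,
                               gap_tolerance_px = 2L, segment_um = 200) {
  stopifnot(identical(dim(gel_mask), dim(retina_mask)))
  W <- ncol(retina_mask)
  boundary <- vapply(seq_len(W), function(cx) {
    r <- which(retina_mask[, cx])
    if (length(r)) r[1] else NA_integer_
  }, integer(1))
  ok <- which(!is.na(boundary))
  if (length(ok) < 2L) stopf("no retina boundary found")
  # arc length along the boundary polyline, um
  dr <- diff(boundary[ok]); dc <- diff(ok)
  arc <- c(0, cumsum(sqrt(dr^2 + dc^2))) * pixel_size
  total_um <- arc[length(arc)]
  if (total_um < segment_um)
    warnf("boundary shorter than one %g um segment", segment_um)
  steps <- seq(0, total_um, by = 1)
  col_at <- round(stats::approx(arc, ok, xout = steps)$y)
  row_at <- round(stats::approx(arc, boundary[ok], xout = steps)$y)
  # gap tolerance applied perpendicular to the interface (a vertical
  # window), so attachment does not bleed sideways across hole edges
  kern <- matrix(1, 2L * gap_tolerance_px + 1L, 1L)
  gel_near <- as.matrix(EBImage::dilate(gel_mask, kern)) > 0
  attached <- gel_near[cbind(row_at, col_at)]

  n <- length(attached)
  seg_id <- pmin((steps %/% segment_um) + 1, ceiling(total_um / segment_um))
  segs <- lapply(sort(unique(seg_id)), function(s) {
    i <- which(seg_id == s)
    data.frame(segment = s, start_um = min(steps[i]),
               length_um = length(i),
               percent_attached = 100 * mean(attached[i]),
               partial = length(i) < segment_um)
  })
  segs <- do.call(rbind, segs)
  r <- rle(!attached)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  holes <- data.frame(start_um = steps[starts[r$values]],
                      length_um = r$lengths[r$values])
  list(attached = attached,
       overall_percent = 100 * mean(attached),
       segments = segs, holes = holes)
}

#' Aggregate attachment over multiple slides
#'
#' Runs [measure_attachment()] per slide and aggregates: the overall
#' percentage over all steps of all slides, and the per-position heat map
#' (fraction of slides attached at each arc position, truncated to the
#' shortest slide).
#'
#' @param slides list with elements carrying `gel_mask` and `retina_mask`
#'   (e.g. from [render_interface()]), or a list of such masks pairs.
#' @param pixel_size um per pixel.
#' @param ... passed to [measure_attachment()].
#' @return list: `overall_percent`, `per_slide` (data.frame),
#'   `heatmap` (numeric in \[0,1\] per arc position), `results`
#'   (per-slide details).
#' @export
aggregate_attachment <- function(slides, pixel_size = 1, ...) {
  res <- lapply(slides, function(s)
    measure_attachment(s$gel_mask, s$retina_mask, pixel_size, ...))
  n_min <- min(vapply(res, function(r) length(r$attached), integer(1)))
  flags <- vapply(res, function(r) r$attached[seq_len(n_min)],
                  logical(n_min))
  all_steps <- unlist(lapply(res, `[[`, "attached"))
  list(overall_percent = 100 * mean(all_steps),
       per_slide = data.frame(
         slide = seq_along(res),
         percent = vapply(res, `[[`, numeric(1), "overall_percent"),
         n_holes = vapply(res, function(r) nrow(r$holes), integer(1))),
       heatmap = rowMeans(flags),
       results = res)
}

#' Register and project an OCT frame stack
#'
#' Frames are registered to the first by integer-pixel translation
#' estimated with phase correlation; frames whose estimated shift exceeds
#' 25% of the frame size are dropped with a warning.  Returns the mean
#' z-projection of the aligned frames.
#'
#' @param frames 3D array (row, col, frame) or list of matrices.
#' @return 2D matrix, with attribute `shifts` (matrix of applied
#'   row/col shifts).
#' @export
preprocess_oct <- function(frames) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  nf <- dim(frames)[3]
  ref <- frames[, , 1]
  d <- dim(ref)
  acc <- ref; n_used <- 1L
  shifts <- matrix(0L, nf, 2)
  if (nf > 1) {
    Fref <- stats::fft(ref)
    for (k in 2:nf) {
      Fk <- stats::fft(frames[, , k])
      cp <- Fref * Conj(Fk)
      cp <- cp / pmax(Mod(cp), 1e-12)
      corr <- Re(stats::fft(cp, inverse = TRUE))
      pk <- which.max(corr)
      pr <- (pk - 1) %% d[1]
      pc <- (pk - 1) %/% d[1]
      # displacement of frame k relative to the reference
      sr <- -(if (pr > d[1] / 2) pr - d[1] else pr)
      sc <- -(if (pc > d[2] / 2) pc - d[2] else pc)
      shifts[k, ] <- c(sr, sc)
      if (abs(sr) > 0.25 * d[1] || abs(sc) > 0.25 * d[2]) {
        warnf("dropping frame %d: shift (%d, %d) exceeds 25%% of frame",
              k, sr, sc)
        next
      }
      shifted <- matrix(0, d[1], d[2])
      src_r <- seq_len(d[1]) + sr
      src_c <- seq_len(d[2]) + sc
      vr <- src_r >= 1 & src_r <= d[1]
      vc <- src_c >= 1 & src_c <= d[2]
      shifted[vr, vc] <- frames[src_r[vr], src_c[vc], k]
      acc <- acc + shifted
      n_used <- n_used + 1L
    }
  }
  structure(acc / n_used, shifts = shifts)
}

#' Surplus gel pixels in an OCT image
#'
#' Otsu-foreground pixel count minus the control-scan baseline, clamped at
#' zero: with the retina processed as background via the baseline, the
#' surplus foreground counts gel.
#'
#' @param oct_image 2D matrix.
#' @param baseline_foreground_px baseline foreground count from control
#'   scans of the same geometry (see [baseline_foreground()]).
#' @return gel pixel count (numeric).
#' @export
quantify_gel <- function(oct_image, baseline_foreground_px) {
  fg <- sum(oct_image > otsu_threshold(oct_image))
  max(0, fg - baseline_foreground_px)
}

#' Baseline foreground count from control scans
#'
#' Mean Otsu-foreground pixel count over control (no-injection) scans.
#'
#' @param control_images list of 2D matrices (>= 1; >= 3 recommended).
#' @return mean foreground count.
#' @export
baseline_foreground <- function(control_images) {
  mean(vapply(control_images, function(img)
    sum(img > otsu_threshold(img)), numeric(1)))
}

#' Normalized gel-mass time series from per-day OCT stacks
#'
#' Each day's stack is registered and projected with [preprocess_oct()],
#' quantified with [quantify_gel()], and normalized to the day-0 count.
#'
#' @param stacks named or ordered list of per-day frame stacks.
#' @param baseline_foreground_px control baseline.
#' @param days day indices (default `seq_along(stacks) - 1`).
#' @return data.frame: `day`, `gel_px`, `normalized_mass`.
#' @export
gel_mass_series <- function(stacks, baseline_foreground_px,
                            days = seq_along(stacks) - 1) {
  gel_px <- vapply(stacks, function(s)
    quantify_gel(preprocess_oct(s), baseline_foreground_px), numeric(1))
  if (gel_px[1] <= 0)
    stopf("day-0 gel pixel count is zero; cannot normalize")
  data.frame(day = days, gel_px = gel_px,
             normalized_mass = gel_px / gel_px[1])
}
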