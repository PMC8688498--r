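# Shared I/O and configuration: TIFF reading/writing with metadata
# sidecars, run configuration, and versioned JSON/CSV reports.

#' Pipeline run configuration
#'
#' Bundles the constants shared across the segmentation and interface
#' pipelines, with validation.  Defaults carry the printed rules of the
#' procedures: low/high fusion thresholds 0.10/0.30, minimum object size
#' 10 px, 5-px border deletion, 200-um interface segments, 2-px gap
#' tolerance.
#'
#' @param pixel_size um per pixel.
#' @param z_step um per z-slice.
#' @param low_threshold,high_threshold fusion-segmentation thresholds.
#' @param opening_radius,closing_radius structuring-element radii, px.
#' @param min_object_px small-object cutoff.
#' @param border_px deleted border frame, px.
#' @param segment_length_um interface segment length.
#' @param gap_tolerance_px attachment gap tolerance.
#' @param seed default seed.
#' @return a `run_config` list.
#' @export
run_config <- function(pixel_size = 0.6, z_step = 1,
                       low_threshold = 0.10, high_threshold = 0.30,
                       opening_radius = 2L, closing_radius = 2L,
                       min_object_px = 10L, border_px = 5L,
                       segment_length_um = 200, gap_tolerance_px = 2L,
                       seed = .default_seed) {
  cfg <- list(pixel_size = pixel_size, z_step = z_step,
              low_threshold = low_threshold,
              high_threshold = high_threshold,
              opening_radius = opening_radius,
              closing_radius = closing_radius,
              min_object_px = min_object_px, border_px = border_px,
              segment_length_um = segment_length_um,
              gap_tolerance_px = gap_tolerance_px, seed = seed)
  for (f in c("pixel_size", "z_step", "segment_length_um"))
    check_number(cfg[[f]], f, 0, closed_lower = FALSE)
  check_number(low_threshold, "low_threshold", 0, 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(high_threshold, "high_threshold", 0, 1,
               closed_lower = FALSE, closed_upper = FALSE)
  if (low_threshold >= high_threshold)
    stopf("low_threshold must be below high_threshold")
  structure(cfg, class = c("run_config", "list"))
}

#' Read a TIFF image with metadata
#'
#' Reads single- or multi-page 8/16-bit TIFFs as \[0, 1\] float matrices
#' (multi-page files become 3D arrays).  Physical metadata (pixel size,
#' z-step) is taken from arguments, or from a `<path>.json` sidecar when
#' present; an error is raised when a um-valued operation would need
#' metadata that is unavailable.
#'
#' @param path TIFF file path.
#' @param pixel_size,z_step optional metadata overrides (um).
#' @param require_metadata error when no pixel size is available.
#' @return matrix or 3D array with attributes `pixel_size`, `z_step`.
#' @export
read_image <- function(path, pixel_size = NULL, z_step = NULL,
                       require_metadata = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stopf("unreadable TIFF %s: %s",
                                              path, conditionMessage(e)))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  pixel_size <- pixel_size %||% meta$pixel_size
  z_step <- z_step %||% meta$z_step
  if (require_metadata && is.null(pixel_size))
    stopf("pixel size required but not provided (argument or %s)", sidecar)
  img <- if (length(pages) == 1L) pages[[1]] else simplify2array(pages)
  if (length(dim(img)) > 2L && !is.na(dim(img)[3]) && length(pages) == 1L)
    img <- img[, , 1]  # collapse RGB planes of a grayscale-coded page
  attr(img, "pixel_size") <- pixel_size
  attr(img, "z_step") <- z_step
  img
}

#' Write an image (and optional metadata sidecar) as 16-bit TIFF
#'
#' @param img matrix or 3D array in \[0, 1\].
#' @param path output path.
#' @param pixel_size,z_step optional metadata written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, pixel_size = NULL, z_step = NULL) {
  imgs <- if (length(dim(img)) == 3L)
    lapply(seq_len(dim(img)[3]), function(k) img[, , k]) else img
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  if (!is.null(pixel_size) || !is.null(z_step))
    jsonlite::write_json(
      Filter(Negate(is.null),
             list(pixel_size = pixel_size, z_step = z_step)),
      paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a reproducible analysis report
#'
#' Serializes scalar results, the configuration (with an md5 content
#' hash) and seeds into a versioned JSON file; any data.frame elements of
#' `results` are additionally written as CSV tables next to it.
#'
#' @param results named list; data.frames become CSV side files.
#' @param path output JSON path.
#' @param config optional [run_config()] echoed into the report.
#' @return list of files written, invisibly.
#' @export
write_report <- function(results, path, config = NULL) {
  stopifnot(is.list(results))
  is_df <- vapply(results, is.data.frame, logical(1))
  files <- path
  for (nm in names(results)[is_df]) {
    csv <- file.path(dirname(path),
                     paste0(sub("\\.json$", "", basename(path)),
                            "_", nm, ".csv"))
    write.csv(results[[nm]], csv, row.names = FALSE)
    files <- c(files, csv)
  }
  cfg_hash <- NULL
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                         digits = NA)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  payload <- list(schema_version = "1.0",
                  results = results[!is_df],
                  tables = names(results)[is_df],
                  config = if (is.null(config)) NULL else unclass(config),
                  config_md5 = cfg_hash)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(files)
}

#' Read back a report written by [write_report()]
#'
#' @param path JSON report path.
#' @return the parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
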