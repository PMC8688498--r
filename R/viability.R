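# Live/dead viability aggregation and z-distribution profiles.

#' Viability from segmented live and dead channels
#'
#' Per-field and pooled viability: 100 x live / (live + dead).  Fields with
#' zero cells are excluded with a warning.  The across-field summary is
#' mean +/- SEM computed over fields (not over cells), matching replicate
#' reporting of multi-field assays.
#'
#' @param live_labeled,dead_labeled a `labeled_image` or a list of them
#'   (one per field; both lists must have equal length).
#' @return list: `per_field` (data.frame `field`, `n_live`, `n_dead`,
#'   `viability`), `n_live`, `n_dead`, `viability` (pooled, percent),
#'   `mean` and `sem` across fields.
#' @export
viability <- function(live_labeled, dead_labeled) {
  as_list <- function(x) if (inherits(x, "labeled_image")) list(x) else x
  lv <- as_list(live_labeled); dd <- as_list(dead_labeled)
  if (length(lv) != length(dd))
    stopf("live and dead field lists differ in length")
  nl <- vapply(lv, function(x) x$n_objects, integer(1))
  nd <- vapply(dd, function(x) x$n_objects, integer(1))
  tot <- nl + nd
  if (any(tot == 0))
    warnf("excluding %d field(s) with zero cells", sum(tot == 0))
  keep <- tot > 0
  per_field <- data.frame(field = which(keep), n_live = nl[keep],
                          n_dead = nd[keep],
                          viability = 100 * nl[keep] / tot[keep])
  v <- per_field$viability
  list(per_field = per_field,
       n_live = sum(nl[keep]), n_dead = sum(nd[keep]),
       viability = if (sum(tot[keep])) 100 * sum(nl[keep]) / sum(tot[keep])
                   else NA_real_,
       mean = mean(v),
       sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
}

#' Axial intensity distribution of a z-stack
#'
#' Mean intensity per z-slab of physical thickness `block` um, normalized
#' to the maximum slab; a flat profile indicates uniform 3D distribution
#' of cells in the gel, while a monolayer peaks in the first slab.
#'
#' @param stack 3D array (row, col, z).
#' @param z_step z spacing, um per slice.
#' @param block slab thickness, um (default 150).
#' @return data.frame: `slab`, `z_um` (slab centre), `intensity`
#'   (normalized).
#' @export
z_profile <- function(stack, z_step, block = 150) {
  if (length(dim(stack)) != 3L) stopf("stack must be a 3D array")
  nz <- dim(stack)[3]
  z <- (seq_len(nz) - 1) * z_step
  slab <- floor(z / block)
  if (max(z) < block)
    warnf("stack thinner than one %g um block; single-slab profile", block)
  means <- vapply(sort(unique(slab)), function(s)
    mean(stack[, , slab == s, drop = FALSE]), numeric(1))
  mx <- max(means)
  data.frame(slab = sort(unique(slab)),
             z_um = (sort(unique(slab)) + 0.5) * block,
             intensity = if (mx > 0) means / mx else means)
}
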