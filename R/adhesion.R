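#' Cell counts on and off micropatterns
#'
#' @param n_on cells whose centroid lies on a labeled pattern pixel.
#' @param area_on total pattern area, square micrometres.
#' @param n_off cells off-pattern.
#' @param area_off off-pattern area, square micrometres.
#' @param condition optional condition label (e.g. the coating).
#' @param reference logical; marks the normalization reference condition
#'   (e.g. the Con A sample).
#' @return A `cell_counts` object.
#' @export
cell_counts <- function(n_on, area_on, n_off, area_off,
                        condition = NA_character_, reference = FALSE) {
  stopifnot(n_on >= 0, n_off >= 0, area_on >= 0, area_off >= 0)
  if ((n_on > 0 && area_on <= 0) || (n_off > 0 && area_off <= 0))
    stop("cells counted in a region of zero area")
  structure(list(n_on = as.integer(n_on), area_on = area_on,
                 n_off = as.integer(n_off), area_off = area_off,
                 condition = condition, reference = isTRUE(reference)),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf(
    "<cell_counts>%s %d cells on %.4g um^2 pattern, %d on %.4g um^2 off-pattern\n",
    if (!is.na(x$condition)) paste0(" [", x$condition, "]") else "",
    x$n_on, x$area_on, x$n_off, x$area_off))
  invisible(x)
}

#' Assign cell centroids to micropatterns
#'
#' A cell is "on" a pattern iff its centroid lies on a labeled pixel (the
#' centroid rule; partial overlap without centroid containment counts as
#' off). The mask should already be diameter-filtered (see
#' [filter_by_diameter()]) when applying the small-pattern analysis rule.
#'
#' @param centroids data.frame with columns `x`, `y` (pixels, 1-based).
#' @param mask a [label_mask()].
#' @param condition,reference passed to [cell_counts()].
#' @return A [cell_counts()]; per-cell assignments are attached as the
#'   `"labels"` attribute.
#' @export
assign_cells <- function(centroids, mask, condition = NA_character_,
                         reference = FALSE) {
  stopifnot(inherits(mask, "label_mask"),
            all(c("x", "y") %in% names(centroids)))
  ps <- pixel_size(mask)
  xi <- round(centroids$x); yi <- round(centroids$y)
  if (any(xi < 1 | xi > ncol(mask) | yi < 1 | yi > nrow(mask)))
    stop("centroid outside field bounds")
  labs <- unclass(mask)[cbind(yi, xi)]
  n_on <- sum(labs > 0)
  area_on <- sum(mask > 0) * ps^2
  area_off <- sum(mask == 0) * ps^2
  out <- cell_counts(n_on, area_on, nrow(centroids) - n_on, area_off,
                     condition = condition, reference = reference)
  attr(out, "labels") <- labs
  out
}

#' Mean patterned cell density of a reference condition
#'
#' @param counts a [cell_counts()] or list of them (one per field of view).
#' @return Mean of the per-field on-pattern densities, cells per square
#'   micrometre.
#' @export
reference_density <- function(counts) {
  if (inherits(counts, "cell_counts")) counts <- list(counts)
  mean(vapply(counts, function(cc) cc$n_on / cc$area_on, numeric(1)))
}

#' Normalized patterned cell density
#'
#' On-pattern cell density divided by the mean on-pattern density of the
#' reference condition:
#' \deqn{\frac{n_{on}/A_{on}}{\overline{(n_{on}/A_{on})}_{ref}}}
#'
#' @param sample a [cell_counts()].
#' @param reference_mean_density reference density, cells per square
#'   micrometre (see [reference_density()]).
#' @return Unitless normalized density.
#' @export
normalized_density <- function(sample, reference_mean_density) {
  stopifnot(inherits(sample, "cell_counts"))
  if (!is.numeric(reference_mean_density) || reference_mean_density <= 0)
    stop("reference density must be > 0")
  (sample$n_on / sample$area_on) / reference_mean_density
}

#' Normalized nonspecific adhesion
#'
#' Percentage of cell density falling off-pattern:
#' \deqn{100\left(1 - \frac{n_{on}/A_{on}}
#'   {n_{on}/A_{on} + n_{off}/A_{off}}\right)
#'   = 100\,\frac{d_{off}}{d_{on} + d_{off}}}
#' 50 at equal densities, 0 for perfectly specific adhesion; always in
#' [0, 100].
#'
#' @param sample a [cell_counts()].
#' @return Percentage, or [unmeasurable()] when both densities are zero.
#' @export
nonspecific_adhesion <- function(sample) {
  stopifnot(inherits(sample, "cell_counts"))
  d_on <- if (sample$area_on > 0) sample$n_on / sample$area_on else 0
  d_off <- if (sample$area_off > 0) sample$n_off / sample$area_off else 0
  if (d_on + d_off == 0)
    return(unmeasurable("no cells in either region"))
  100 * (1 - d_on / (d_on + d_off))
}
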