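#' Label mask of micropattern regions
#'
#' An integer matrix where 0 is background and each positive value labels one
#' connected micropattern.
#'
#' @param data integer matrix of labels.
#' @param pixel_size micrometres per pixel.
#' @return A `label_mask`.
#' @export
label_mask <- function(data, pixel_size = 0.11) {
  stopifnot(is.matrix(data), pixel_size > 0)
  storage.mode(data) <- "integer"
  if (any(data < 0)) stop("labels must be >= 0")
  structure(data, pixel_size = pixel_size,
            class = c("label_mask", class(data)))
}

#' @export
print.label_mask <- function(x, ...) {
  labs <- setdiff(unique(as.integer(x)), 0L)
  cat(sprintf("<label_mask> %d x %d px, %d labels, %.3g um/px\n",
              nrow(x), ncol(x), length(labs), attr(x, "pixel_size")))
  invisible(x)
}

#' Per-label areas and equivalent diameters
#'
#' @param mask a [label_mask()].
#' @return `data.frame` with `label`, `n_pixels`, `area_um2` and
#'   `diameter_um` (equivalent diameter `2 * sqrt(area / pi)`).
#' @export
label_areas <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  ps <- pixel_size(mask)
  labs <- as.integer(mask)
  labs <- labs[labs > 0]
  if (length(labs) == 0)
    return(data.frame(label = integer(0), n_pixels = integer(0),
                      area_um2 = numeric(0), diameter_um = numeric(0)))
  tab <- table(labs)
  area <- as.numeric(tab) * ps^2
  data.frame(label = as.integer(names(tab)),
             n_pixels = as.integer(tab),
             area_um2 = area,
             diameter_um = 2 * sqrt(area / pi))
}

# Merge 4-connected labels that touch diagonally into 8-connected components
# (union-find over the small label graph).
merge_diagonal <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment micropatterns from an anchor-fluorescence channel
#'
#' Thresholds the (optionally Gaussian-smoothed) anchor channel, fills holes,
#' removes components below a minimum area, and labels the remaining
#' connected components. Manual ROI masks remain first-class inputs
#' elsewhere; this provides a reproducible automatic alternative.
#'
#' @param anchor an [image_frame()] (or matrix plus `pixel_size`).
#' @param min_area minimum component area to keep, in square micrometres.
#' @param method `"otsu"` (default) or `"fixed_threshold"`.
#' @param threshold intensity threshold in ADU, required for
#'   `"fixed_threshold"`.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels (0 disables).
#' @param connectivity 8 (default) or 4.
#' @param pixel_size used when `anchor` is a bare matrix.
#' @return A [label_mask()]. When nothing survives, an empty mask is
#'   returned with a warning (not an error).
#' @export
segment_patterns <- function(anchor, min_area = 10,
                             method = c("otsu", "fixed_threshold"),
                             threshold = NULL, smooth_sigma = 1,
                             connectivity = 8, pixel_size = NULL) {
  method <- match.arg(method)
  stopifnot(connectivity %in% c(4, 8))
  ps <- if (inherits(anchor, "image_frame")) pixel_size(anchor)
        else if (!is.null(pixel_size)) pixel_size
        else 0.11
  img <- unclass(anchor)
  attributes(img) <- list(dim = dim(img))
  rng <- range(img)
  if (diff(rng) <= 0) stop("anchor image has no dynamic range")
  work <- if (smooth_sigma > 0) EBImage::gblur(img, sigma = smooth_sigma)
          else img
  if (method == "otsu") {
    norm <- (work - min(work)) / (max(work) - min(work))
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    bin <- norm > thr
    # Otsu always splits something, including pure noise: require the
    # foreground to stand clear of the background spread
    if (any(bin) && !all(bin) &&
        mean(work[bin]) - mean(work[!bin]) < 3 * stats::mad(work)) {
      warning("no component survived segmentation; returning empty mask")
      return(label_mask(matrix(0L, nrow(img), ncol(img)), pixel_size = ps))
    }
  } else {
    if (is.null(threshold)) stop("fixed_threshold requires a threshold")
    bin <- work > threshold
  }
  bin <- EBImage::fillHull(matrix(as.integer(bin), nrow(img), ncol(img)))
  lab <- EBImage::bwlabel(bin)          # 4-connected
  lab <- matrix(as.integer(round(lab)), nrow(img), ncol(img))
  if (connectivity == 8 && max(lab) > 1) lab <- merge_diagonal(lab)
  if (max(lab) > 0) {
    tab <- tabulate(lab[lab > 0])
    keep <- which(tab * ps^2 >= min_area)
    lab[!(lab %in% keep)] <- 0L
    if (length(keep)) lab[lab > 0] <- match(lab[lab > 0], sort(keep))
  }
  if (max(lab) == 0)
    warning("no component survived segmentation; returning empty mask")
  label_mask(lab, pixel_size = ps)
}

#' Keep micropatterns within a diameter range
#'
#' Retains labels whose equivalent diameter `2*sqrt(area/pi)` lies in
#' `[min_d, max_d]` (inclusive); typically 20-40 um for cell-adhesion
#' analysis, where only small micropatterns are considered. Surviving
#' labels keep their exact pixel sets; labels are renumbered consecutively.
#'
#' @param mask a [label_mask()].
#' @param min_d,max_d diameter bounds in micrometres.
#' @return Filtered [label_mask()].
#' @export
filter_by_diameter <- function(mask, min_d = 20, max_d = 40) {
  stopifnot(inherits(mask, "label_mask"))
  if (min_d > max_d) stop("min_d must be <= max_d")
  info <- label_areas(mask)
  keep <- info$label[info$diameter_um >= min_d & info$diameter_um <= max_d]
  out <- unclass(mask)
  out[!(out %in% keep)] <- 0L
  if (length(keep)) out[out > 0] <- match(out[out > 0], sort(keep))
  label_mask(out, pixel_size = pixel_size(mask))
}
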