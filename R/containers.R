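#' Calibrated image frame
#'
#' Wraps a numeric matrix of intensities (analog-digital units, ADU) with the
#' physical pixel size and an optional channel label. Rows index y, columns
#' index x; pixels are 1-based and pixel-centered, following R matrix
#' conventions.
#'
#' @param data numeric matrix of intensities (ADU).
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param channel optional channel label (e.g. `"ATTO488"`).
#' @return An `image_frame`: the matrix with `pixel_size` and `channel`
#'   attributes.
#' @export
image_frame <- function(data, pixel_size = 0.11, channel = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), pixel_size > 0)
  structure(data,
            pixel_size = pixel_size,
            channel = channel,
            class = c("image_frame", class(data)))
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %.3g um/px%s\n",
              nrow(x), ncol(x), attr(x, "pixel_size"),
              if (!is.null(attr(x, "channel")))
                paste0(", channel ", attr(x, "channel")) else ""))
  invisible(x)
}

#' Time-lapse movie
#'
#' A y-by-x-by-time array of intensities with pixel size and frame interval.
#'
#' @param data numeric 3D array (y, x, t) of intensities (ADU).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between consecutive frames.
#' @param channel optional channel label.
#' @return A `time_lapse` array.
#' @export
time_lapse <- function(data, pixel_size = 0.11, frame_interval = 1,
                       channel = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, pixel_size > 0)
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  structure(data,
            pixel_size = pixel_size,
            frame_interval = frame_interval,
            channel = channel,
            class = c("time_lapse", class(data)))
}

#' @export
print.time_lapse <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<time_lapse> %d x %d px, %d frames, %.3g um/px, %.3g s/frame\n",
              d[1], d[2], d[3], attr(x, "pixel_size"),
              attr(x, "frame_interval")))
  invisible(x)
}

#' Pixel size of an image or movie
#' @param x an `image_frame`, `time_lapse` or `label_mask`.
#' @return micrometres per pixel.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) stop("object carries no pixel_size attribute")
  ps
}

#' Summary statistics of intensities within one region of interest
#'
#' The atoms of every micropattern metric: arithmetic mean, unbiased
#' (n-1 denominator) sample variance, and pixel count. A single-pixel ROI
#' gets variance 0 and `degenerate = TRUE`.
#'
#' @param mean mean intensity (ADU).
#' @param variance sample variance of intensities (ADU^2).
#' @param n_pixels number of pixels in the region.
#' @param degenerate logical; `TRUE` when the variance is a convention rather
#'   than an estimate (single-pixel ROI).
#' @return A `roi_stats` object.
#' @export
roi_stats <- function(mean, variance, n_pixels, degenerate = FALSE) {
  stopifnot(is.numeric(mean), length(mean) == 1,
            is.numeric(variance), length(variance) == 1,
            n_pixels >= 1)
  if (variance < 0) stop("variance must be >= 0")
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance),
                 n_pixels = as.integer(n_pixels),
                 degenerate = isTRUE(degenerate)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> mean %.4g ADU, var %.4g ADU^2, n = %d%s\n",
              x$mean, x$variance, x$n_pixels,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Camera dark-signal background
#'
#' Mean and variance of the camera signal recorded with no light (lid on).
#' Per the standard usage these values also stand in for the coverslip
#' background, since a passivated coverslip never exposed to fluorophore is
#' indistinguishable from the camera floor.
#'
#' @param mean mean dark intensity (ADU).
#' @param variance dark-signal variance (ADU^2).
#' @return A `camera_background` object.
#' @export
camera_background <- function(mean, variance) {
  stopifnot(is.numeric(mean), is.numeric(variance), length(mean) == 1,
            length(variance) == 1)
  if (variance < 0) stop("variance must be >= 0")
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance)),
            class = "camera_background")
}

#' @export
print.camera_background <- function(x, ...) {
  cat(sprintf("<camera_background> mean %.4g ADU, var %.4g ADU^2\n",
              x$mean, x$variance))
  invisible(x)
}

#' Estimate the camera background from a dark-frame stack
#'
#' Pools the per-pixel mean and per-pixel (n-1) variance across the stack,
#' then averages each over pixels, yielding the single scalar pair used by
#' all background-corrected metrics.
#'
#' @param stack a y-by-x-by-t array of dark frames (or a `time_lapse`).
#' @return A [camera_background()].
#' @export
estimate_camera_background <- function(stack) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  nt <- dim(stack)[3]
  if (nt < 2) stop("need at least 2 dark frames to estimate variance")
  px_mean <- apply(stack, c(1, 2), mean)
  px_var <- apply(stack, c(1, 2), stats::var)
  camera_background(mean(px_mean), mean(px_var))
}

#' Unmeasurable metric result
#'
#' Metrics whose denominator sits at or below the camera floor are reported
#' as a typed "unmeasurable" value (not clipped, not infinite) so downstream
#' aggregation can exclude them explicitly.
#'
#' @param reason short explanation of why the value cannot be measured.
#' @return An `mp_unmeasurable` value (an `NA_real_` carrying the reason).
#' @export
unmeasurable <- function(reason) {
  structure(NA_real_, reason = reason,
            class = c("mp_unmeasurable", "numeric"))
}

#' @rdname unmeasurable
#' @param x object to test.
#' @export
is_unmeasurable <- function(x) inherits(x, "mp_unmeasurable")

#' @export
print.mp_unmeasurable <- function(x, ...) {
  cat(sprintf("<unmeasurable> %s\n", attr(x, "reason")))
  invisible(x)
}

#' Ordered set of sequential micropatterns
#'
#' Holds the masks of sequentially written micropatterns in patterning order
#' together with the channel-to-intended-pattern assignment that drives
#' cross-adsorption normalization (channel c is normalized to the pattern
#' written for it).
#'
#' @param masks named list of logical masks (one per pattern, same dims),
#'   in micropatterning order; names are the pattern ids.
#' @param assignment named character vector mapping channel name to
#'   pattern id.
#' @return A `pattern_set`.
#' @export
pattern_set <- function(masks, assignment) {
  stopifnot(is.list(masks), length(masks) >= 1, !is.null(names(masks)))
  dims <- lapply(masks, dim)
  if (length(unique(dims)) != 1) stop("all masks must share dimensions")
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  acc <- Reduce(`+`, masks)
  if (any(acc > 1)) stop("pattern masks must be disjoint")
  stopifnot(is.character(assignment), !is.null(names(assignment)))
  missing <- setdiff(assignment, names(masks))
  if (length(missing))
    stop("assignment references unknown pattern(s): ",
         paste(missing, collapse = ", "))
  structure(list(masks = masks, assignment = assignment),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d patterns (%s); channels: %s\n",
              length(x$masks), paste(names(x$masks), collapse = ", "),
              paste(sprintf("%s->%s", names(x$assignment), x$assignment),
                    collapse = ", ")))
  invisible(x)
}
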