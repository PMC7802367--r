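#' Measure intensity statistics in a region of interest
#'
#' @param image an [image_frame()] or numeric matrix.
#' @param mask logical matrix of the same dimensions; `TRUE` pixels belong to
#'   the ROI.
#' @return A [roi_stats()] with mean, unbiased sample variance and pixel
#'   count. A one-pixel ROI returns variance 0 with `degenerate = TRUE`.
#' @export
measure_roi <- function(image, mask) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (is.null(dim(mask)) || !all(dim(mask) == dim(image)))
    stop("mask and image dimensions differ")
  mask <- as.logical(mask)
  vals <- as.numeric(image)[mask]
  n <- length(vals)
  if (n == 0) stop("empty mask")
  if (n == 1) return(roi_stats(vals, 0, 1L, degenerate = TRUE))
  roi_stats(mean(vals), stats::var(vals), n)
}

as_roi <- function(x, what) {
  if (inherits(x, "roi_stats")) return(x)
  if (is.numeric(x) && length(x) == 1) return(roi_stats(x, 0, 1L, TRUE))
  stop(what, " must be a roi_stats object")
}

#' Micropatterning selectivity
#'
#' Background-corrected ratio of the on-pattern to off-pattern mean
#' intensity:
#' \deqn{S = \frac{\bar I_{pattern} - \bar I_{camera}}
#'              {\bar I_{notpattern} - \bar I_{camera}}}
#' Higher is cleaner patterning; 1 means no contrast. Being a ratio, it can
#' be compared across fluorophores.
#'
#' @param pattern [roi_stats()] of the on-pattern ROI.
#' @param not_pattern [roi_stats()] of an adjacent off-pattern ROI of
#'   identical size.
#' @param camera [camera_background()].
#' @return The selectivity (unitless), or an [unmeasurable()] result when the
#'   off-pattern mean sits at or below the camera floor.
#' @export
selectivity <- function(pattern, not_pattern, camera) {
  pattern <- as_roi(pattern, "pattern")
  not_pattern <- as_roi(not_pattern, "not_pattern")
  stopifnot(inherits(camera, "camera_background"))
  den <- not_pattern$mean - camera$mean
  if (den <= 0)
    return(unmeasurable("off-pattern mean at or below camera floor"))
  (pattern$mean - camera$mean) / den
}

#' Micropatterning homogeneity
#'
#' Background-corrected on-pattern mean divided by the background-corrected
#' on-pattern variance:
#' \deqn{H = \frac{\bar I_{pattern} - \bar I_{camera}}
#'              {\mathrm{var}\,I_{pattern} - \mathrm{var}\,I_{camera}}}
#' Higher means more uniform deposition. The denominator is the variance
#' (units ADU^-1 for the ratio), as conventionally printed; see
#' [homogeneity_sd()] for the standard-deviation variant, which is never
#' substituted silently.
#'
#' @inheritParams selectivity
#' @return Homogeneity in ADU^-1, or [unmeasurable()] when the pattern
#'   variance does not exceed the camera variance.
#' @export
homogeneity <- function(pattern, camera) {
  pattern <- as_roi(pattern, "pattern")
  stopifnot(inherits(camera, "camera_background"))
  den <- pattern$variance - camera$variance
  if (den <= 0)
    return(unmeasurable("pattern variance at or below camera floor"))
  (pattern$mean - camera$mean) / den
}

#' Standard-deviation variant of homogeneity
#'
#' Same numerator as [homogeneity()], but divided by the square root of the
#' background-corrected variance (a unitless mean/SD, i.e. an inverse
#' coefficient of variation). Exposed under its own name for users who
#' prefer a dimensionless index; never used in place of [homogeneity()].
#'
#' @inheritParams homogeneity
#' @return Unitless mean/SD ratio, or [unmeasurable()].
#' @export
homogeneity_sd <- function(pattern, camera) {
  h <- homogeneity(pattern, camera)
  if (is_unmeasurable(h)) return(h)
  pattern <- as_roi(pattern, "pattern")
  (pattern$mean - camera$mean) /
    sqrt(pattern$variance - camera$variance)
}

#' Amount of protein patterned
#'
#' Difference of the on-pattern and adjacent off-pattern mean intensities,
#' a proxy for the amount of protein specifically deposited. Only comparable
#' within one fluorophore (it also reflects dye photophysics and instrument
#' sensitivity). Negative values (pattern dimmer than surround) are permitted
#' and flagged via the `"negative"` attribute.
#'
#' @inheritParams selectivity
#' @return Intensity difference in ADU.
#' @export
amount_patterned <- function(pattern, not_pattern) {
  pattern <- as_roi(pattern, "pattern")
  not_pattern <- as_roi(not_pattern, "not_pattern")
  out <- pattern$mean - not_pattern$mean
  if (out < 0) attr(out, "negative") <- TRUE
  out
}

#' Normalized cross-adsorption matrix for sequential micropatterns
#'
#' For each imaging channel, the background-corrected mean signal on every
#' pattern is normalized to the background-corrected signal on the channel's
#' intended pattern (the one written for it in the sequential protocol):
#' \deqn{M[c, i] = \frac{\bar I_{c,\,pattern\ i} - \bar I_{bg}}
#'                     {\bar I_{c,\,intended(c)} - \bar I_{bg}}}
#' so each intended entry is exactly 1 and off-diagonal entries are the
#' fraction of protein adsorbed to the wrong pattern.
#'
#' @param images named list of [image_frame()]s (or matrices), one per
#'   channel in `patterns$assignment`.
#' @param patterns a [pattern_set()].
#' @param camera [camera_background()].
#' @return Numeric matrix (channels x patterns) of unitless fractions, with
#'   intended entries identically 1. Channels whose intended-pattern signal
#'   does not exceed background have all entries `NA` and are listed in the
#'   `"unmeasurable_channels"` attribute.
#' @export
cross_adsorption_matrix <- function(images, patterns, camera) {
  stopifnot(inherits(patterns, "pattern_set"),
            inherits(camera, "camera_background"))
  channels <- names(patterns$assignment)
  missing <- setdiff(channels, names(images))
  if (length(missing))
    stop("no image supplied for channel(s): ", paste(missing, collapse = ", "))
  pats <- names(patterns$masks)
  out <- matrix(NA_real_, length(channels), length(pats),
                dimnames = list(channels, pats))
  bad <- character(0)
  for (ch in channels) {
    img <- images[[ch]]
    means <- vapply(patterns$masks,
                    function(m) measure_roi(img, m)$mean, numeric(1))
    intended <- patterns$assignment[[ch]]
    den <- means[[intended]] - camera$mean
    if (den <= 0) {
      bad <- c(bad, ch)
      next
    }
    out[ch, ] <- (means - camera$mean) / den
    out[ch, intended] <- 1  # self-normalization, exact by construction
  }
  if (length(bad)) attr(out, "unmeasurable_channels") <- bad
  out
}

#' Nonspecific binding to the passivated substrate
#'
#' Fraction of a channel's protein found on unexposed, passivated substrate
#' (e.g. PLL-PEG) relative to its intended micropattern:
#' \deqn{\frac{\bar I_{off field} - \bar I_{bg}}
#'            {\bar I_{intended} - \bar I_{bg}}}
#' The off-field ROI must be congruent to the intended-pattern ROI — same
#' shape at the same position in the field of view, with the stage moved to
#' a pattern-free area — so that illumination inhomogeneity cancels.
#'
#' @param images named list of per-channel images of the patterned field.
#' @param offfield_images named list of per-channel images of a matched
#'   pattern-free field.
#' @param patterns a [pattern_set()]; each channel's intended mask is reused,
#'   at the identical field position, on the off-field image.
#' @param camera [camera_background()].
#' @return Named numeric vector of per-channel unitless fractions;
#'   unmeasurable channels are `NA` with a `"reason"` entry in attributes.
#' @export
nonspecific_binding <- function(images, offfield_images, patterns, camera) {
  stopifnot(inherits(patterns, "pattern_set"),
            inherits(camera, "camera_background"))
  channels <- names(patterns$assignment)
  out <- stats::setNames(rep(NA_real_, length(channels)), channels)
  for (ch in channels) {
    img <- images[[ch]]
    off <- offfield_images[[ch]]
    if (is.null(img) || is.null(off))
      stop("missing image for channel ", ch)
    if (!all(dim(off) == dim(img)))
      stop("off-field image for channel ", ch,
           " is not congruent to the patterned field")
    mask <- patterns$masks[[patterns$assignment[[ch]]]]
    on_mean <- measure_roi(img, mask)$mean
    off_mean <- measure_roi(off, mask)$mean
    den <- on_mean - camera$mean
    if (den <= 0) next
    out[ch] <- (off_mean - camera$mean) / den
  }
  out
}

#' Per-pattern metric table
#'
#' Convenience wrapper computing selectivity, homogeneity and amount for
#' every (channel, pattern) pair of a [pattern_set()], with automatic
#' placement of the off-pattern ROI (see [auto_off_roi()]) unless one is
#' supplied.
#'
#' @param images named list of per-channel images.
#' @param patterns a [pattern_set()].
#' @param camera [camera_background()].
#' @param off_mask optional logical matrix: the off-pattern ROI shared by all
#'   patterns. When `NULL`, each pattern gets its own mask translated to the
#'   nearest clear position.
#' @return `data.frame` with columns `pattern_id`, `channel`, `selectivity`,
#'   `homogeneity`, `amount`, `flags`.
#' @export
quantify_patterns <- function(images, patterns, camera, off_mask = NULL) {
  stopifnot(inherits(patterns, "pattern_set"))
  all_pat <- Reduce(`|`, patterns$masks)
  rows <- list()
  for (ch in names(patterns$assignment)) {
    img <- images[[ch]]
    if (is.null(img)) stop("missing image for channel ", ch)
    for (pid in names(patterns$masks)) {
      mask <- patterns$masks[[pid]]
      omask <- if (is.null(off_mask)) auto_off_roi(mask, all_pat) else off_mask
      on <- measure_roi(img, mask)
      off <- measure_roi(img, omask)
      s <- selectivity(on, off, camera)
      h <- homogeneity(on, camera)
      flags <- c(if (is_unmeasurable(s)) "selectivity_unmeasurable",
                 if (is_unmeasurable(h)) "homogeneity_unmeasurable")
      rows[[length(rows) + 1]] <- data.frame(
        pattern_id = pid, channel = ch,
        selectivity = as.numeric(s), homogeneity = as.numeric(h),
        amount = as.numeric(amount_patterned(on, off)),
        flags = if (length(flags)) paste(flags, collapse = ";") else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Automatic placement of the off-pattern ROI
#'
#' Translates a pattern mask to the nearest position whose footprint,
#' dilated by `margin` pixels, avoids every pattern — a deterministic
#' reading of "an off-pattern ROI of identical size adjacent to the
#' micropattern". Candidate translations are ranked by Euclidean length,
#' ties broken by angle from east, counterclockwise.
#'
#' @param mask logical matrix: the pattern ROI to displace.
#' @param all_patterns logical matrix marking every patterned pixel.
#' @param margin clearance in pixels between the placed ROI and any pattern.
#' @param max_radius largest translation length searched, in pixels.
#' @return Logical matrix of the same dimensions: the translated ROI.
#' @export
auto_off_roi <- function(mask, all_patterns, margin = 2, max_radius = NULL) {
  stopifnot(all(dim(mask) == dim(all_patterns)))
  mask <- as.logical(mask) & TRUE
  dim(mask) <- dim(all_patterns)
  nr <- nrow(mask); nc <- ncol(mask)
  if (is.null(max_radius)) max_radius <- max(nr, nc)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  # forbidden zone: patterns dilated by margin (Chebyshev)
  forbidden <- all_patterns
  if (margin > 0) {
    k <- matrix(1, 2 * margin + 1, 2 * margin + 1)
    forbidden <- EBImage::dilate(matrix(as.numeric(all_patterns), nr, nc),
                                 k) > 0
  }
  cand <- expand.grid(dy = -max_radius:max_radius, dx = -max_radius:max_radius)
  cand <- cand[cand$dy != 0 | cand$dx != 0, ]
  r2 <- cand$dy^2 + cand$dx^2
  ang <- atan2(-cand$dy, cand$dx) %% (2 * pi)  # from east, CCW (y grows down)
  cand <- cand[order(r2, ang), ]
  for (i in seq_len(nrow(cand))) {
    ny <- idx[, 1] + cand$dy[i]
    nx <- idx[, 2] + cand$dx[i]
    if (any(ny < 1 | ny > nr | nx < 1 | nx > nc)) next
    lin <- cbind(ny, nx)
    if (any(forbidden[lin])) next
    out <- matrix(FALSE, nr, nc)
    out[lin] <- TRUE
    return(out)
  }
  stop("no clear position found for off-pattern ROI within search radius")
}
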