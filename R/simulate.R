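#' Camera noise model
#'
#' Minimal sCMOS-like model: a pixel reading is
#' `Poisson(signal * gain) + Normal(offset_mean, read_noise_sd)`,
#' i.e. shot noise on the (gain-scaled) signal plus Gaussian read noise on a
#' constant offset. This is the smallest model consistent with quantifying a
#' camera-background mean and variance from dark frames.
#'
#' @param offset_mean constant camera offset (ADU).
#' @param read_noise_sd read-noise standard deviation (ADU).
#' @param gain ADU per photon.
#' @return A `camera_model`.
#' @export
camera_model <- function(offset_mean = 100, read_noise_sd = 1.6, gain = 2) {
  stopifnot(offset_mean >= 0, read_noise_sd >= 0, gain > 0)
  structure(list(offset_mean = offset_mean, read_noise_sd = read_noise_sd,
                 gain = gain),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> offset %.4g ADU, read noise %.4g ADU, gain %.4g ADU/photon\n",
              x$offset_mean, x$read_noise_sd, x$gain))
  invisible(x)
}

#' Micropattern specification for simulation
#'
#' @param shape one of `"disk"`, `"stripe"`, `"annulus"`, `"rectangle"`.
#' @param center pattern center, `c(x, y)` in pixels (1-based).
#' @param size diameter (disk/annulus outer), width (stripe) or side
#'   (rectangle), in micrometres.
#' @param on_mean mean photon rate per pixel inside the pattern.
#' @param on_cv coefficient of variation of the spatially varying on-pattern
#'   signal (0 = perfectly uniform deposition).
#' @param off_fraction fraction of `on_mean` adsorbed outside the pattern.
#' @param inner_size inner diameter (annulus only), micrometres.
#' @param size2 second rectangle side (defaults to `size`), micrometres.
#' @return A `pattern_spec`.
#' @export
pattern_spec <- function(shape = c("disk", "stripe", "annulus", "rectangle"),
                         center, size, on_mean, on_cv = 0.05,
                         off_fraction = 0.005, inner_size = size / 2,
                         size2 = size) {
  shape <- match.arg(shape)
  if (size <= 0 || size2 <= 0) stop("pattern size must be positive")
  stopifnot(on_mean > 0, on_cv >= 0, off_fraction >= 0, off_fraction <= 1)
  if (shape == "annulus" && inner_size >= size)
    stop("annulus inner_size must be smaller than size")
  structure(list(shape = shape, center = center, size = size,
                 on_mean = on_mean, on_cv = on_cv,
                 off_fraction = off_fraction, inner_size = inner_size,
                 size2 = size2),
            class = "pattern_spec")
}

# Rasterize one pattern_spec into a logical mask (pixel-centered).
render_spec_mask <- function(spec, field_size, pixel_size) {
  nr <- field_size[1]; nc <- field_size[2]
  cx <- spec$center[1]; cy <- spec$center[2]
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr), nr, nc)
  r_px <- (spec$size / 2) / pixel_size
  switch(spec$shape,
    disk = (x - cx)^2 + (y - cy)^2 <= r_px^2,
    annulus = {
      r2 <- (x - cx)^2 + (y - cy)^2
      ri_px <- (spec$inner_size / 2) / pixel_size
      r2 <= r_px^2 & r2 > ri_px^2
    },
    stripe = abs(x - cx) <= (spec$size / 2) / pixel_size,
    rectangle = abs(x - cx) <= (spec$size / 2) / pixel_size &
      abs(y - cy) <= (spec$size2 / 2) / pixel_size)
}

# Run code with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Smooth unit-variance field restricted to masked pixels: white Gaussian
# noise low-pass filtered (Gaussian sigma in px), then standardized over the
# mask so the realized CV matches the request exactly.
smooth_unit_field <- function(nr, nc, mask, sigma = 3) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  z <- EBImage::gblur(z, sigma = sigma)
  v <- z[mask]
  if (length(v) < 2 || stats::sd(v) == 0) return(z * 0)
  z <- (z - mean(v)) / stats::sd(v)
  z
}

# Apply the camera model to a photon-rate field.
apply_camera <- function(signal, camera) {
  n <- length(signal)
  shot <- stats::rpois(n, lambda = pmax(signal, 0) * camera$gain)
  read <- stats::rnorm(n, camera$offset_mean, camera$read_noise_sd)
  out <- matrix(shot + read, nrow(signal), ncol(signal))
  out
}

#' Simulate a micropatterned fluorescence image
#'
#' Renders one or more micropatterns onto a passivated background and applies
#' the camera model. Inside a pattern the photon rate is
#' `on_mean * (1 + on_cv * z)` with `z` a smooth standardized field (so the
#' realized within-pattern CV equals `on_cv`); outside all patterns it is the
#' sum over specs of `on_mean * off_fraction` (adsorption from each protein
#' adds). The returned ground truth carries the exact masks and the
#' closed-form metric values implied by the generating parameters, computed
#' before any noise is drawn.
#'
#' @param specs a [pattern_spec()] or list of them; patterns must not
#'   overlap.
#' @param camera a [camera_model()].
#' @param field_size `c(rows, cols)` in pixels.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param pixel_size micrometres per pixel.
#' @return A list with `image` (an [image_frame()]) and `truth`, a list
#'   holding `label_mask`, per-pattern `true_selectivity` (expected
#'   background-corrected ratio, `1/off_total` where `off_total` is the
#'   summed off-pattern fraction), `true_homogeneity`
#'   (`mu_e / (mu_e + (cv * mu_e)^2)` in ADU^-1, with `mu_e = on_mean * gain`),
#'   `true_amount` (ADU) and the generating parameters.
#' @export
simulate_pattern_image <- function(specs, camera = camera_model(),
                                   field_size = c(128, 128), seed = 1,
                                   pixel_size = 0.11) {
  if (inherits(specs, "pattern_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, inherits(camera, "camera_model"))
  masks <- lapply(specs, render_spec_mask, field_size = field_size,
                  pixel_size = pixel_size)
  if (any(vapply(masks, sum, numeric(1)) == 0))
    stop("a pattern falls entirely outside the field")
  acc <- Reduce(`+`, lapply(masks, as.numeric))
  if (any(acc > 1)) stop("pattern specs overlap")
  nr <- field_size[1]; nc <- field_size[2]

  off_photons <- sum(vapply(specs, function(s) s$on_mean * s$off_fraction,
                            numeric(1)))
  g <- camera$gain
  truth <- list(
    label_mask = {
      lm <- matrix(0L, nr, nc)
      for (i in seq_along(masks)) lm[masks[[i]]] <- i
      label_mask(lm, pixel_size = pixel_size)
    },
    true_selectivity = vapply(specs, function(s)
      if (off_photons > 0) s$on_mean / off_photons else NA_real_, numeric(1)),
    true_homogeneity = vapply(specs, function(s) {
      mu_e <- s$on_mean * g
      mu_e / (mu_e + (s$on_cv * mu_e)^2)
    }, numeric(1)),
    true_amount = vapply(specs, function(s)
      (s$on_mean - off_photons) * g, numeric(1)),
    off_photon_rate = off_photons,
    specs = specs, camera = camera, pixel_size = pixel_size)

  img <- with_seed(seed, {
    signal <- matrix(off_photons, nr, nc)
    for (i in seq_along(specs)) {
      s <- specs[[i]]; m <- masks[[i]]
      if (s$on_cv > 0) {
        z <- smooth_unit_field(nr, nc, m)
        signal[m] <- pmax(s$on_mean * (1 + s$on_cv * z[m]), 0)
      } else signal[m] <- s$on_mean
    }
    apply_camera(signal, camera)
  })
  list(image = image_frame(img, pixel_size = pixel_size), truth = truth)
}

#' Simulate a sequential multiplexed micropattern series
#'
#' One image per channel: channel `c` deposits photon rate
#' `on_mean(c) * crosstalk[c, i]` on pattern `i`, with the intended entry
#' fixed at 1 and spatial variation (`on_cv`) applied on the intended
#' pattern only. Emulates sequential multiplexed micropatterning of several
#' fluorescent proteins with small cross-adsorption between steps.
#'
#' @param pattern_specs named list of [pattern_spec()]s in patterning order.
#' @param assignment named character vector channel -> pattern id; defaults
#'   to the identity over pattern names.
#' @param crosstalk channels-x-patterns matrix of fractions in `[0, 1]`;
#'   intended entries must equal 1.
#' @param camera a [camera_model()].
#' @param field_size `c(rows, cols)` pixels.
#' @param seed integer seed.
#' @param pixel_size micrometres per pixel.
#' @return List with `images` (named list of [image_frame()]s), `patterns`
#'   (a [pattern_set()]) and `truth` (including `crosstalk_matrix`, equal to
#'   the input).
#' @export
simulate_multiplex_series <- function(pattern_specs, assignment = NULL,
                                      crosstalk = NULL,
                                      camera = camera_model(),
                                      field_size = c(128, 192), seed = 1,
                                      pixel_size = 0.11) {
  stopifnot(is.list(pattern_specs), !is.null(names(pattern_specs)))
  pats <- names(pattern_specs)
  if (is.null(assignment))
    assignment <- stats::setNames(pats, paste0("ch_", pats))
  channels <- names(assignment)
  if (any(!assignment %in% pats))
    stop("assignment references a missing pattern")
  if (is.null(crosstalk)) {
    crosstalk <- matrix(0, length(channels), length(pats),
                        dimnames = list(channels, pats))
    for (ch in channels) crosstalk[ch, assignment[[ch]]] <- 1
  }
  stopifnot(all(crosstalk >= 0), all(crosstalk <= 1))
  for (ch in channels)
    if (crosstalk[ch, assignment[[ch]]] != 1)
      stop("intended crosstalk entries must equal 1")

  masks <- lapply(pattern_specs, render_spec_mask, field_size = field_size,
                  pixel_size = pixel_size)
  acc <- Reduce(`+`, lapply(masks, as.numeric))
  if (any(acc > 1)) stop("pattern specs overlap")
  nr <- field_size[1]; nc <- field_size[2]

  images <- with_seed(seed, {
    out <- list()
    for (ch in channels) {
      spec <- pattern_specs[[assignment[[ch]]]]
      signal <- matrix(0, nr, nc)
      for (p in pats) {
        rate <- spec$on_mean * crosstalk[ch, p]
        if (rate <= 0) next
        m <- masks[[p]]
        if (p == assignment[[ch]] && spec$on_cv > 0) {
          z <- smooth_unit_field(nr, nc, m)
          signal[m] <- pmax(rate * (1 + spec$on_cv * z[m]), 0)
        } else signal[m] <- rate
      }
      out[[ch]] <- image_frame(apply_camera(signal, camera),
                               pixel_size = pixel_size, channel = ch)
    }
    out
  })
  truth <- list(crosstalk_matrix = crosstalk, masks = masks,
                camera = camera, pixel_size = pixel_size)
  list(images = images,
       patterns = pattern_set(masks, assignment),
       truth = truth)
}

#' Simulate camera dark frames
#'
#' Frames recorded with no light: pure read noise around the offset.
#'
#' @param camera a [camera_model()].
#' @param n_frames number of frames (>= 2).
#' @param field_size `c(rows, cols)` pixels.
#' @param seed integer seed.
#' @return A y-by-x-by-t array of dark frames (ADU).
#' @export
simulate_dark_frames <- function(camera = camera_model(), n_frames = 100,
                                 field_size = c(64, 64), seed = 1) {
  stopifnot(inherits(camera, "camera_model"), n_frames >= 2)
  with_seed(seed, {
    array(stats::rnorm(prod(field_size) * n_frames, camera$offset_mean,
                       camera$read_noise_sd),
          dim = c(field_size, n_frames))
  })
}

#' Simulate a field of cells adhering to micropatterns
#'
#' Cell counts per region are Poisson with mean `density * area`; centroids
#' are placed uniformly within their region, rejecting positions that would
#' overlap an already-placed cell where possible. Cells are rendered as
#' uniform disks on top of the camera background.
#'
#' @param patterns a [label_mask()] of (diameter-filtered) micropatterns.
#' @param density_on on-pattern cell density, cells per square micrometre.
#' @param density_off off-pattern density, cells per square micrometre.
#' @param cell_radius cell radius in micrometres.
#' @param camera a [camera_model()].
#' @param cell_photons photon rate per pixel inside a rendered cell.
#' @param seed integer seed.
#' @return List with `image`, `centroids` (data.frame `x`, `y`, `on_pattern`,
#'   `label`) and `truth` (areas in um^2, realized and expected counts, the
#'   generating densities, and the implied nonspecific-adhesion percentage
#'   `100 * d_off / (d_on + d_off)`).
#' @export
simulate_adhesion_field <- function(patterns, density_on, density_off,
                                    cell_radius = 5,
                                    camera = camera_model(),
                                    cell_photons = 150, seed = 1) {
  stopifnot(inherits(patterns, "label_mask"), density_on >= 0,
            density_off >= 0, cell_radius > 0)
  ps <- pixel_size(patterns)
  nr <- nrow(patterns); nc <- ncol(patterns)
  on_mask <- patterns > 0
  area_on <- sum(on_mask) * ps^2
  area_off <- sum(!on_mask) * ps^2
  r_px <- cell_radius / ps

  with_seed(seed, {
    n_on <- stats::rpois(1, density_on * area_on)
    n_off <- stats::rpois(1, density_off * area_off)
    for (nm in c("on", "off")) {
      n <- if (nm == "on") n_on else n_off
      area <- if (nm == "on") area_on else area_off
      if (n * pi * cell_radius^2 > 0.7 * area)
        stop("requested ", nm, "-pattern density exceeds close packing")
    }
    place <- function(n, region_mask) {
      idx <- which(region_mask)
      if (n > 0 && length(idx) == 0)
        stop("no room to place cells: empty region")
      pts <- matrix(numeric(0), 0, 2)
      tries <- 0
      while (nrow(pts) < n && tries < 200 * n + 200) {
        tries <- tries + 1
        k <- idx[sample.int(length(idx), 1)]
        y <- (k - 1) %% nr + 1
        x <- (k - 1) %/% nr + 1
        if (nrow(pts) == 0 ||
            all((pts[, 1] - x)^2 + (pts[, 2] - y)^2 >= (2 * r_px)^2))
          pts <- rbind(pts, c(x, y))
      }
      if (nrow(pts) < n)
        stop("could not place requested cells without overlap")
      pts
    }
    pts_on <- place(n_on, on_mask)
    pts_off <- place(n_off, !on_mask)
    centroids <- data.frame(
      x = c(pts_on[, 1], pts_off[, 1]),
      y = c(pts_on[, 2], pts_off[, 2]),
      on_pattern = rep(c(TRUE, FALSE), c(n_on, n_off)))
    centroids$label <- ifelse(centroids$on_pattern,
                              patterns[cbind(centroids$y, centroids$x)], 0L)

    signal <- matrix(0, nr, nc)
    if (nrow(centroids) > 0) {
      xg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      yg <- matrix(seq_len(nr), nr, nc)
      for (i in seq_len(nrow(centroids))) {
        hit <- (xg - centroids$x[i])^2 + (yg - centroids$y[i])^2 <= r_px^2
        signal[hit] <- cell_photons
      }
    }
    img <- image_frame(apply_camera(signal, camera), pixel_size = ps)
    d_on <- density_on; d_off <- density_off
    truth <- list(area_on = area_on, area_off = area_off,
                  n_on = n_on, n_off = n_off,
                  expected_n_on = density_on * area_on,
                  expected_n_off = density_off * area_off,
                  density_on = d_on, density_off = d_off,
                  expected_nonspecific_pct =
                    if (d_on + d_off > 0) 100 * d_off / (d_on + d_off)
                    else NA_real_)
    list(image = img, centroids = centroids, truth = truth)
  })
}
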