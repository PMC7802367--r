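#' Scripted filament for gliding-assay simulation
#'
#' Ground-truth description of one microtubule-like filament gliding along a
#' path: it advances at `speed` during "moving" frames and is stationary
#' during "paused" frames, with pause placement drawn to match `duty_ratio`.
#' Filaments scripted off-pattern never move (no motor underneath).
#'
#' @param path polyline, an n-by-2 matrix of `(x, y)` pixel coordinates.
#' @param speed gliding speed in micrometres per second.
#' @param duty_ratio fraction of inter-frame intervals in the moving state.
#' @param on_pattern logical; off-pattern filaments are forced immobile.
#' @param length_um filament length in micrometres.
#' @param photons peak photon rate per pixel along the filament ridge.
#' @param sigma_px Gaussian cross-profile sigma in pixels.
#' @return A `filament_script`.
#' @export
filament_script <- function(path, speed, duty_ratio, on_pattern = TRUE,
                            length_um = 5, photons = 300, sigma_px = 1.3) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, nrow(path) >= 2, speed >= 0,
            duty_ratio >= 0, duty_ratio <= 1, length_um > 0)
  structure(list(path = path, speed = speed, duty_ratio = duty_ratio,
                 on_pattern = isTRUE(on_pattern), length_um = length_um,
                 photons = photons, sigma_px = sigma_px),
            class = "filament_script")
}

# Arc-length parametrization of a polyline: point at arclength s (px).
path_point <- function(path, s) {
  seg <- diff(path)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(len))
  f <- (s - cum[i]) / len[i]
  cbind(path[i, 1] + f * seg[i, 1], path[i, 2] + f * seg[i, 2])
}

path_length_px <- function(path) sum(sqrt(rowSums(diff(path)^2)))

# Draw the per-interval moving/paused state sequence for one filament.
# Exactly round((1 - duty) * n) intervals are paused, grouped into pause
# blocks of 2-5 frames placed at random gaps between runs, so the realized
# moving fraction matches the request to rounding while pauses stay long
# enough to be distinguishable from frame-to-frame jitter.
draw_states <- function(n_intervals, duty) {
  if (duty >= 1) return(rep(TRUE, n_intervals))
  if (duty <= 0) return(rep(FALSE, n_intervals))
  n_paused <- round((1 - duty) * n_intervals)
  if (n_paused == 0) return(rep(TRUE, n_intervals))
  blocks <- integer(0)
  left <- n_paused
  while (left > 0) {
    len <- min(left, sample(2:5, 1))
    if (left - len == 1) len <- len + 1  # avoid a trailing 1-frame pause
    blocks <- c(blocks, min(len, left))
    left <- left - min(len, left)
  }
  n_move <- n_intervals - n_paused
  k <- length(blocks)
  gaps <- sort(sample.int(n_move + 1, min(k, n_move + 1)))
  states <- logical(0)
  b <- 1
  for (g in seq_len(n_move + 1)) {
    if (b <= k && g %in% gaps) {
      states <- c(states, rep(FALSE, blocks[b]))
      b <- b + 1
    }
    if (g <= n_move) states <- c(states, TRUE)
  }
  while (b <= k) {  # leftover blocks when pauses outnumber gaps
    states <- c(states, rep(FALSE, blocks[b]))
    b <- b + 1
  }
  states[seq_len(n_intervals)]
}

# Splat a Gaussian-profile line segment onto `signal` (photon rates).
# The ridge is sampled at sub-pixel spacing and each sample contributes an
# analytically evaluated isotropic Gaussian, so sub-pixel positions are
# rendered exactly rather than stamped to the nearest pixel.
render_filament <- function(signal, path, s_center, half_len, photons,
                            sigma) {
  spacing <- 0.25
  ss <- seq(s_center - half_len, s_center + half_len, by = spacing)
  pts <- path_point(path, ss)
  nr <- nrow(signal); nc <- ncol(signal)
  w <- photons * spacing / (sqrt(2 * pi) * sigma)
  r <- ceiling(4 * sigma)
  for (k in seq_len(nrow(pts))) {
    x0 <- pts[k, 1]; y0 <- pts[k, 2]
    xs <- max(1, floor(x0 - r)):min(nc, ceiling(x0 + r))
    ys <- max(1, floor(y0 - r)):min(nr, ceiling(y0 + r))
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - x0)^2 / (2 * sigma^2))
    gy <- exp(-(ys - y0)^2 / (2 * sigma^2))
    signal[ys, xs] <- signal[ys, xs] + w * outer(gy, gx)
  }
  signal
}

#' Simulate a gliding-assay movie
#'
#' Renders scripted filaments as Gaussian-profile line segments advancing
#' along their paths, then applies the camera model per frame. The ground
#' truth records, per filament, the realized per-interval moving states, the
#' realized duty fraction, the centerline position along the path at every
#' frame, and the net displacement.
#'
#' @param scripts list of [filament_script()]s.
#' @param field_size `c(rows, cols)` pixels.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds per frame (> 0).
#' @param camera a [camera_model()].
#' @param pattern_mask optional logical/label matrix of the motor-coated
#'   micropattern, stored for downstream on/off-pattern grouping.
#' @param seed integer seed.
#' @param pixel_size micrometres per pixel.
#' @return List with `movie` (a [time_lapse()]) and `truth` (per-filament
#'   records plus the pattern mask).
#' @export
simulate_gliding_movie <- function(scripts, field_size, n_frames = 200,
                                   frame_interval = 0.2,
                                   camera = camera_model(),
                                   pattern_mask = NULL, seed = 1,
                                   pixel_size = 0.11) {
  if (inherits(scripts, "filament_script")) scripts <- list(scripts)
  stopifnot(n_frames >= 2, length(scripts) >= 1)
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  nr <- field_size[1]; nc <- field_size[2]
  for (sc in scripts) {
    if (sc$length_um / pixel_size >= max(nr, nc))
      stop("filament longer than the field")
  }
  with_seed(seed, {
    records <- list()
    movie <- array(0, dim = c(nr, nc, n_frames))
    for (j in seq_along(scripts)) {
      sc <- scripts[[j]]
      duty <- if (sc$on_pattern) sc$duty_ratio else 0
      states <- draw_states(n_frames - 1, duty)
      half_len <- (sc$length_um / 2) / pixel_size
      step_px <- sc$speed * frame_interval / pixel_size
      pos <- (half_len + 1) +  # tail starts at the path origin
        c(0, cumsum(states)) * step_px
      if (max(pos) + half_len > path_length_px(sc$path))
        stop("filament ", j, " runs off the end of its path; extend the path")
      for (t in seq_len(n_frames))
        movie[, , t] <- render_filament(movie[, , t], sc$path, pos[t],
                                        half_len, sc$photons, sc$sigma_px)
      records[[j]] <- list(
        on_pattern = sc$on_pattern,
        speed = sc$speed,
        requested_duty = duty,
        moving = states,
        realized_duty = mean(states),
        position_um = pos * pixel_size,
        net_displacement_um = (pos[n_frames] - pos[1]) * pixel_size)
    }
    for (t in seq_len(n_frames))
      movie[, , t] <- apply_camera(movie[, , t], camera)
    list(movie = time_lapse(movie, pixel_size = pixel_size,
                            frame_interval = frame_interval),
         truth = list(filaments = records, pattern_mask = pattern_mask))
  })
}

#' Time projection of a movie
#'
#' Per-pixel maximum (default) or mean over all frames; the maximum
#' projection traces the paths of moving filaments and is the standard
#' starting point for drawing kymograph paths.
#'
#' @param movie a [time_lapse()] (or 3D array).
#' @param method `"max"` or `"mean"`.
#' @return An [image_frame()].
#' @export
time_project <- function(movie, method = c("max", "mean")) {
  method <- match.arg(method)
  if (!is.array(movie) || length(dim(movie)) != 3 || dim(movie)[3] < 1)
    stop("movie must be a y-x-t array with at least one frame")
  ps <- attr(movie, "pixel_size")
  out <- apply(movie, c(1, 2), if (method == "max") max else mean)
  image_frame(out, pixel_size = if (is.null(ps)) 0.11 else ps)
}

bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x < 1 | x > nc | y < 1 | y > nr))
    stop("sample point outside image bounds")
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Build a kymograph along a path
#'
#' For every frame, intensity is sampled by bilinear interpolation at 1 px
#' steps along the path, averaged over `width` samples placed symmetrically
#' along the local normal, and stacked into a distance-by-time image.
#'
#' @param movie a [time_lapse()].
#' @param path polyline, n-by-2 matrix of `(x, y)` pixel coordinates.
#' @param width odd number of perpendicular samples averaged per point.
#' @return A `kymograph`: distance-by-time matrix with `pixel_size`,
#'   `frame_interval` and `path` attributes.
#' @export
build_kymograph <- function(movie, path, width = 3) {
  stopifnot(inherits(movie, "time_lapse"))
  path <- as.matrix(path)
  if (width %% 2 != 1) stop("width must be odd")
  total <- path_length_px(path)
  if (total <= 0) stop("degenerate (zero-length) path")
  ss <- seq(0, total, by = 1)
  pts <- path_point(path, ss)
  tang <- path_point(path, pmin(ss + 0.5, total)) -
    path_point(path, pmax(ss - 0.5, 0))
  tn <- sqrt(rowSums(tang^2)); tang <- tang / tn
  normal <- cbind(-tang[, 2], tang[, 1])
  offs <- seq(-(width - 1) / 2, (width - 1) / 2)
  nt <- dim(movie)[3]
  kymo <- matrix(0, length(ss), nt)
  for (t in seq_len(nt)) {
    frame <- movie[, , t]
    acc <- 0
    for (o in offs)
      acc <- acc + bilinear_sample(frame, pts[, 1] + o * normal[, 1],
                                   pts[, 2] + o * normal[, 2])
    kymo[, t] <- acc / width
  }
  structure(kymo, pixel_size = pixel_size(movie),
            frame_interval = attr(movie, "frame_interval"), path = path,
            class = c("kymograph", "matrix", "array"))
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d px x %d frames, %.3g um/px, %.3g s/frame\n",
              nrow(x), ncol(x), attr(x, "pixel_size"),
              attr(x, "frame_interval")))
  invisible(x)
}

#' Extract a motility trace from a kymograph
#'
#' Per-frame position is the intensity-weighted centroid along the distance
#' axis after per-frame background subtraction (column median) and
#' suppression of weak pixels. Frames whose instantaneous speed stays below
#' `pause_threshold_frac` times the median moving speed for at least
#' `min_pause_frames` consecutive intervals are labeled paused; mean speed
#' is computed over moving intervals only (interior ones, since transition
#' intervals mix both states) and the duty fraction is
#' moving intervals / total intervals (so duty + paused fraction = 1).
#'
#' @param kymo a [build_kymograph()] result.
#' @param pause_threshold_frac pause threshold as a fraction of the median
#'   moving speed.
#' @param min_pause_frames minimum consecutive sub-threshold intervals that
#'   count as a pause.
#' @param min_snr minimum peak/noise ratio to accept localization.
#' @param stationary_tol_um traces whose total positional range stays below
#'   this are classified stationary (duty 0, speed undefined).
#' @return A `motility_trace` with per-frame `position_um`, the per-interval
#'   `moving` states, `duty`, `mean_speed_um_s`, `net_displacement_um` and
#'   flags; or a rejected trace (`rejected = TRUE` with a `reason`) when the
#'   signal is too weak to localize.
#' @export
trace_filament <- function(kymo, pause_threshold_frac = 0.2,
                           min_pause_frames = 2, min_snr = 5,
                           stationary_tol_um = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  ps <- attr(kymo, "pixel_size")
  dt <- attr(kymo, "frame_interval")
  if (is.null(stationary_tol_um)) stationary_tol_um <- 3 * ps
  nt <- ncol(kymo)
  d_um <- (seq_len(nrow(kymo)) - 1) * ps
  pos <- rep(NA_real_, nt)
  snr <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    col <- kymo[, t]
    # lower-quartile background and below-background noise keep both
    # robust even when the filament covers much of the path
    bg <- stats::quantile(col, 0.25, names = FALSE)
    w <- col - bg
    # one-sided robust sigma: for Gaussian noise the median of the
    # below-quartile tail sits 0.476 sigma under the quartile
    low <- col[col <= bg]
    noise <- (bg - stats::median(low)) / 0.4758
    peak <- max(w)
    snr[t] <- if (noise > 0) peak / noise else Inf
    w[w < 0.3 * peak] <- 0
    if (sum(w) <= 0) next
    pos[t] <- sum(d_um * w) / sum(w)
  }
  if (anyNA(pos) || stats::median(snr) < min_snr)
    return(structure(list(rejected = TRUE,
                          reason = "signal too weak to localize filament"),
                     class = "motility_trace"))
  sm <- if (nt >= 3) stats::runmed(pos, 3) else pos
  v <- diff(sm) / dt
  v_mag <- abs(v)
  if (diff(range(sm)) < stationary_tol_um) {
    moving <- rep(FALSE, nt - 1)
    out <- list(rejected = FALSE, position_um = pos, moving = moving,
                duty = 0, mean_speed_um_s = NA_real_,
                net_displacement_um = abs(sm[nt] - sm[1]),
                stationary = TRUE, frame_interval = dt)
    return(structure(out, class = "motility_trace"))
  }
  med_top <- stats::median(v_mag[v_mag >= stats::median(v_mag)])
  thr <- pause_threshold_frac * med_top
  moving <- v_mag >= thr
  # remove isolated misclassifications (jitter spikes inside a pause and
  # single dips inside a run) before applying the pause-length rule
  if (length(moving) >= 3)
    moving <- as.logical(stats::runmed(as.numeric(moving), 3))
  # sub-threshold dips shorter than min_pause_frames are not pauses
  r <- rle(moving)
  r$values[!r$values & r$lengths < min_pause_frames] <- TRUE
  moving <- inverse.rle(r)
  duty <- mean(moving)
  # mean speed over interior moving intervals: run/pause transition
  # intervals mix both states and would dilute the estimate
  nv <- length(moving)
  core <- if (nv >= 3)
    moving & c(TRUE, moving[-nv]) & c(moving[-1], TRUE) else moving
  if (!any(core)) core <- moving
  mean_speed <- if (any(moving)) mean(v_mag[core]) else NA_real_
  structure(list(rejected = FALSE, position_um = pos, moving = moving,
                 duty = duty, mean_speed_um_s = mean_speed,
                 net_displacement_um = abs(sm[nt] - sm[1]),
                 stationary = FALSE, frame_interval = dt),
            class = "motility_trace")
}

#' @export
print.motility_trace <- function(x, ...) {
  if (isTRUE(x$rejected)) {
    cat(sprintf("<motility_trace> rejected: %s\n", x$reason))
  } else {
    cat(sprintf(
      "<motility_trace> %d frames, duty %.2f, speed %s um/s, net %.2f um\n",
      length(x$position_um), x$duty,
      if (is.na(x$mean_speed_um_s)) "NA"
      else sprintf("%.3f", x$mean_speed_um_s),
      x$net_displacement_um))
  }
  invisible(x)
}

#' Motile fractions on and off the motor pattern
#'
#' A trace is motile iff its net displacement reaches
#' `min_net_displacement`. Traces are grouped by their `on_pattern` tag
#' (set it from the script, or from the majority of the path's pixels over
#' the pattern mask via [tag_on_pattern()]). Empty groups report `NA`
#' (undefined), not 0.
#'
#' @param traces list of accepted `motility_trace`s, each with an
#'   `on_pattern` element.
#' @param min_net_displacement micrometres.
#' @return `data.frame` with `group`, `n`, `n_motile`, `fraction_motile`.
#' @export
classify_motile <- function(traces, min_net_displacement = 1) {
  stopifnot(is.list(traces))
  traces <- Filter(function(tr) !isTRUE(tr$rejected), traces)
  onp <- vapply(traces, function(tr) {
    if (is.null(tr$on_pattern)) stop("trace lacks an on_pattern tag")
    isTRUE(tr$on_pattern)
  }, logical(1))
  motile <- vapply(traces, function(tr)
    tr$net_displacement_um >= min_net_displacement, logical(1))
  res <- lapply(c(on_pattern = TRUE, off_pattern = FALSE), function(g) {
    sel <- onp == g
    n <- sum(sel)
    data.frame(n = n, n_motile = sum(motile[sel]),
               fraction_motile = if (n > 0) sum(motile[sel]) / n
               else NA_real_)
  })
  out <- do.call(rbind, res)
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Tag a trace on/off pattern by its path pixels
#'
#' A trace is on-pattern iff the majority of its (rounded) path pixels fall
#' on a labeled pixel of the mask.
#'
#' @param trace a `motility_trace`.
#' @param path the n-by-2 path polyline the kymograph was built along.
#' @param mask a [label_mask()] or logical matrix.
#' @return The trace with `on_pattern` set.
#' @export
tag_on_pattern <- function(trace, path, mask) {
  pts <- path_point(path, seq(0, path_length_px(path), by = 1))
  xi <- pmin(pmax(round(pts[, 1]), 1), ncol(mask))
  yi <- pmin(pmax(round(pts[, 2]), 1), nrow(mask))
  trace$on_pattern <- mean(mask[cbind(yi, xi)] > 0) > 0.5
  trace
}

#' Mean +/- SEM summary of accepted traces
#'
#' @param traces list of accepted `motility_trace`s.
#' @return `data.frame` with one row per statistic (`speed_um_s`, `duty`)
#'   giving `mean`, `sem` and `n`, the standard reporting convention.
#' @export
motility_summary <- function(traces) {
  traces <- Filter(function(tr) !isTRUE(tr$rejected), traces)
  speed <- vapply(traces, function(tr) tr$mean_speed_um_s, numeric(1))
  duty <- vapply(traces, function(tr) tr$duty, numeric(1))
  row <- function(name, v) {
    v <- v[!is.na(v)]
    data.frame(statistic = name, mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  }
  rbind(row("speed_um_s", speed), row("duty", duty))
}
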