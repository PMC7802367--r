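# Naive-loop oracles, written independently of the package internals:
# explicit pixel loops and literal transcriptions of the defining formulas.

oracle_roi <- function(img, mask) {
  s <- 0; n <- 0
  for (j in seq_len(ncol(img))) for (i in seq_len(nrow(img))) {
    if (mask[i, j]) { s <- s + img[i, j]; n <- n + 1 }
  }
  m <- s / n
  ss <- 0
  for (j in seq_len(ncol(img))) for (i in seq_len(nrow(img))) {
    if (mask[i, j]) ss <- ss + (img[i, j] - m)^2
  }
  list(mean = m, variance = if (n > 1) ss / (n - 1) else 0, n = n)
}

oracle_selectivity <- function(p_mean, np_mean, cam_mean)
  (p_mean - cam_mean) / (np_mean - cam_mean)

oracle_homogeneity <- function(p_mean, p_var, cam_mean, cam_var)
  (p_mean - cam_mean) / (p_var - cam_var)

oracle_amount <- function(p_mean, np_mean) p_mean - np_mean

oracle_crosstalk_entry <- function(wrong_mean, intended_mean, bg)
  (wrong_mean - bg) / (intended_mean - bg)

oracle_nonspecific <- function(off_mean, intended_mean, bg)
  (off_mean - bg) / (intended_mean - bg)

oracle_enrich_simple <- function(inner, outer, bg)
  (inner - bg) / (outer - bg)

oracle_enrich_corrected <- function(inner, inner_cf, outer, outer_cf)
  (inner - inner_cf) / (outer - outer_cf)

oracle_enrich_temporal <- function(in_t, in_0, out_t, out_0)
  (in_t - in_0) / (out_t - out_0)

oracle_signal_increase <- function(in_t, in_0, out_t, out_0)
  (in_t - in_0) - (out_t - out_0)

oracle_norm_density <- function(n_on, area_on, ref) (n_on / area_on) / ref

oracle_nonspecific_adhesion <- function(n_on, a_on, n_off, a_off) {
  d_on <- n_on / a_on; d_off <- n_off / a_off
  (1 - d_on / (d_on + d_off)) * 100
}

oracle_time_project <- function(movie, method = "max") {
  d <- dim(movie)
  out <- matrix(0, d[1], d[2])
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    v <- movie[i, j, ]
    out[i, j] <- if (method == "max") max(v) else mean(v)
  }
  out
}

# per-frame, per-distance-sample bilinear sampling with its own interpolator
oracle_kymograph <- function(movie, path, width) {
  seg <- diff(path)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  point_at <- function(s) {
    s <- min(max(s, 0), total)
    i <- max(which(cum <= s + 1e-12)); i <- min(i, length(len))
    f <- (s - cum[i]) / len[i]
    c(path[i, 1] + f * seg[i, 1], path[i, 2] + f * seg[i, 2])
  }
  bil <- function(frame, x, y) {
    x0 <- min(floor(x), ncol(frame) - 1); y0 <- min(floor(y), nrow(frame) - 1)
    fx <- x - x0; fy <- y - y0
    frame[y0, x0] * (1 - fx) * (1 - fy) + frame[y0, x0 + 1] * fx * (1 - fy) +
      frame[y0 + 1, x0] * (1 - fx) * fy + frame[y0 + 1, x0 + 1] * fx * fy
  }
  ss <- seq(0, total, by = 1)
  nt <- dim(movie)[3]
  out <- matrix(0, length(ss), nt)
  for (t in seq_len(nt)) {
    for (k in seq_along(ss)) {
      p <- point_at(ss[k])
      a <- point_at(min(ss[k] + 0.5, total))
      b <- point_at(max(ss[k] - 0.5, 0))
      tv <- (a - b) / sqrt(sum((a - b)^2))
      nv <- c(-tv[2], tv[1])
      acc <- 0
      for (o in seq(-(width - 1) / 2, (width - 1) / 2))
        acc <- acc + bil(movie[, , t], p[1] + o * nv[1], p[2] + o * nv[2])
      out[k, t] <- acc / width
    }
  }
  out
}

# fixture builders -----------------------------------------------------------

disk_mask <- function(nr, nc, cx, cy, r_px) {
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr), nr, nc)
  (x - cx)^2 + (y - cy)^2 <= r_px^2
}

random_roi <- function() {
  roi_stats(mean = runif(1, 50, 5000), variance = runif(1, 0, 400),
            n_pixels = sample(2:4096, 1))
}

# a horizontal gliding setup long enough for the scripted travel
gliding_setup <- function(speed, duty, n_frames, frame_interval = 0.2,
                          pixel_size = 0.11, length_um = 4) {
  travel_px <- speed * duty * n_frames * frame_interval / pixel_size
  len_px <- length_um / pixel_size
  nc <- ceiling(travel_px + 2 * len_px + 80)
  path <- cbind(c(3, nc - 3), c(12, 12))
  list(path = path, field = c(24, nc))
}
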