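# TIFF intensities are stored scaled by 1/65535 (the tiff package writes
# values in [0,1]); 32-bit float pages keep ADU fidelity to ~1e-4 ADU.
.tiff_scale <- 65535

#' Read a (multi-page) TIFF as an image or movie
#'
#' @param path TIFF file.
#' @param pixel_size micrometres per pixel (TIFFs written by this package do
#'   not embed it).
#' @param frame_interval seconds per frame, used when the file has several
#'   pages.
#' @return An [image_frame()] (single page) or [time_lapse()] (t-stack),
#'   in ADU.
#' @export
read_image_tiff <- function(path, pixel_size = 0.11, frame_interval = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # drop extra samples
    p * .tiff_scale
  })
  if (length(pages) == 1)
    return(image_frame(pages[[1]], pixel_size = pixel_size))
  time_lapse(array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))),
             pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Write an image or movie to TIFF
#'
#' Intensities are stored as 32-bit float pages scaled to [0, 1] by 1/65535;
#' [read_image_tiff()] undoes the scaling.
#'
#' @param x an [image_frame()], [time_lapse()], matrix or 3D array (ADU).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path) {
  if (is.matrix(x)) {
    pages <- list(unclass(x) / .tiff_scale)
  } else if (is.array(x) && length(dim(x)) == 3) {
    pages <- lapply(seq_len(dim(x)[3]), function(t) x[, , t] / .tiff_scale)
  } else stop("x must be a matrix or y-x-t array")
  pages <- lapply(pages, function(p) {
    attributes(p) <- list(dim = dim(p))
    pmin(pmax(p, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(path)
}

#' Read / write a 16-bit label-mask TIFF
#'
#' @param path TIFF file.
#' @param pixel_size micrometres per pixel.
#' @return [label_mask()] for the reader; `path` invisibly for the writer.
#' @export
read_label_tiff <- function(path, pixel_size = 0.11) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  label_mask(matrix(as.integer(round(m * .tiff_scale)), nrow(m), ncol(m)),
             pixel_size = pixel_size)
}

#' @rdname read_label_tiff
#' @param mask a [label_mask()] (labels must be < 65536).
#' @export
write_label_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask) >= .tiff_scale) stop("too many labels for 16-bit storage")
  m <- unclass(mask) / .tiff_scale
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a ground-truth sidecar as JSON
#'
#' Serializes the scalar/vector components of a simulation ground truth
#' (masks are written separately as label TIFFs).
#'
#' @param truth a ground-truth list from a `simulate_*` function.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  keep <- Filter(function(x) !is.matrix(x) && !inherits(x, "label_mask"),
                 truth)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' A flat key-value file declaring at least `pixel_size` (um/px) and
#' `assignment` (channel -> intended pattern id).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$assignment)) cfg$assignment <- unlist(cfg$assignment)
  cfg
}

#' Write a per-pattern metrics table or crosstalk matrix as CSV
#'
#' @param x `data.frame` (metrics table) or matrix (crosstalk).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  if (is.matrix(x)) {
    utils::write.csv(as.data.frame(x), path, row.names = TRUE)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}
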