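#' Receptor enrichment on an inner ligand pattern (simple background)
#'
#' Fold enrichment of a receptor over the ligand-bearing inner pattern
#' relative to the surrounding adhesive ring, both corrected by the
#' off-pattern background:
#' \deqn{E = \frac{\bar I_{inner} - \bar I_{bg}}{\bar I_{outer} - \bar I_{bg}}}
#' E = 1 means no relocalization. Scale-invariant: multiplying all
#' intensities by a > 0 leaves it unchanged.
#'
#' @param inner [roi_stats()] (or scalar mean) of the inner, ligand-bearing
#'   pattern ROI.
#' @param outer [roi_stats()] of the surrounding adhesive ring ROI.
#' @param nonpattern_bg [roi_stats()] of an unpatterned background region.
#' @return Unitless fold, or [unmeasurable()] when the denominator is <= 0.
#' @export
enrichment_simple <- function(inner, outer, nonpattern_bg) {
  inner <- as_roi(inner, "inner"); outer <- as_roi(outer, "outer")
  nonpattern_bg <- as_roi(nonpattern_bg, "nonpattern_bg")
  den <- outer$mean - nonpattern_bg$mean
  if (den <= 0)
    return(unmeasurable("outer signal at or below non-pattern background"))
  (inner$mean - nonpattern_bg$mean) / den
}

#' Enrichment with cell-free bleed-through correction
#'
#' For receptors imaged in a channel into which the patterned ligand may
#' bleed, each ROI is corrected by its counterpart on a neighbouring pattern
#' with no adhered cell:
#' \deqn{E = \frac{\bar I_{inner} - \bar I_{inner,\,cell\mbox{-}free}}
#'               {\bar I_{outer} - \bar I_{outer,\,cell\mbox{-}free}}}
#' ROI pairing (which cell-free pattern corrects which cell) is explicit
#' user input.
#'
#' @param inner,outer [roi_stats()] on the pattern carrying the cell.
#' @param inner_cellfree,outer_cellfree [roi_stats()] on a matched cell-free
#'   pattern.
#' @return Unitless fold, or [unmeasurable()] when the denominator is <= 0.
#' @export
enrichment_bleedthrough_corrected <- function(inner, inner_cellfree,
                                              outer, outer_cellfree) {
  inner <- as_roi(inner, "inner"); outer <- as_roi(outer, "outer")
  inner_cellfree <- as_roi(inner_cellfree, "inner_cellfree")
  outer_cellfree <- as_roi(outer_cellfree, "outer_cellfree")
  den <- outer$mean - outer_cellfree$mean
  if (den <= 0)
    return(unmeasurable("outer signal at or below cell-free counterpart"))
  (inner$mean - inner_cellfree$mean) / den
}

#' Temporal fold enrichment against a pre-landing baseline
#'
#' Fold enrichment of receptor recruitment a fixed time after a cell lands
#' on the pattern, using the same ROIs before landing as the bleed-through
#' baseline:
#' \deqn{E = \frac{\bar I_{inner}(t) - \bar I_{inner}(t_0)}
#'               {\bar I_{outer}(t) - \bar I_{outer}(t_0)}}
#' Note a uniform additive drift affecting all ROIs equally does not cancel
#' here (it cancels in [signal_increase()]).
#'
#' @param inner_t,outer_t [roi_stats()] at the measurement timepoint.
#' @param inner_t0,outer_t0 [roi_stats()] of the same ROIs before landing.
#' @return Unitless fold, or [unmeasurable()] when the denominator is <= 0.
#' @export
enrichment_temporal <- function(inner_t, inner_t0, outer_t, outer_t0) {
  inner_t <- as_roi(inner_t, "inner_t"); inner_t0 <- as_roi(inner_t0, "inner_t0")
  outer_t <- as_roi(outer_t, "outer_t"); outer_t0 <- as_roi(outer_t0, "outer_t0")
  den <- outer_t$mean - outer_t0$mean
  if (den <= 0)
    return(unmeasurable("no outer signal change since baseline"))
  (inner_t$mean - inner_t0$mean) / den
}

#' Raw signal increase over the inner pattern
#'
#' Difference-of-differences recruitment index, preferred over the fold
#' change at low signal because it is less volatile:
#' \deqn{\Delta = (\bar I_{inner}(t) - \bar I_{inner}(t_0)) -
#'               (\bar I_{outer}(t) - \bar I_{outer}(t_0))}
#' Invariant under any per-frame global additive offset.
#'
#' @inheritParams enrichment_temporal
#' @return Intensity increase in ADU.
#' @export
signal_increase <- function(inner_t, inner_t0, outer_t, outer_t0) {
  inner_t <- as_roi(inner_t, "inner_t"); inner_t0 <- as_roi(inner_t0, "inner_t0")
  outer_t <- as_roi(outer_t, "outer_t"); outer_t0 <- as_roi(outer_t0, "outer_t0")
  (inner_t$mean - inner_t0$mean) - (outer_t$mean - outer_t0$mean)
}

#' Recruitment time course from a live movie
#'
#' Applies [signal_increase()] per frame against the baseline frame `t0`
#' (the last frame before the cell contacts the inner pattern, chosen by the
#' user).
#'
#' @param movie a [time_lapse()].
#' @param inner_mask,outer_mask logical masks of the inner and outer ROIs.
#' @param t0 baseline frame index (1-based).
#' @return `data.frame` with `frame`, `time_min` (relative to `t0`) and
#'   `signal_increase` (ADU); the `t0` row is 0 by construction.
#' @export
enrichment_timecourse <- function(movie, inner_mask, outer_mask, t0 = 1) {
  stopifnot(inherits(movie, "time_lapse"))
  nt <- dim(movie)[3]
  if (t0 < 1 || t0 > nt) stop("t0 out of range")
  if (any(inner_mask & outer_mask)) stop("inner and outer ROIs must be disjoint")
  dt_min <- attr(movie, "frame_interval") / 60
  inner_means <- vapply(seq_len(nt),
                        function(t) mean(movie[, , t][inner_mask]), numeric(1))
  outer_means <- vapply(seq_len(nt),
                        function(t) mean(movie[, , t][outer_mask]), numeric(1))
  data.frame(
    frame = seq_len(nt),
    time_min = (seq_len(nt) - t0) * dt_min,
    signal_increase = (inner_means - inner_means[t0]) -
      (outer_means - outer_means[t0]))
}
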