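---
title: "Models and methods behind mpquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpquant)
```

`mpquant` quantifies protein micropatterns and the assays built on them.
This vignette records the models the package assumes, the tunable
parameters and their defaults, the numerical choices made where the
definitions are silent, and the limits of what the synthetic-data
validation can show.

## ROI statistics and the background model

Every intensity metric is a function of three-number ROI summaries
(`roi_stats`: mean, unbiased sample variance, pixel count) and a camera
background (`camera_background`: scalar mean and variance pooled from a
dark-frame stack). Two conventions are fixed here:

- **Variance** uses the $n-1$ denominator. A one-pixel ROI is assigned
  variance 0 and flagged `degenerate` rather than `NA`, so that
  single-pixel probes still flow through pipelines that only use means.
- **Camera background** is reduced to one scalar pair: the per-pixel mean
  and per-pixel temporal variance are computed across the dark stack and
  then averaged over pixels. This matches how the background enters the
  metric formulas (as scalars), and deliberately ignores pixel-to-pixel
  fixed-pattern structure — see Limitations.

The same pair also stands in for the coverslip background of a passivated,
never-exposed surface, which is empirically indistinguishable from the
camera floor for the substrates this pipeline targets.

### Unmeasurable results

Each ratio metric has a denominator that can sit at or below the camera
floor (e.g. off-pattern mean ≤ camera mean). Such results are returned as
a typed `unmeasurable` value carrying a reason string — never clipped,
never `Inf` — so that downstream aggregation has to handle exclusion
explicitly. `is_unmeasurable()` tests for it.

### Homogeneity denominator

Homogeneity is implemented exactly as conventionally defined,
with the background-corrected **variance** in the denominator (units
ADU⁻¹), although a standard-deviation denominator would give a unitless
inverse coefficient of variation. Because the variance reading is
sometimes suspected to be a typographic loss of a square root, the SD
variant is exported as `homogeneity_sd()` under its own name; it is never
substituted silently.

### Off-pattern ROI auto-placement

The off-pattern ROI is defined as "identical size, adjacent". When the
user does not supply one, `auto_off_roi()` translates the pattern mask to
the nearest position whose footprint, dilated by a 2 px margin, clears
every pattern. Candidate translations are ordered by Euclidean length,
ties broken by angle from east counterclockwise — a deterministic rule, so
repeated runs place identical ROIs. Manual ROIs always take precedence.

### Coordinates

All coordinates are R-native: 1-based, pixel-centered, rows = y,
columns = x. Masks are inclusive pixel sets. (A 0-based convention was
considered and rejected: every exchange with base R and EBImage indexing
would need a ±1 shift.)

## The synthetic imaging model

The generator exists to provide ground truth for every metric; its noise
model is the minimal one consistent with using a dark-frame mean and
variance as background:

$$\mathrm{ADU}(x) \sim \mathrm{Poisson}(g\, S(x)) +
  \mathcal N(\mu_{off}, \sigma_{read}^2)$$

with $S(x)$ the photon rate, $g$ the gain (ADU/photon), $\mu_{off}$ the
constant offset and $\sigma_{read}$ the read noise. Defaults
($\mu_{off} = 100$ ADU, $\sigma_{read} = 1.6$ ADU, $g = 2$ ADU/photon,
pixel size 0.11 µm/px) are conventional values for a back-illuminated
sCMOS behind a 100× objective; they are configurable and nothing
downstream depends on their specific values, because all metrics are
background-corrected.

Within a pattern, $S = \mu_{on}(1 + c\,z(x))$ where $z$ is a white
Gaussian field low-pass filtered (Gaussian, σ = 3 px) and then
standardized **over the pattern's pixels**, so the realized spatial CV
equals the requested $c$ exactly and homogeneity is controllable
independently of the mean. Outside all patterns,
$S = \sum_k \mu_{on,k} f_{off,k}$ — off-pattern adsorption from each
deposited protein adds.

Ground truth is computed in closed form from the generating parameters
before any noise is drawn:

- selectivity $= \mu_{on} / \sum_k \mu_{on,k} f_{off,k}$ (camera terms
  cancel);
- homogeneity $= \mu_e / (\mu_e + (c\,\mu_e)^2)$ with
  $\mu_e = g\,\mu_{on}$, i.e. shot variance plus spatial variance (read
  noise cancels against the camera variance);
- amount $= g(\mu_{on} - \sum_k \mu_{on,k} f_{off,k})$.

For multiplexed series, channel $c$ deposits
$\mu_{on}(c) \cdot \mathrm{crosstalk}[c, i]$ on pattern $i$, the intended
entry pinned at 1; spatial variation is applied on the intended pattern
only (crosstalk deposits are tiny and rendered flat).

Filaments are rendered as Gaussian-profile line segments (σ = 1.3 px,
peak 300 photons/px by default) along arbitrary polylines, evaluated
analytically at sub-pixel positions (ridge sampled every 0.25 px; each
sample contributes an isotropic Gaussian). Pause placement is drawn to
realize the requested duty ratio to rounding: exactly
$\mathrm{round}((1-d)\,n)$ of the $n$ inter-frame intervals are paused,
grouped into blocks of 2–5 frames at random gaps. Blocks rather than
i.i.d. frames, because 1-frame pauses are physically and analytically
indistinguishable from localization jitter; exact counts rather than
geometric run lengths, because block-length randomness would make the
realized duty wander far beyond binomial scatter. Off-pattern filaments
never move (no motor beneath them).

Cell-adhesion fields draw Poisson counts with mean density × area per
region, place centroids uniformly (rejecting overlaps; a request beyond
~70 % packing errors out), and record every centroid, so count metrics
can be checked exactly against bookkeeping.

All simulators take an explicit `seed`, run on a private RNG stream, and
restore the caller's `.Random.seed`; a fixed seed is bit-reproducible.

### What the generator does not emulate

No optical PSF or TIRF evanescent-field depth profile, no photobleaching,
no fixed-pattern (per-pixel) camera nonuniformity, no cell morphology
beyond disks, no filament bending or crossing. Passing recovery tests
therefore demonstrates correctness of the *measurement* pipeline under
the stated noise model — not robustness to optical blur between adjacent
patterns, bleaching drifts in time courses, or crowded gliding fields.
Those effects must be controlled experimentally or handled upstream.

## Segmentation

`segment_patterns()` is a reproducible alternative to manually drawn
ROIs (which remain first-class inputs everywhere): Gaussian smoothing
(σ = 1 px), Otsu threshold (or a fixed threshold for exact
reproducibility), hole filling, minimum-area filtering, connected-component
labeling. Because Otsu always splits *something*, a guard rejects
segmentations whose foreground–background mean separation is below 3
robust SDs of the image — a blank or noise-only field returns an empty
mask with a warning, not spurious labels. Connectivity is 8 by default
(4 available); labeling is EBImage's 4-connected `bwlabel` plus a
union-find merge of diagonally touching labels. Equivalent diameter is
$2\sqrt{A/\pi}$; `filter_by_diameter()` bounds are inclusive, and the
20–40 µm gate used for cell-adhesion analysis is its default.

## Enrichment indices

The four variants share one algebraic skeleton (a ratio or difference of
background-corrected inner/outer means) and differ only in what serves as
background: an unpatterned region (simple), a paired cell-free pattern
(bleed-through corrected), or the same ROIs before cell landing
(temporal, and the raw signal increase). ROI pairing for the cell-free
correction is explicit user input — no automatic cell detection is
attempted. The raw increase is invariant under global additive drift; the
temporal fold is not, which is why the increase is preferred at low
signal. Time courses report minutes relative to a user-chosen baseline
frame `t0` (default: a single frame, not a window; a window average can
be emulated by passing averaged stats).

## Gliding analysis

`build_kymograph()` samples each frame by bilinear interpolation at 1 px
arc-length steps along the path, averaging `width` (odd, default 3)
samples along the local normal. `trace_filament()` localizes the filament
per frame by an intensity-weighted centroid after per-column background
subtraction (lower-quartile background; pixels below 30 % of the peak
zeroed). The lower quartile, not the median, is used so that a filament
occupying a large fraction of a short path does not contaminate the
background estimate; noise is estimated one-sided from the below-quartile
tail (scaled by the Gaussian factor 0.476) and traces whose median
peak/noise ratio falls below 5 are rejected with a reason.

Run/pause segmentation: positions are median-filtered (window 3),
instantaneous speeds thresholded at 20 % of the median moving speed
(`pause_threshold_frac`), the state sequence median-filtered to remove
single-frame flips, and sub-threshold dips shorter than
`min_pause_frames = 2` reabsorbed into runs. Duty is the moving fraction
of intervals (duty + paused fraction = 1 by construction); mean speed is
averaged over *interior* moving intervals only, since transition
intervals straddle both states and would bias the speed low. Traces whose
positional range stays under 3 px are classified stationary (duty 0,
speed undefined) before any thresholding, so the threshold never operates
on pure jitter. These defaults stand in for an external kymograph tool
whose pause criterion is unpublished; they are exposed as arguments and
recorded in output metadata.

Motility calls replace manual annotation with an explicit rule: motile
iff net displacement ≥ `min_net_displacement` (default 1 µm). Group
fractions (on/off pattern, by majority of path pixels) report `NA` for
empty groups, never 0. Aggregates are reported as mean ± SEM with n.

## Adhesion metrics

A cell is on-pattern iff its centroid lies on a labeled pixel — the
centroid rule, chosen over any-overlap because it is unambiguous for
cells spanning a pattern edge; the assignment of every cell is returned
so users can apply a different rule. The nonspecific-adhesion formula is
read as $100(1 - d_{on}/(d_{on}+d_{off}))$; the alternative literal
left-to-right grouping is unbounded and contradicts its use as a bounded
percentage, so it was rejected. Normalized density divides by the *mean*
reference density across reference fields, so the reference condition
itself averages to 1 by construction.

## Validation design and problem sizes

The test suite validates three layers, kept deliberately distinct:

1. **Formula layer** — every metric against independently written
   naive-loop oracles on randomized inputs (1,000 draws), agreement to
   1e−9 relative.
2. **Recovery layer** — metrics recomputed from simulated images recover
   the generating parameters: 50 fields of 96×96 px per condition for
   selectivity (2–100), crosstalk (0–3 %) and off-pattern fractions
   (0.4–1 %), judged on the median against the generating value (10 %,
   or twice the shot/read-noise floor for near-zero fractions); gliding
   movies of 200 frames at 0.25–1 µm/s and duty 0/0.7/1, with eight
   filaments aggregated per condition — mirroring how the assay reports
   statistics over n filaments — and compared against the *realized*
   scripted ground truth.
3. **Invariance layer** — affine/scale/drift invariances, diagonal ≡ 1,
   bounds, determinism (seed-fixed bit-identity), idempotence of
   segmentation.

Field sizes (96×96 to 40×96 px), frame counts (200) and replicate counts
(8–50) were chosen as the smallest sizes at which the expected sampling
error of each recovered quantity is several times smaller than the
tolerance being tested, so failures indicate defects rather than noise.

## Known limitations

- Homogeneity's printed-variance form has units ADU⁻¹ and therefore
  depends on gain; comparisons are only meaningful at fixed acquisition
  settings (the SD variant is unitless but is not the reference form).
- The scalar camera background ignores fixed-pattern noise; for cameras
  with strong per-pixel offset structure, flat-field upstream.
- The centroid tracker assumes one dominant filament per kymograph;
  crossing filaments need path-level separation by the user.
- Sub-pixel speeds below ~0.2 px/frame approach the localization noise
  floor; duty estimates degrade before speed estimates do.
- No multiple-testing or hypothesis-testing layer is provided; the
  package stops at per-object metrics and mean ± SEM summaries.
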