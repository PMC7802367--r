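test_that("measure_roi returns mean, unbiased variance and pixel count", {
  img <- matrix(7, 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[2:4, 2:4] <- TRUE
  st <- measure_roi(img, mask)
  expect_equal(st$mean, 7)
  expect_equal(st$variance, 0)
  expect_equal(st$n_pixels, 9L)

  img2 <- matrix(0, 2, 2); img2[1, 1] <- 1; img2[1, 2] <- 2; img2[2, 1] <- 3
  mask2 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  st2 <- measure_roi(img2, mask2)
  expect_equal(st2$mean, 2)
  expect_equal(st2$variance, 1)  # n-1 denominator

  one <- matrix(FALSE, 2, 2); one[1, 1] <- TRUE
  st3 <- measure_roi(img2, one)
  expect_equal(st3$variance, 0)
  expect_true(st3$degenerate)
})

test_that("measure_roi rejects empty or mismatched masks", {
  img <- matrix(1, 4, 4)
  expect_error(measure_roi(img, matrix(FALSE, 4, 4)), "empty mask")
  expect_error(measure_roi(img, matrix(TRUE, 3, 4)), "dimensions differ")
})

test_that("measure_roi matches the naive pixel-loop oracle", {
  set.seed(41)
  for (i in 1:10) {
    nr <- sample(4:64, 1); nc <- sample(4:64, 1)
    img <- matrix(runif(nr * nc, 0, 4000), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.3, nr, nc)
    if (sum(mask) < 2) mask[1:2, 1] <- TRUE
    st <- measure_roi(img, mask)
    orc <- oracle_roi(img, mask)
    expect_equal(st$mean, orc$mean, tolerance = 1e-12)
    expect_equal(st$variance, orc$variance, tolerance = 1e-12)
    expect_equal(st$n_pixels, orc$n)
  }
})

test_that("selectivity follows the background-corrected ratio", {
  cam <- camera_background(100, 10)
  p <- roi_stats(1000, 50, 200)
  np <- roi_stats(110, 12, 200)
  expect_equal(selectivity(p, np, cam), 90)
  expect_equal(selectivity(p, p, cam), 1)
  u <- selectivity(p, roi_stats(100, 5, 200), cam)
  expect_true(is_unmeasurable(u))
  expect_match(attr(u, "reason"), "camera floor")
})

test_that("selectivity is invariant under affine rescaling of intensities", {
  set.seed(7)
  for (i in 1:20) {
    cam_m <- runif(1, 50, 150)
    p <- runif(1, 500, 4000); np <- runif(1, cam_m + 5, 400)
    a <- runif(1, 0.1, 10); b <- runif(1, -20, 50)
    s0 <- selectivity(roi_stats(p, 1, 10), roi_stats(np, 1, 10),
                      camera_background(cam_m, 1))
    s1 <- selectivity(roi_stats(a * p + b, 1, 10),
                      roi_stats(a * np + b, 1, 10),
                      camera_background(a * cam_m + b, 1))
    expect_equal(s1, s0, tolerance = 1e-12)
  }
})

test_that("homogeneity divides corrected mean by corrected variance", {
  cam <- camera_background(100, 10)
  expect_equal(homogeneity(roi_stats(600, 30, 50), cam), 25)
  # monotone: larger variance at equal means gives smaller homogeneity
  h1 <- homogeneity(roi_stats(600, 30, 50), cam)
  h2 <- homogeneity(roi_stats(600, 45, 50), cam)
  expect_lt(h2, h1)
  expect_true(is_unmeasurable(homogeneity(roi_stats(600, 9, 50), cam)))
})

test_that("homogeneity_sd is the SD-denominator variant, exposed separately", {
  cam <- camera_background(100, 10)
  expect_equal(homogeneity_sd(roi_stats(600, 30, 50), cam), 500 / sqrt(20))
  expect_true(is_unmeasurable(homogeneity_sd(roi_stats(600, 10, 50), cam)))
})

test_that("amount_patterned is the plain mean difference", {
  expect_equal(amount_patterned(roi_stats(1000, 1, 5), roi_stats(110, 1, 5)),
               890)
  x <- roi_stats(321, 4, 9)
  expect_equal(amount_patterned(x, x), 0)
  neg <- amount_patterned(roi_stats(100, 1, 5), roi_stats(200, 1, 5))
  expect_equal(as.numeric(neg), -100)
  expect_true(attr(neg, "negative"))
})

make_two_pattern_fixture <- function(means, bg = 100) {
  # two constant 4x4 patterns in a 12x20 field; means[[ch]] = c(p1, p2)
  m1 <- matrix(FALSE, 12, 20); m1[3:6, 3:6] <- TRUE
  m2 <- matrix(FALSE, 12, 20); m2[3:6, 13:16] <- TRUE
  imgs <- lapply(means, function(mu) {
    img <- matrix(bg, 12, 20); img[m1] <- mu[1]; img[m2] <- mu[2]
    img
  })
  list(images = imgs,
       patterns = pattern_set(list(p1 = m1, p2 = m2),
                              c(ch1 = "p1", ch2 = "p2")),
       camera = camera_background(bg, 1))
}

test_that("cross-adsorption normalizes each channel to its intended pattern", {
  fx <- make_two_pattern_fixture(list(ch1 = c(2100, 126), ch2 = c(126, 2100)))
  M <- cross_adsorption_matrix(fx$images, fx$patterns, fx$camera)
  expect_equal(unname(diag(M)), c(1, 1))
  expect_equal(M["ch1", "p2"], 26 / 2000)  # the ~1.3% regime
  expect_equal(M["ch2", "p1"], 0.013)
  # wrong-pattern mean at background -> exactly 0
  fx0 <- make_two_pattern_fixture(list(ch1 = c(2100, 100), ch2 = c(100, 2100)))
  M0 <- cross_adsorption_matrix(fx0$images, fx0$patterns, fx0$camera)
  expect_equal(M0["ch1", "p2"], 0)
})

test_that("channels with intended signal at background are unmeasurable", {
  fx <- make_two_pattern_fixture(list(ch1 = c(100, 130), ch2 = c(126, 2100)))
  M <- cross_adsorption_matrix(fx$images, fx$patterns, fx$camera)
  expect_true(all(is.na(M["ch1", ])))
  expect_equal(attr(M, "unmeasurable_channels"), "ch1")
  expect_equal(M["ch2", "p2"], 1)
})

test_that("cross-adsorption requires an image per assigned channel", {
  fx <- make_two_pattern_fixture(list(ch1 = c(2100, 126), ch2 = c(126, 2100)))
  expect_error(cross_adsorption_matrix(fx$images["ch1"], fx$patterns,
                                       fx$camera), "ch2")
})

test_that("nonspecific binding is the off-field fraction of intended signal", {
  fx <- make_two_pattern_fixture(list(ch1 = c(1100, 100), ch2 = c(100, 1100)))
  off <- lapply(fx$images, function(i) matrix(104, 12, 20))
  ns <- nonspecific_binding(fx$images, off, fx$patterns, fx$camera)
  expect_equal(unname(ns["ch1"]), 4 / 1000)  # the ~0.40% regime
  # off-field at camera background -> exactly 0
  off0 <- lapply(fx$images, function(i) matrix(100, 12, 20))
  ns0 <- nonspecific_binding(fx$images, off0, fx$patterns, fx$camera)
  expect_equal(unname(ns0["ch1"]), 0)
  # non-congruent off-field image rejected (matched ROI position rule)
  offbad <- lapply(fx$images, function(i) matrix(104, 12, 21))
  expect_error(nonspecific_binding(fx$images, offbad, fx$patterns, fx$camera),
               "congruent")
})

test_that("auto off-pattern ROI preserves shape and avoids all patterns", {
  m <- disk_mask(60, 60, 20, 30, 8)
  all_pat <- m | disk_mask(60, 60, 45, 30, 6)
  off <- auto_off_roi(m, all_pat, margin = 2)
  expect_equal(sum(off), sum(m))        # identical size
  expect_false(any(off & all_pat))      # clear of every pattern
  # deterministic: same inputs, same placement
  expect_identical(off, auto_off_roi(m, all_pat, margin = 2))
})

test_that("quantify_patterns assembles the per-pattern metric table", {
  set.seed(5)
  spec <- pattern_spec("disk", center = c(30, 48), size = 3, on_mean = 500,
                       on_cv = 0.05, off_fraction = 0.01)
  sim <- simulate_pattern_image(spec, field_size = c(96, 96), seed = 21)
  masks <- list(p1 = unclass(sim$truth$label_mask) == 1)
  ps <- pattern_set(masks, c(chA = "p1"))
  cam <- estimate_camera_background(simulate_dark_frames(seed = 22))
  tab <- quantify_patterns(list(chA = sim$image), ps, cam)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pattern_id, "p1")
  expect_gt(tab$selectivity, 50)
  expect_gt(tab$amount, 0)
  expect_equal(tab$flags, "")
})
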