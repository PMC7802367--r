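test_that("fixed seed gives bit-identical simulator output", {
  spec <- pattern_spec("disk", center = c(20, 20), size = 2, on_mean = 300)
  a <- simulate_pattern_image(spec, field_size = c(48, 48), seed = 9)
  b <- simulate_pattern_image(spec, field_size = c(48, 48), seed = 9)
  expect_identical(a$image, b$image)
  d1 <- simulate_dark_frames(n_frames = 5, field_size = c(16, 16), seed = 2)
  d2 <- simulate_dark_frames(n_frames = 5, field_size = c(16, 16), seed = 2)
  expect_identical(d1, d2)
})

test_that("simulators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_pattern_image(
    pattern_spec("disk", c(20, 20), 2, 300), field_size = c(48, 48),
    seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("ground truth equals the closed-form functions of the parameters", {
  cam <- camera_model(offset_mean = 100, read_noise_sd = 1.6, gain = 2)
  spec <- pattern_spec("disk", center = c(24, 24), size = 2, on_mean = 500,
                       on_cv = 0.08, off_fraction = 0.01)
  tr <- simulate_pattern_image(spec, cam, field_size = c(48, 48),
                               seed = 1)$truth
  # selectivity: on_mean / (on_mean * off_fraction), camera cancels
  expect_equal(tr$true_selectivity, 500 / 5)
  # homogeneity: mu_e / (shot + spatial variance), mu_e = on_mean * gain
  mu_e <- 500 * 2
  expect_equal(tr$true_homogeneity, mu_e / (mu_e + (0.08 * mu_e)^2))
  expect_equal(tr$true_amount, (500 - 5) * 2)
  # off_fraction 1: pattern indistinguishable from background
  sp1 <- pattern_spec("disk", c(24, 24), 2, 500, off_fraction = 1)
  expect_equal(simulate_pattern_image(sp1, cam, c(48, 48),
                                      seed = 1)$truth$true_selectivity, 1)
})

test_that("increasing on_cv strictly decreases true homogeneity", {
  hs <- vapply(c(0, 0.02, 0.05, 0.1, 0.2), function(cv) {
    sp <- pattern_spec("disk", c(24, 24), 2, 500, on_cv = cv)
    simulate_pattern_image(sp, field_size = c(48, 48),
                           seed = 1)$truth$true_homogeneity
  }, numeric(1))
  expect_true(all(diff(hs) < 0))
})

test_that("realized within-pattern CV matches the request", {
  # the spatial field is standardized over the pattern, so the noise-free
  # CV is exact; after shot noise the measured variance decomposes as
  # shot + spatial
  spec <- pattern_spec("disk", c(48, 48), 6, on_mean = 2000, on_cv = 0.1,
                       off_fraction = 0)
  cam <- camera_model(gain = 2)
  sim <- simulate_pattern_image(spec, cam, field_size = c(96, 96), seed = 3)
  m <- unclass(sim$truth$label_mask) == 1
  st <- measure_roi(sim$image, m)
  expected_var <- 2000 * 2 + (0.1 * 2000 * 2)^2 + cam$read_noise_sd^2
  expect_equal(st$variance, expected_var, tolerance = 0.1)
})

test_that("overlapping or out-of-field pattern specs are rejected", {
  a <- pattern_spec("disk", c(20, 20), 2, 300)
  b <- pattern_spec("disk", c(22, 20), 2, 300)
  expect_error(simulate_pattern_image(list(a, b), field_size = c(48, 48)),
               "overlap")
  far <- pattern_spec("disk", c(500, 500), 2, 300)
  expect_error(simulate_pattern_image(far, field_size = c(48, 48)),
               "outside the field")
  expect_error(pattern_spec("disk", c(10, 10), -1, 300), "positive")
})

test_that("dark-frame statistics converge to the camera model", {
  cam <- camera_model(offset_mean = 100, read_noise_sd = 1.6)
  stack <- simulate_dark_frames(cam, n_frames = 100, field_size = c(64, 64),
                                seed = 5)
  bg <- estimate_camera_background(stack)
  sem <- cam$read_noise_sd / sqrt(length(stack))
  expect_lt(abs(bg$mean - 100), 3 * sem)
  expect_equal(bg$variance, 1.6^2, tolerance = 0.05)
})

test_that("multiplex ground truth carries the input crosstalk matrix", {
  specs <- list(p1 = pattern_spec("disk", c(16, 16), 1.5, 1000, off_fraction = 0),
                p2 = pattern_spec("disk", c(48, 16), 1.5, 800, off_fraction = 0))
  ct <- matrix(c(1, 0.013, 0.03, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("ch_p1", "ch_p2"), c("p1", "p2")))
  sim <- simulate_multiplex_series(specs, crosstalk = ct,
                                   field_size = c(32, 64), seed = 2)
  expect_identical(sim$truth$crosstalk_matrix, ct)
  expect_named(sim$images, c("ch_p1", "ch_p2"))
})

test_that("multiplex validates assignment and intended entries", {
  specs <- list(p1 = pattern_spec("disk", c(16, 16), 1.5, 1000))
  expect_error(simulate_multiplex_series(specs, assignment = c(ch = "p9"),
                                         field_size = c(32, 32)),
               "missing pattern")
  specs2 <- list(p1 = pattern_spec("disk", c(16, 16), 1.5, 1000, off_fraction = 0),
                 p2 = pattern_spec("disk", c(48, 16), 1.5, 800, off_fraction = 0))
  ct <- matrix(c(0.9, 0, 0, 1), 2, 2,
               dimnames = list(c("ch_p1", "ch_p2"), c("p1", "p2")))
  expect_error(simulate_multiplex_series(specs2, crosstalk = ct,
                                         field_size = c(32, 64)),
               "must equal 1")
})

test_that("gliding script kinematics are exact on the noise-free centerline", {
  setup <- gliding_setup(0.5, 1, 50)
  sc <- filament_script(setup$path, speed = 0.5, duty_ratio = 1)
  sim <- simulate_gliding_movie(sc, field_size = setup$field, n_frames = 50,
                                frame_interval = 0.2, seed = 1)
  rec <- sim$truth$filaments[[1]]
  # duty 1: displacement after t intervals is exactly speed * t * dt
  expect_equal(rec$position_um - rec$position_um[1],
               0.5 * 0.2 * (0:49), tolerance = 1e-12)
  # duty 0: stationary
  sc0 <- filament_script(setup$path, speed = 0.5, duty_ratio = 0)
  sim0 <- simulate_gliding_movie(sc0, field_size = setup$field, n_frames = 50,
                                 frame_interval = 0.2, seed = 1)
  expect_equal(sim0$truth$filaments[[1]]$net_displacement_um, 0)
})

test_that("realized moving fraction matches the requested duty ratio", {
  setup <- gliding_setup(0.5, 0.7, 200)
  sc <- filament_script(setup$path, speed = 0.5, duty_ratio = 0.7)
  for (seed in 1:5) {
    sim <- simulate_gliding_movie(sc, field_size = setup$field,
                                  n_frames = 200, frame_interval = 0.2,
                                  seed = seed)
    rec <- sim$truth$filaments[[1]]
    expect_lt(abs(rec$realized_duty - 0.7),
              3 * sqrt(0.7 * 0.3 / 199))  # binomial error at n = 199
    expect_equal(rec$realized_duty, mean(rec$moving))
  }
})

test_that("off-pattern filaments never move and bad intervals are rejected", {
  setup <- gliding_setup(0.5, 1, 30)
  sc <- filament_script(setup$path, speed = 0.5, duty_ratio = 1,
                        on_pattern = FALSE)
  sim <- simulate_gliding_movie(sc, field_size = setup$field, n_frames = 30,
                                frame_interval = 0.2, seed = 2)
  expect_equal(sim$truth$filaments[[1]]$net_displacement_um, 0)
  expect_error(simulate_gliding_movie(sc, field_size = setup$field,
                                      n_frames = 30, frame_interval = 0),
               "frame_interval")
})

make_adhesion_mask <- function() {
  l <- matrix(0L, 150, 150)
  x <- col(l); y <- row(l)
  l[(x - 40)^2 + (y - 40)^2 <= 25^2] <- 1L
  l[(x - 105)^2 + (y - 105)^2 <= 25^2] <- 2L
  label_mask(l, pixel_size = 0.5)
}

test_that("adhesion field places all centroids on pattern when density_off = 0", {
  lab <- make_adhesion_mask()
  sim <- simulate_adhesion_field(lab, density_on = 0.005, density_off = 0,
                                 cell_radius = 2, seed = 4)
  expect_true(all(sim$centroids$on_pattern))
  expect_true(all(unclass(lab)[cbind(sim$centroids$y,
                                     sim$centroids$x)] > 0))
  expect_equal(sim$truth$n_off, 0)
})

test_that("adhesion counts follow Poisson sampling around density * area", {
  lab <- make_adhesion_mask()
  sim <- simulate_adhesion_field(lab, density_on = 0.01, density_off = 0.001,
                                 cell_radius = 1.2, seed = 6)
  lam_on <- sim$truth$expected_n_on
  expect_lt(abs(sim$truth$n_on - lam_on), 4 * sqrt(lam_on))
  expect_equal(sim$truth$expected_nonspecific_pct,
               100 * 0.001 / 0.011)
})

test_that("densities beyond close packing are rejected", {
  lab <- make_adhesion_mask()
  expect_error(simulate_adhesion_field(lab, density_on = 1, density_off = 0,
                                       cell_radius = 5, seed = 1),
               "close packing")
})
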