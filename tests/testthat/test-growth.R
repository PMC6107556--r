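test_that("perimeter extraction matches the analytic circumference", {
  g <- voxel_geometry(dz = 1)
  cells <- data.frame(x = 30, y = 30, z = 0.5, r = 20, dividing = TRUE)
  sl <- render_membrane_frame(cells, g, c(60, 60, 1), psf_sigma_um = 0.3,
                              snr = 20, seed = 1)[1, , ]
  p <- extract_perimeter(sl, g)
  expect_equal(p, 2 * pi * 20, tolerance = 0.03)
  expect_error(extract_perimeter(matrix(0, 32, 32), g), "foreground")
  # two objects: only the larger is measured
  cells2 <- data.frame(x = c(25, 70), y = c(40, 40), z = 0.5, r = c(20, 6),
                       dividing = TRUE)
  sl2 <- render_membrane_frame(cells2, g, c(90, 80, 1), psf_sigma_um = 0.3,
                               snr = 20, seed = 2)[1, , ]
  expect_equal(extract_perimeter(sl2, g), 2 * pi * 20, tolerance = 0.03)
})

test_that("sphere volume follows the perimeter model exactly", {
  expect_equal(sphere_volume_from_perimeter(2 * pi), 4 * pi / 3)
  expect_equal(sphere_volume_from_perimeter(4 * pi), 4 / 3 * pi * 8)
  p <- runif(5, 1, 100)
  expect_equal(sphere_volume_from_perimeter(2 * p),
               8 * sphere_volume_from_perimeter(p))
  expect_error(sphere_volume_from_perimeter(0), "positive")
  expect_error(sphere_volume_from_area(-1), "positive")
  # area route agrees with the perimeter route for a true circle
  r <- 3.7
  expect_equal(sphere_volume_from_area(pi * r^2),
               sphere_volume_from_perimeter(2 * pi * r))
})

test_that("growth-rate fitting is exact on linear data and unbiased on noise", {
  s <- volume_time_series(c(0, 60, 120, 180), c(100, 119, 138, 157))
  fit <- fit_growth_rate(s)
  expect_equal(fit$rate_um3_per_hr, 19, tolerance = 1e-12)
  expect_equal(fit$sd, 0, tolerance = 1e-9)
  flat <- fit_growth_rate(volume_time_series(c(0, 60, 120), rep(50, 3)))
  expect_equal(flat$rate_um3_per_hr, 0)
  expect_error(fit_growth_rate(volume_time_series(c(0, 60), c(1, 2))), "3 time")
  # Monte-Carlo unbiasedness: slope 19, additive noise SD 5, n = 10
  set.seed(42)
  slopes <- replicate(100, {
    t <- seq(0, 180, length.out = 10)
    v <- 100 + 19 * t / 60 + rnorm(10, 0, 5)
    fit_growth_rate(list(times_min = t, volumes_um3 = v))$rate_um3_per_hr
  })
  expect_lt(abs(mean(slopes) - 19), 1)
})

test_that("division-rate model reproduces the printed arithmetic", {
  expect_identical(required_division_rate(19, 6), 3L)
  expect_identical(required_division_rate(0, 6), 0L)
  expect_identical(required_division_rate(12, 6), 2L)
  expect_error(required_division_rate(19, 0), "positive")
  expect_equal(growth_decomposition(19, 1.7, 6), 1.7 * 6 / 19)
  expect_equal(growth_decomposition(19, 1.7, 6), 0.537, tolerance = 0.001)
  expect_equal(growth_decomposition(19, 0, 6), 0)
  expect_equal(growth_decomposition(19, 4, 6), 1) # capped
  expect_error(growth_decomposition(0, 1, 6), "positive")
})

test_that("volume pipeline recovers the growth rate of a rendered sphere movie", {
  # growing sphere with substantial growth over the movie, re-measured from
  # the rendered frames (per-frame contour jitter is ~1%, so the growth span
  # must dominate it)
  g <- voxel_geometry(dz = 1)
  times <- seq(0, 180, by = 20)
  vols <- 150 + 200 * times / 60
  radii <- (3 * vols / (4 * pi))^(1 / 3)
  frames <- lapply(radii, function(r) {
    cells <- data.frame(x = 15, y = 15, z = 0.5, r = r, dividing = TRUE)
    render_membrane_frame(cells, g, c(30, 30, 1), psf_sigma_um = 0.2,
                          snr = 15, seed = round(r * 100))
  })
  data <- array(0, c(length(frames), 1, dim(frames[[1]])[2:3]))
  for (i in seq_along(frames)) data[i, 1, , ] <- frames[[i]][1, , ]
  seq <- image_sequence(data, g)
  series <- measure_volume_series(seq)
  fit <- fit_growth_rate(series)
  expect_equal(fit$rate_um3_per_hr, 200, tolerance = 0.05)
})
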