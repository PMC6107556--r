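test_that("cell packing places the requested count without overlap", {
  pk <- generate_cell_packing(2, c(40, 40, 40), seed = 1)
  expect_equal(nrow(pk), 2)
  d <- sqrt(sum((pk[1, c("x", "y", "z")] - pk[2, c("x", "y", "z")])^2))
  expect_gte(d, (pk$r[1] + pk$r[2]) * 0.9)
  # the lateral-domain box holds its full mid-stage complement
  pk2 <- generate_cell_packing(212, c(32, 41, 20), seed = 2)
  expect_equal(nrow(pk2), 212)
  expect_true(all(pk2$x >= pk2$r & pk2$x <= 32 - pk2$r))
  # identical seeds give identical packings
  expect_identical(generate_cell_packing(50, c(30, 30, 10), seed = 7),
                   generate_cell_packing(50, c(30, 30, 10), seed = 7))
  expect_error(generate_cell_packing(500, c(10, 10, 10), radius_mean_um = 2,
                                     max_tries = 50, seed = 1), "infeasible")
})

test_that("motion model honours speed, drift and boundary reflection", {
  pk <- generate_cell_packing(30, c(50, 50, 10), seed = 3)
  still <- simulate_motion(pk, list(mode = "random", mean_speed = 0,
                                    speed_sd = 0, drift_weight = 0),
                           n_frames = 5, seed = 4, domain_um = c(50, 50, 10))
  expect_equal(max(tapply(still$x_um, still$track_id, function(x) diff(range(x)))), 0)
  # drift_weight 1: every step points exactly at the sink
  drift <- simulate_motion(pk, list(mode = "directed", mean_speed = 0.2,
                                    speed_sd = 0.05, sink = c(200, 200),
                                    drift_weight = 1),
                           n_frames = 3, seed = 5, domain_um = c(50, 50, 10))
  one <- drift[drift$track_id == pk$cell_id[1], ]
  step <- c(diff(one$x_um)[1], diff(one$y_um)[1])
  to_sink <- c(200 - one$x_um[1], 200 - one$y_um[1])
  cosang <- sum(step * to_sink) / sqrt(sum(step^2) * sum(to_sink^2))
  expect_gt(cosang, 0.9999)
  # positions stay inside the domain
  expect_true(all(drift$x_um >= 0 & drift$x_um <= 50))
})

test_that("random-walk step headings are circularly uniform", {
  pk <- generate_cell_packing(500, c(400, 400, 5), radius_mean_um = 1,
                              seed = 11)
  tr <- simulate_motion(pk, list(mode = "random", mean_speed = 0.2,
                                 speed_sd = 0.05, drift_weight = 0),
                        n_frames = 10, seed = 12, domain_um = c(400, 400, 5))
  ang <- unlist(lapply(split(tr, tr$track_id), function(t)
    atan2(diff(t$y_um), diff(t$x_um)) * 180 / pi))
  expect_gt(rayleigh_p(ang), 0.01)
})

test_that("division schedule follows the Poisson model", {
  pk <- generate_cell_packing(100, c(100, 100, 10), seed = 1)
  expect_equal(nrow(simulate_divisions(pk, 0, 180, seed = 1)), 0)
  # expected 4.4/hr * 3 hr = 13.2 events; empirical mean over 200 seeds
  counts <- vapply(1:200, function(s)
    nrow(simulate_divisions(pk, 4.4, 180, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 13.2), 0.5)
  sch <- simulate_divisions(pk, 4.4, 180, duration_min = 25, seed = 3)
  expect_true(all(sch$t_end_min - sch$t_start_min == 25))
  expect_true(all(sch$t_start_min >= 0 & sch$t_start_min <= 180))
})

test_that("membrane rendering puts peak intensity on the shell", {
  g <- voxel_geometry()
  cells <- data.frame(x = 10, y = 10, z = 5, r = 4)
  img <- render_membrane_frame(cells, g, c(20, 20, 10), psf_sigma_um = 0,
                               shell_um = 0.5, snr = NULL)
  zc <- round(5 / g$dz)
  sl <- img[zc, , ]
  peak <- which(sl == max(sl), arr.ind = TRUE)
  r_peak <- sqrt(((peak[, 1] - 0.5) * g$dy - 10)^2 +
                 ((peak[, 2] - 0.5) * g$dx - 10)^2)
  # radius at the slice plane (slice may sit slightly off the equator)
  z_off <- (zc - 0.5) * g$dz - 5
  r_slice <- sqrt(4^2 - z_off^2)
  expect_true(all(abs(r_peak - r_slice) <= max(g$dx, g$dz)))
  # interior dark
  cy <- round(10 / g$dy); cx <- round(10 / g$dx)
  expect_lt(sl[cy, cx], 0.05 * max(sl))
  # zero cells, noise on: pure noise frame
  nf <- render_membrane_frame(cells[0, ], g, c(10, 10, 2), snr = 10, seed = 1)
  expect_lt(max(nf), 0.35 * 100) # no structure above the noise floor
  # noise and blur off: binary-ish shell mask with empty interior
  expect_equal(min(img), 0)
})

test_that("simulated movies are deterministic and conserve the growth law", {
  cfg <- quick_config(seed = 9, n_cells = 15, division_rate = 3)
  a <- simulate_somite_movie(cfg, n_frames = 6)
  b <- simulate_somite_movie(cfg, n_frames = 6)
  expect_identical(a$seq$data, b$seq$data)
  expect_identical(a$truth$tracks, b$truth$tracks)
  # linear total-volume growth within 2% despite divisions
  vol <- a$truth$volumes
  fitv <- stats::lm(volume_um3 ~ t_min, vol)
  pred <- stats::fitted(fitv)
  expect_lt(max(abs(vol$volume_um3 - pred) / vol$volume_um3), 0.02)
  g_hr <- unname(stats::coef(fitv)[2]) * 60
  expect_equal(g_hr, cfg$growth$rate_um3_per_hr, tolerance = 0.02)
  # daughters conserve volume at the split: r_d = r / 2^(1/3)
  cells <- a$truth$cells
  div_t <- a$truth$divisions$t_min
  expect_gt(length(div_t), 0)
})

test_that("ground truth exports round-trip through CSV", {
  cfg <- quick_config(seed = 10, n_cells = 8, division_rate = 2)
  sim <- simulate_somite_movie(cfg, n_frames = 4, render = FALSE)
  dir <- withr::local_tempdir()
  export_ground_truth(sim$truth, dir)
  back <- read_ground_truth(dir)
  expect_equal(as.data.frame(back$tracks), as.data.frame(sim$truth$tracks),
               tolerance = 1e-12)
  expect_equal(nrow(back$divisions), nrow(sim$truth$divisions))
  if (nrow(back$divisions) > 0)
    expect_equal(back$divisions, sim$truth$divisions, tolerance = 1e-12)
  expect_equal(back$volumes, sim$truth$volumes, tolerance = 1e-12)
  # empty tracks give a header-only file that reloads as an empty table
  empty <- sim$truth
  empty$tracks <- as_track_table(empty$tracks[0, ])
  export_ground_truth(empty, dir)
  expect_equal(nrow(read_ground_truth(dir)$tracks), 0)
})
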