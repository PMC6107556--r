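test_that("preprocessing removes flat and smooth backgrounds", {
  g <- voxel_geometry()
  const <- image_sequence(array(50, c(2, 1, 64, 64)), g)
  out <- preprocess_for_tracking(const)
  expect_equal(max(out$data), 0)
  expect_error(preprocess_for_tracking(const, rolling_ball_radius_px = 0),
               "positive")
  # dark blob on a smooth gradient: after inversion the blob is bright and
  # the gradient residual stays below 5% of the blob response
  grad <- matrix(rep(seq(40, 90, length.out = 64), each = 64), 64, 64)
  blob <- 80 * draw_disk(64, 64, 32, 32, 6)
  img <- pmax(grad - blob, 0)
  seq <- image_sequence(array(img, c(1, 1, 64, 64)), g)
  pp <- matrix(preprocess_for_tracking(seq)$data[1, 1, , ], 64, 64)
  peak <- max(pp[24:40, 24:40])
  residual <- max(pp[8:18, 44:60]) # off-blob background region
  expect_gt(peak, 0)
  expect_lt(residual, 0.05 * peak)
})

test_that("spot detection is sub-pixel accurate on rendered blobs", {
  g <- voxel_geometry()
  truth <- data.frame(x_um = c(5.2, 15.7, 25.3, 8.9, 20.1),
                      y_um = c(6.1, 9.4, 22.8, 25.6, 16.3))
  img <- matrix(0, 128, 128)
  for (i in 1:5)
    img <- img + 100 * draw_disk(128, 128, truth$y_um[i] / g$dy,
                                 truth$x_um[i] / g$dx, 8)
  set.seed(3)
  img <- pmax(img + matrix(rnorm(128^2, 0, 6), 128, 128), 0)
  sp <- detect_spots(img, g, diameter_um = 4)
  expect_equal(nrow(sp), 5)
  for (i in 1:5) {
    d <- min(sqrt((sp$x_um - truth$x_um[i])^2 + (sp$y_um - truth$y_um[i])^2))
    expect_lt(d, 0.5)
  }
  expect_equal(nrow(detect_spots(matrix(0, 64, 64), g)), 0)
  expect_equal(nrow(detect_spots(img, g, quality_threshold = Inf)), 0)
})

test_that("LAP linking builds, splits and gates tracks", {
  frames <- lapply(0:4, function(f)
    data.frame(x_um = c(0 + f, 30 + f), y_um = c(0, 0)))
  tr <- link_spots_lap(frames, max_link_um = 5)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(as.integer(table(tr$track_id)), c(5, 5))
  # a jump beyond the gate splits the track
  frames2 <- list(data.frame(x_um = 0, y_um = 0),
                  data.frame(x_um = 1, y_um = 0),
                  data.frame(x_um = 20, y_um = 0))
  tr2 <- link_spots_lap(frames2, max_link_um = 5)
  expect_equal(length(unique(tr2$track_id)), 2)
  expect_error(link_spots_lap(frames, max_link_um = -1), "positive")
  # single-frame gap closing rejoins interrupted tracks
  frames3 <- list(data.frame(x_um = 0, y_um = 0),
                  data.frame(x_um = numeric(0), y_um = numeric(0)),
                  data.frame(x_um = 1.5, y_um = 0))
  tr3a <- link_spots_lap(frames3, max_link_um = 5, allow_gap = 0)
  tr3b <- link_spots_lap(frames3, max_link_um = 5, allow_gap = 1)
  expect_equal(length(unique(tr3a$track_id)), 2)
  expect_equal(length(unique(tr3b$track_id)), 1)
})

test_that("LAP links equal brute-force optimal assignment", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:7, 1); m <- sample(1:7, 1)
    a <- data.frame(x_um = runif(n, 0, 20), y_um = runif(n, 0, 20))
    b <- data.frame(x_um = runif(m, 0, 20), y_um = runif(m, 0, 20))
    max_link <- runif(1, 3, 12)
    lap <- somitedyn:::link_frame_pair(a, b, max_link)
    bf <- brute_force_links(a, b, max_link)
    expect_equal(link_cost(a, b, lap, max_link), bf$cost, tolerance = 1e-9)
    expect_identical(lap, bf$links)
  }
})

test_that("track metrics use circular means and physical units", {
  tr <- data.frame(frame = 0:3, x_um = c(0, 4, 8, 12), y_um = 0)
  m <- track_metrics(tr, dt_min = 20)
  expect_equal(m$theta_deg, 0)
  expect_equal(m$mean_speed_um_per_min, 0.2)
  expect_equal(m$net_displacement_um, 12)
  expect_equal(m$path_length_um, 12)
  # +45 then -45 degree steps of equal length average to 0
  tr2 <- data.frame(frame = 0:2, x_um = c(0, 1, 2), y_um = c(0, 1, 0))
  expect_equal(track_metrics(tr2, 20)$theta_deg, 0, tolerance = 1e-9)
  # wrap-around: headings 359 and 1 degree average to 0, not 180
  tr3 <- data.frame(frame = 0:2,
                    x_um = c(0, cos(-pi / 180), cos(-pi / 180) + cos(pi / 180)),
                    y_um = c(0, sin(-pi / 180), sin(-pi / 180) + sin(pi / 180)))
  expect_equal(track_metrics(tr3, 20)$theta_deg, 0, tolerance = 1e-6)
  expect_error(track_metrics(tr[1, , drop = FALSE], 20), "2 spots")
})

test_that("directionality index behaves like the mean resultant length", {
  many <- rep(37, 25)
  di <- directionality_index(many)
  expect_equal(di$R, 1)
  expect_equal(di$mean_angle_deg, 37)
  expect_equal(directionality_index(c(0, 180))$R, 0, tolerance = 1e-12)
  # E[R] under uniform angles ~ 0.886 / sqrt(N)
  set.seed(11)
  Rs <- replicate(1000, directionality_index(runif(100, -180, 180))$R)
  expect_lt(abs(mean(Rs) - 0.886 / sqrt(100)), 0.01)
  expect_error(directionality_index(numeric(0)), "no valid tracks")
})

test_that("angle histograms are half-open, complete and uniform under the null", {
  h <- angle_distribution(rep(0.001, 9), n_bins = 16)
  expect_equal(sum(h$count), 9)
  expect_equal(sum(h$count > 0), 1)
  expect_error(angle_distribution(c(0, 10), n_bins = 1), "at least 2")
  set.seed(13)
  h2 <- angle_distribution(runif(8000, -180, 180), n_bins = 16)
  expect_equal(sum(h2$count), 8000)
  expect_gt(stats::chisq.test(h2$count)$p.value, 0.01)
  # boundary angle +180 lands in the last bin
  h3 <- angle_distribution(c(180, -179.9), n_bins = 4)
  expect_equal(sum(h3$count), 2)
})

test_that("directed motion is distinguished from matched random motion", {
  run_stage <- function(seed, mode, drift) {
    cfg <- quick_config(seed = seed, n_cells = 40, domain = c(110, 110, 0.5),
                        mode = mode, mean_speed = 0.21, speed_sd = 0.11,
                        sink = if (mode == "directed") c(165, 165) else NULL,
                        drift_weight = drift, radius = 3.5)
    sim <- simulate_somite_movie(cfg, n_frames = 7)
    track_movie(sim$seq, diameter_um = 7, max_link_um = 12)
  }
  null_R <- vapply(1:8, function(s) run_stage(s, "random", 0)$directionality$R,
                   numeric(1))
  dir_res <- run_stage(100, "directed", 0.7)
  expect_gt(dir_res$directionality$R, stats::quantile(null_R, 0.95))
  # recovered mean direction points at the sink (45 degrees) within 15
  expect_lt(abs(somitedyn:::wrap_angle(dir_res$directionality$mean_angle_deg - 45)),
            15)
  # speed recovery within 10% of the generator mean speed
  expect_equal(dir_res$mean_speed_um_per_min, 0.21, tolerance = 0.1)
})
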