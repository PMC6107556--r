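test_that("circularity formula matches analytic shapes", {
  a <- 7.3
  expect_equal(circularity(a^2, 4 * a), pi / 4)
  expect_equal(circularity(pi * 4^2, 2 * pi * 4), 1)
  # 4:1 ellipse via the Ramanujan perimeter approximation
  b <- 3; A <- pi * 4 * b * b
  P <- pi * (3 * (4 * b + b) - sqrt((3 * 4 * b + b) * (4 * b + 3 * b)))
  expect_lt(circularity(A, P), 0.6)
  expect_error(circularity(0, 1), "degenerate")
  # discretization overshoot is clipped to 1
  expect_equal(circularity(100, sqrt(4 * pi * 100) * 0.99), 1)
})

test_that("round-object detector applies the diameter and circularity gates", {
  g <- voxel_geometry()
  px <- function(um) um / g$dx
  frame <- draw_disk(160, 160, 80, 80, px(7)) * 100 # 14 um disk
  set.seed(1)
  noisy <- frame + matrix(rnorm(160^2, 0, 5), 160, 160)
  det <- detect_round_objects(pmax(noisy, 0), g)
  expect_equal(nrow(det), 1)
  expect_equal(det$d_um, 14, tolerance = 0.05)
  expect_gte(det$circ, 0.95)
  expect_lt(sqrt((det$x_um - 20)^2 + (det$y_um - 20)^2), 1)
  # 8 um disk fails the 12 um minimum
  small <- draw_disk(160, 160, 80, 80, px(4)) * 100
  expect_equal(nrow(detect_round_objects(small, g)), 0)
  # 14 um (minor-axis-matched area) 4:1 ellipse fails the circularity gate
  ell <- draw_ellipse(200, 200, 100, 100, px(14), px(3.5)) * 100
  expect_equal(nrow(detect_round_objects(ell, g)), 0)
  # but it is large enough that only circularity rejected it
  loose <- detect_round_objects(ell, g, circularity_min = 0)
  expect_equal(nrow(loose), 1)
  expect_gte(loose$d_um, 12)
})

test_that("event deduplication merges rounding phases and respects gaps", {
  det <- data.frame(frame = c(3, 4), x_um = c(10, 11), y_um = c(20, 20),
                    area_um2 = c(150, 140))
  ev <- deduplicate_events(det, link_radius_um = 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, 3)
  expect_equal(ev$n_detections, 2)
  # two distant disks in the same frame stay distinct
  det2 <- data.frame(frame = c(2, 2), x_um = c(0, 50), y_um = c(0, 0))
  expect_equal(nrow(deduplicate_events(det2, 5)), 2)
  # a 2-frame gap exceeds max_gap_frames = 1
  det3 <- data.frame(frame = c(3, 6), x_um = c(10, 10), y_um = c(10, 10))
  expect_equal(nrow(deduplicate_events(det3, 5, max_gap_frames = 1)), 2)
  # three consecutive detections exceed one 25-min phase: second event opens
  det4 <- data.frame(frame = 1:3, x_um = rep(5, 3), y_um = rep(5, 3))
  expect_equal(nrow(deduplicate_events(det4, 5)), 2)
  expect_equal(nrow(deduplicate_events(det4[0, ], 5)), 0)
})

test_that("proliferation rate converts event counts per observation window", {
  expect_equal(proliferation_rate(9, 180), 3)
  expect_equal(proliferation_rate(data.frame(onset_frame = integer(0)), 120), 0)
  expect_error(proliferation_rate(1, 0), "positive")
})

test_that("the movie-level detector recovers the simulated division rate", {
  ests <- t(vapply(1:4, function(s) {
    cfg <- quick_config(seed = s, n_cells = 60, domain = c(96, 96, 0.5),
                        division_rate = 4.4)
    sim <- simulate_somite_movie(cfg, n_frames = 10)
    dv <- detect_divisions(sim$seq)
    c(est = dv$rate_per_hr, true = nrow(sim$truth$divisions) * 60 / 180)
  }, numeric(2)))
  # per-movie agreement: detected events track true events closely
  expect_lt(mean(abs(ests[, "est"] - ests[, "true"])), 0.5)
})
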