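test_that("image sequence TIFF round-trip is exact for 16-bit data", {
  d <- array(sample(0:65535, 2 * 4 * 12 * 10, TRUE), c(2, 4, 12, 10))
  s <- image_sequence(d, voxel_geometry())
  f <- withr::local_tempfile(fileext = ".tif")
  write_image_sequence(s, f)
  s2 <- read_image_sequence(f, n_z = 4)
  expect_identical(s2$data, d * 1.0)
  expect_equal(dim(s2$data), c(2, 4, 12, 10))
})

test_that("page count must divide by the declared z-depth", {
  m <- matrix(runif(16), 4, 4)
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(rep(list(m), 7), f, bits.per.sample = 16)
  expect_error(read_image_sequence(f, n_z = 4), "divisible")
  expect_silent(read_image_sequence(f, n_z = 7))
  expect_error(read_image_sequence(tempfile(), n_z = 1), "not found")
})

test_that("image sequence validates shape, sign and emptiness", {
  expect_error(image_sequence(array(-1, c(1, 1, 4, 4))), "non-negative")
  expect_error(image_sequence(array(NA_real_, c(1, 1, 4, 4))))
  expect_error(write_image_sequence(
    image_sequence(array(70000, c(1, 1, 2, 2))), tempfile()), "16-bit")
  # 3D input promoted to single-slice 4D
  s <- image_sequence(array(0, c(3, 5, 5)))
  expect_equal(dim(s$data), c(3, 1, 5, 5))
  expect_equal(n_frames(s), 3)
})

test_that("track tables round-trip and reject invariant violations", {
  tt <- data.frame(track_id = c(1, 1, 1, 2, 2), frame = c(0, 1, 2, 0, 1),
                   x_um = rnorm(5), y_um = rnorm(5), z_um = rnorm(5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tt, f)
  back <- read_tracks(f)
  expect_equal(length(unique(back$track_id)), 2)
  expect_equal(as.data.frame(back)[names(tt)], tt, tolerance = 1e-12)
  dup <- tt; dup$frame[2] <- 0
  expect_error(as_track_table(dup), "duplicate")
  dec <- tt; dec$frame[1:3] <- c(2, 1, 0)
  expect_error(as_track_table(dec), "increasing")
  expect_error(as_track_table(data.frame(track_id = 1, frame = 0, x_um = Inf,
                                         y_um = 0)), "finite")
})

test_that("ROI boxes are half-open, validated, and crop correctly", {
  expect_error(roi_box(5, 5, 0, 1, 0, 1), "x0<x1")
  roi <- roi_box(2, 6, 1, 4, 0, 3)
  fr <- array(seq_len(5 * 6 * 8), c(5, 6, 8)) # (z, y, x)
  cr <- crop_frame(fr, roi)
  expect_equal(dim(cr), c(3, 3, 4))
  expect_equal(cr[1, 1, 1], fr[1, 2, 3])
  expect_error(crop_frame(fr, roi_box(0, 9, 0, 1, 0, 1)), "fit")
  # physical box helper: the 32 x 41 x 20 um domain box at default voxels
  rb <- roi_from_um(c(0, 0, 0), c(32, 41, 20), voxel_geometry())
  expect_equal(c(rb$x1, rb$y1, rb$z1), c(128, 164, 39))
})

test_that("voxel geometry rejects non-positive calibration", {
  expect_error(voxel_geometry(dx = 0), "positive")
  expect_error(voxel_geometry(dt_min = -1), "positive")
  g <- voxel_geometry()
  expect_equal(c(g$dx, g$dy, g$dz, g$dt_min), c(0.25, 0.25, 0.51, 20))
})

test_that("configuration loading fills defaults and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines("", f)
  cfg <- load_config(f)
  expect_equal(cfg$detect$min_diameter_um, 12)
  expect_equal(cfg$detect$circularity_min, 0.85)
  expect_equal(cfg$division$duration_min, 25)
  writeLines("detect:\n  circularity_min: 1.5", f)
  expect_error(load_config(f), "circularity")
  writeLines("no_such_section: 3", f)
  expect_error(load_config(f), "unknown configuration key")
  writeLines("detect:\n  no_such_param: 3", f)
  expect_error(load_config(f), "detect.no_such_param")
  writeLines("tissue:\n  n_cells: 5\ndetect:\n  min_diameter_um: 10", f)
  cfg <- load_config(f)
  expect_equal(cfg$tissue$n_cells, 5)
  expect_equal(cfg$detect$min_diameter_um, 10)
  expect_equal(cfg$motion$mean_speed, 0.14) # untouched default
})
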