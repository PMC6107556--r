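#' Read a multi-page TIFF as a 4D image sequence
#'
#' Pages are interpreted as t-major (`t1z1, t1z2, ..., t2z1, ...` for
#' `page_order = "tz"`) or z-major (`page_order = "zt"`). Pixel values are
#' returned on the stored integer scale (a 16-bit file yields 0..65535), so
#' integer data written by [write_image_sequence()] round-trips exactly.
#'
#' @param path Path to a multi-page TIFF.
#' @param n_z Number of z-slices per time point; the page count must be an
#'   exact multiple.
#' @param geometry A [voxel_geometry()] to attach.
#' @param page_order `"tz"` (default) or `"zt"`.
#' @return An [image_sequence()].
#' @export
read_image_sequence <- function(path, n_z, geometry = voxel_geometry(),
                                page_order = c("tz", "zt")) {
  page_order <- match.arg(page_order)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  if (n_z < 1 || n_pages %% n_z != 0)
    stop(sprintf("page count (%d) is not divisible by z-depth (%d)", n_pages, n_z))
  n_t <- n_pages %/% n_z
  m1 <- pages[[1]]
  if (length(dim(m1)) == 3) pages <- lapply(pages, function(p) p[, , 1])
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, dim = c(n_t, n_z, ny, nx))
  for (p in seq_len(n_pages)) {
    if (page_order == "tz") {
      t <- (p - 1) %/% n_z + 1; z <- (p - 1) %% n_z + 1
    } else {
      z <- (p - 1) %/% n_t + 1; t <- (p - 1) %% n_t + 1
    }
    data[t, z, , ] <- pages[[p]]
  }
  data <- data * 65535
  if (max(abs(data - round(data))) < 1e-6) data <- round(data)
  image_sequence(data, geometry)
}

#' Write an image sequence to a multi-page TIFF
#'
#' Pages are written t-major at 16 bits per sample. Intensities must lie in
#' `[0, 65535]`; integer values round-trip exactly through
#' [read_image_sequence()].
#'
#' @param seq An [image_sequence()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq$data)
  if (prod(d) == 0) stop("cannot write an empty image sequence")
  if (max(seq$data) > 65535)
    stop("intensities exceed the 16-bit range; rescale before writing")
  pages <- vector("list", d[1] * d[2])
  p <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    pages[[p]] <- matrix(seq$data[t, z, , ] / 65535, d[3], d[4])
    p <- p + 1L
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16), silent = TRUE)
  if (inherits(ok, "try-error")) stop("could not write TIFF to ", path)
  invisible(path)
}

#' Read a track table from CSV
#'
#' Expects a header `track_id,frame,x_um,y_um` with optional `z_um`.
#' Invariant violations (duplicate frames within a track, non-monotone
#' frames) are rejected.
#'
#' @param path CSV path.
#' @return A validated track table (see [as_track_table()]).
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  as_track_table(df)
}

#' Write a track table to CSV
#' @param table A track table.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tracks <- function(table, path) {
  table <- as_track_table(as.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the simulator and analysis pipeline with their
#' defaults: acquisition geometry, tissue/motion/division/growth models for
#' the synthetic generator, rendering, division-detection gates (12 um
#' minimum diameter, 0.85 circularity) and tracking parameters.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    geometry = list(dx = 0.25, dy = 0.25, dz = 0.51, dt_min = 20),
    tissue = list(n_cells = 212L, domain_um = c(32, 41, 20),
                  radius_mean_um = 1.5, radius_sd_um = 0.15,
                  radius_mean2_um = NULL, fraction2 = 0,
                  max_overlap = 0.1),
    motion = list(mode = "random", mean_speed = 0.14, speed_sd = 0.08,
                  sink = NULL, drift_weight = 0),
    division = list(rate_per_hr = 1.7, duration_min = 25,
                    rounded_diameter_um = 14),
    growth = list(rate_um3_per_hr = 19, proliferation_fraction = 0.5),
    render = list(psf_sigma_um = 0.3, shell_um = 0.5, peak = 100, snr = 10),
    detect = list(min_diameter_um = 12, circularity_min = 0.85,
                  link_radius_um = 5, max_gap_frames = 1),
    tracking = list(spot_diameter_um = 8, max_link_um = 5,
                    rolling_ball_px = 20, min_track_spots = 3)
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(base)) stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && !is.null(base[[key]])) {
      if (!is.list(user[[key]])) stop("expected a section for key: ", full)
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[key] <- user[key]
    }
  }
  base
}

validate_config <- function(cfg) {
  g <- cfg$geometry
  if (any(unlist(g) <= 0)) stop("geometry values must be positive")
  if (!is.null(cfg$detect$circularity_min) &&
      (cfg$detect$circularity_min < 0 || cfg$detect$circularity_min > 1))
    stop("circularity_min must lie in [0, 1]")
  if (cfg$detect$min_diameter_um <= 0) stop("min_diameter_um must be positive")
  if (cfg$motion$drift_weight < 0 || cfg$motion$drift_weight > 1)
    stop("drift_weight must lie in [0, 1]")
  if (cfg$motion$mean_speed < 0) stop("mean_speed must be non-negative")
  if (!cfg$motion$mode %in% c("random", "directed", "inward"))
    stop("motion mode must be one of random, directed, inward")
  if (cfg$motion$mode == "directed" && is.null(cfg$motion$sink))
    stop("directed motion requires a sink")
  if (cfg$division$rate_per_hr < 0) stop("division rate must be non-negative")
  if (cfg$tissue$n_cells < 0) stop("n_cells must be non-negative")
  invisible(cfg)
}

#' Load a YAML pipeline configuration
#'
#' Reads a (possibly empty) YAML file, fills every missing key from
#' [default_config()], rejects unknown keys and range violations, and returns
#' the complete parameter set.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return The merged, validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("malformed configuration file")
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}
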