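#' Voxel geometry of an image sequence
#'
#' Physical calibration of a 3D+t acquisition: in-plane pixel size, z-step and
#' frame interval. Defaults match two-photon somite imaging at 20x (250 nm
#' in-plane pixels, 510 nm z-steps, frames every 20 minutes).
#'
#' @param dx,dy Pixel size in x and y, micrometres.
#' @param dz Z-step, micrometres.
#' @param dt_min Frame interval, minutes.
#' @return An object of class `voxel_geometry`.
#' @export
#' @examples
#' voxel_geometry()
voxel_geometry <- function(dx = 0.25, dy = 0.25, dz = 0.51, dt_min = 20) {
  vals <- c(dx = dx, dy = dy, dz = dz, dt_min = dt_min)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all voxel geometry fields must be finite and strictly positive")
  structure(list(dx = dx, dy = dy, dz = dz, dt_min = dt_min),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> dx=%g dy=%g dz=%g um, dt=%g min\n",
              x$dx, x$dy, x$dz, x$dt_min))
  invisible(x)
}

#' 4D image sequence
#'
#' Container for a time series of 3D intensity stacks with its physical
#' calibration. Axis order is fixed as `(t, z, y, x)`; a single frame is the
#' `(z, y, x)` array `seq$data[t, , , ]` and a slice is a `(y, x)` matrix.
#'
#' @param data 4D non-negative finite numeric array ordered `(t, z, y, x)`.
#'   3D input is promoted to a single-slice sequence `(t, 1, y, x)`.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `image_sequence` with elements `data` and
#'   `geometry`.
#' @export
image_sequence <- function(data, geometry = voxel_geometry()) {
  if (length(dim(data)) == 3L) {
    # (t, y, x) single-slice movie
    data <- array(data, dim = c(dim(data)[1], 1L, dim(data)[2], dim(data)[3]))
  }
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array ordered (t, z, y, x)")
  if (dim(data)[1] < 1L) stop("image sequence needs at least one frame")
  if (!all(is.finite(data)) || any(data < 0))
    stop("intensities must be finite and non-negative")
  stopifnot(inherits(geometry, "voxel_geometry"))
  structure(list(data = data, geometry = geometry), class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_sequence> %d frame(s), %d z x %d y x %d x voxels\n",
              d[1], d[2], d[3], d[4]))
  print(x$geometry)
  invisible(x)
}

#' Number of frames in an image sequence
#' @param seq An [image_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "image_sequence"))
  dim(seq$data)[1]
}

#' Extract one 3D frame from an image sequence
#' @param seq An [image_sequence()].
#' @param t 1-based frame index.
#' @return A `(z, y, x)` numeric array.
#' @export
get_frame <- function(seq, t) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq$data)
  if (t < 1 || t > d[1]) stop("frame index out of range")
  array(seq$data[t, , , ], dim = d[2:4])
}

#' Rectangular region of interest in voxel coordinates
#'
#' Indices are 0-based and half-open (`x0 <= x < x1`), so `x1 - x0` is the
#' width in voxels. Use [roi_from_um()] for a box given in micrometres.
#'
#' @param x0,x1,y0,y1,z0,z1 Integer voxel bounds, 0-based, half-open.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(x0, x1, y0, y1, z0, z1) {
  v <- c(x0, x1, y0, y1, z0, z1)
  if (any(v != round(v)) || any(v < 0)) stop("ROI bounds must be non-negative integers")
  if (!(x0 < x1 && y0 < y1 && z0 < z1)) stop("ROI must satisfy x0<x1, y0<y1, z0<z1")
  structure(list(x0 = x0, x1 = x1, y0 = y0, y1 = y1, z0 = z0, z1 = z1),
            class = "roi_box")
}

#' Build an ROI box from physical coordinates
#'
#' @param origin_um Length-3 numeric `(x, y, z)` origin in micrometres.
#' @param size_um Length-3 numeric box size in micrometres. The domain-box
#'   default (32 x 41 x 20 um) is the fixed medial/lateral analysis window.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `roi_box`.
#' @export
roi_from_um <- function(origin_um = c(0, 0, 0), size_um = c(32, 41, 20),
                        geometry = voxel_geometry()) {
  px <- c(geometry$dx, geometry$dy, geometry$dz)
  o <- round(origin_um / px)
  s <- pmax(1, round(size_um / px))
  roi_box(o[1], o[1] + s[1], o[2], o[2] + s[2], o[3], o[3] + s[3])
}

#' Crop a 3D frame to an ROI box
#' @param frame A `(z, y, x)` array.
#' @param roi An [roi_box()].
#' @return The cropped `(z, y, x)` array.
#' @export
crop_frame <- function(frame, roi) {
  stopifnot(inherits(roi, "roi_box"), length(dim(frame)) == 3L)
  d <- dim(frame) # (z, y, x)
  if (roi$z1 > d[1] || roi$y1 > d[2] || roi$x1 > d[3])
    stop("ROI does not fit inside the image")
  frame[(roi$z0 + 1):roi$z1, (roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1,
        drop = FALSE]
}

#' Validate a track table
#'
#' A track table is a data frame with columns `track_id`, `frame`, `x_um`,
#' `y_um` and optionally `z_um`: the per-frame position of each tracked cell.
#' Within a track, frame indices must be strictly increasing.
#'
#' @param df A data frame.
#' @return The validated data frame, classed `track_table`.
#' @export
as_track_table <- function(df) {
  req <- c("track_id", "frame", "x_um", "y_um")
  if (!all(req %in% names(df)))
    stop("track table needs columns track_id, frame, x_um, y_um")
  num_cols <- intersect(c("frame", "x_um", "y_um", "z_um"), names(df))
  for (cl in num_cols)
    if (nrow(df) > 0 && !all(is.finite(df[[cl]])))
      stop("track table positions and frames must be finite")
  if (nrow(df) > 0) {
    by_track <- split(df$frame, df$track_id)
    if (any(vapply(by_track, anyDuplicated, integer(1)) > 0))
      stop("duplicate (track_id, frame) pair")
    if (any(vapply(by_track, function(f) any(diff(f) <= 0), logical(1))))
      stop("frame indices must be strictly increasing within a track")
  }
  class(df) <- unique(c("track_table", class(df)))
  df
}

#' Volume time series for a somite or somitocoel
#'
#' @param times_min Strictly increasing times in minutes (length >= 2).
#' @param volumes_um3 Positive volumes in cubic micrometres.
#' @param label `"somite"` or `"somitocoel"`.
#' @return An object of class `volume_time_series`.
#' @export
volume_time_series <- function(times_min, volumes_um3,
                               label = c("somite", "somitocoel")) {
  label <- match.arg(label)
  if (length(times_min) != length(volumes_um3) || length(times_min) < 2)
    stop("need matched times and volumes of length >= 2")
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  if (any(volumes_um3 <= 0) || !all(is.finite(volumes_um3)))
    stop("volumes must be positive and finite")
  structure(list(times_min = times_min, volumes_um3 = volumes_um3, label = label),
            class = "volume_time_series")
}
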