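#' Preprocess a movie for spot tracking
#'
#' Replicates the standard tracking preparation for membrane images: invert
#' intensities (dark cell interiors become bright blobs), band-pass with a
#' difference of Gaussians, then subtract the background estimated by a
#' morphological rolling ball (grey-scale opening with a disc of the given
#' radius). Output intensities are clamped to be non-negative.
#'
#' @param seq An [image_sequence()] with a single z-slice (or a `(t, y, x)`
#'   array).
#' @param rolling_ball_radius_px Rolling-ball radius in pixels (> 0).
#' @param band_sigma_px Length-2 `(low, high)` Gaussian sigmas of the
#'   band-pass, pixels.
#' @param invert Invert intensities first (default `TRUE`).
#' @return An [image_sequence()] of the same shape.
#' @export
preprocess_for_tracking <- function(seq, rolling_ball_radius_px = 20,
                                    band_sigma_px = c(1, 10), invert = TRUE) {
  if (!inherits(seq, "image_sequence")) seq <- image_sequence(seq)
  if (rolling_ball_radius_px <= 0) stop("rolling-ball radius must be positive")
  d <- dim(seq$data)
  if (d[2] != 1) stop("tracking preprocessing expects a single-slice sequence")
  brush <- EBImage::makeBrush(2 * round(rolling_ball_radius_px) + 1, "disc")
  out <- array(0, d)
  gmax <- max(seq$data)
  for (t in seq_len(d[1])) {
    img <- matrix(seq$data[t, 1, , ], d[3], d[4])
    if (invert) img <- gmax - img
    lo <- blur2d(img, band_sigma_px[1])
    hi <- blur2d(img, band_sigma_px[2])
    img <- pmax(lo - hi, 0)
    bg <- EBImage::opening(img, brush)
    out[t, 1, , ] <- pmax(img - bg, 0)
  }
  image_sequence(out, seq$geometry)
}

# Laplacian-of-Gaussian (DoG-approximated) blob response, positive at bright
# blob centres of the given scale.
log_response <- function(img, sigma_px) {
  s1 <- sigma_px; s2 <- 1.6 * sigma_px
  (blur2d(img, s1) - blur2d(img, s2)) / (1 - 1 / 1.6^2)
}

#' Detect spots in one frame
#'
#' Laplacian-of-Gaussian blob detection at the scale of the expected cell
#' diameter (`sigma = d / (2 * sqrt(2))`), keeping 8-neighbourhood local
#' maxima above a quality threshold, with sub-pixel centroid refinement by a
#' 1D quadratic fit per axis. Quality is the filter response at the maximum.
#'
#' @param frame A `(y, x)` intensity matrix (preprocessed).
#' @param geometry A [voxel_geometry()].
#' @param diameter_um Expected spot diameter, micrometres.
#' @param quality_threshold Numeric threshold on the response, or `"auto"`
#'   (Otsu split of the local-maxima responses).
#' @return A data frame `x_um, y_um, quality` (possibly empty).
#' @export
detect_spots <- function(frame, geometry = voxel_geometry(), diameter_um = 8,
                         quality_threshold = "auto") {
  stopifnot(is.matrix(frame))
  sigma_px <- diameter_um / (2 * sqrt(2)) / geometry$dx
  resp <- log_response(frame, sigma_px)
  ny <- nrow(resp); nx <- ncol(resp)
  if (ny < 3 || nx < 3) return(data.frame(x_um = numeric(0), y_um = numeric(0),
                                          quality = numeric(0)))
  core <- resp[2:(ny - 1), 2:(nx - 1)]
  ismax <- core > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & (core >= resp[2:(ny - 1) + dr, 2:(nx - 1) + dc])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0), quality = numeric(0)))
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
  q <- resp[cbind(rows, cols)]
  # auto threshold splits noise from spot maxima on the log response scale,
  # which is robust to a few very bright objects (e.g. mitotic disks)
  thr <- if (identical(quality_threshold, "auto")) {
    if (length(q) > 2 && stats::sd(log(q)) > 0)
      max(exp(otsu_threshold(log(q))), 0.02 * max(q)) # 2% floor prunes stragglers
    else max(q) / 2
  } else quality_threshold
  keep <- q > thr
  rows <- rows[keep]; cols <- cols[keep]; q <- q[keep]
  if (!length(rows))
    return(data.frame(x_um = numeric(0), y_um = numeric(0), quality = numeric(0)))
  # non-maximum suppression: one spot per expected radius
  ord <- order(-q)
  rows <- rows[ord]; cols <- cols[ord]; q <- q[ord]
  min_d2 <- (diameter_um / 2 / geometry$dx)^2
  sel <- logical(length(rows))
  for (i in seq_along(rows)) {
    if (i == 1 || all(((rows[i] - rows[sel])^2 +
                       (cols[i] - cols[sel])^2) > min_d2)) sel[i] <- TRUE
  }
  rows <- rows[sel]; cols <- cols[sel]; q <- q[sel]
  # sub-pixel quadratic refinement along each axis
  sub_off <- function(fm1, f0, fp1) {
    den <- fm1 - 2 * f0 + fp1
    off <- ifelse(abs(den) > 1e-12, 0.5 * (fm1 - fp1) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  dr <- sub_off(resp[cbind(rows - 1, cols)], q, resp[cbind(rows + 1, cols)])
  dc <- sub_off(resp[cbind(rows, cols - 1)], q, resp[cbind(rows, cols + 1)])
  data.frame(x_um = (cols - 1 + dc + 0.5) * geometry$dx,
             y_um = (rows - 1 + dr + 0.5) * geometry$dy,
             quality = q)
}

#' Detect spots in every frame of a sequence
#'
#' @param seq A single-slice [image_sequence()] (typically the output of
#'   [preprocess_for_tracking()]).
#' @inheritParams detect_spots
#' @return A list of per-frame spot data frames.
#' @export
detect_spots_sequence <- function(seq, diameter_um = 8,
                                  quality_threshold = "auto") {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq$data)
  lapply(seq_len(d[1]), function(t)
    detect_spots(matrix(seq$data[t, 1, , ], d[3], d[4]), seq$geometry,
                 diameter_um, quality_threshold))
}

# Frame-to-frame LAP: returns an integer vector over spots of frame a giving
# the linked spot index in frame b (NA = no link). Cost = squared distance,
# non-link alternative cost = max_link^2; links beyond max_link forbidden.
link_frame_pair <- function(a, b, max_link_um) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  b2 <- max_link_um^2
  BIG <- 4 * b2 * (n + m) + 1
  D2 <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
  C <- matrix(BIG, n + m, n + m)
  link <- D2
  link[D2 > b2] <- BIG
  C[1:n, 1:m] <- link
  for (i in 1:n) C[i, m + i] <- b2
  for (j in 1:m) C[n + j, j] <- b2
  C[(n + 1):(n + m), (m + 1):(m + n)] <- 0
  asg <- cpp_lap_solve(C)
  out <- rep(NA_integer_, n)
  for (i in 1:n) if (asg[i] <= m && C[i, asg[i]] < BIG) out[i] <- asg[i]
  out
}

#' Link spots into tracks with a simple LAP tracker
#'
#' For each consecutive frame pair, solves the linear assignment problem over
#' squared inter-spot distances, with a non-link alternative cost of
#' `max_link_um^2` (links longer than `max_link_um` are forbidden). Unlinked
#' spots terminate or start tracks. Optional single-frame gap closing joins a
#' track end at frame `f` to a track start at frame `f + 2` within
#' `max_link_um` by a second assignment round. No merge or split costs.
#'
#' @param spots_by_frame List of per-frame spot data frames with columns
#'   `x_um, y_um` (frame 1 first).
#' @param max_link_um Maximum link distance, micrometres (> 0).
#' @param allow_gap 0 (default) or 1 missing frame to close over.
#' @return A track table with 0-based `frame` indices.
#' @export
link_spots_lap <- function(spots_by_frame, max_link_um = 5, allow_gap = 0) {
  if (max_link_um <= 0) stop("max link distance must be positive")
  nf <- length(spots_by_frame)
  tracks <- list() # each: data.frame(frame, x_um, y_um)
  open <- integer(0) # track index per spot of current frame
  for (f in seq_len(nf)) {
    sp <- spots_by_frame[[f]]
    n <- if (is.null(sp)) 0 else nrow(sp)
    if (f == 1) {
      open <- integer(n)
      for (i in seq_len(n)) {
        tracks[[length(tracks) + 1]] <-
          data.frame(frame = 0L, x_um = sp$x_um[i], y_um = sp$y_um[i])
        open[i] <- length(tracks)
      }
      prev <- sp
      next
    }
    lnk <- link_frame_pair(prev, sp, max_link_um)
    new_open <- rep(NA_integer_, n)
    for (i in seq_along(lnk)) {
      if (!is.na(lnk[i])) {
        tr <- open[i]
        tracks[[tr]] <- rbind(tracks[[tr]],
                              data.frame(frame = f - 1L,
                                         x_um = sp$x_um[lnk[i]],
                                         y_um = sp$y_um[lnk[i]]))
        new_open[lnk[i]] <- tr
      }
    }
    for (j in seq_len(n)) {
      if (is.na(new_open[j])) {
        tracks[[length(tracks) + 1]] <-
          data.frame(frame = f - 1L, x_um = sp$x_um[j], y_um = sp$y_um[j])
        new_open[j] <- length(tracks)
      }
    }
    open <- new_open
    prev <- sp
  }
  if (allow_gap >= 1 && length(tracks) > 1) tracks <- close_gaps(tracks, max_link_um)
  if (!length(tracks))
    return(as_track_table(data.frame(track_id = integer(0), frame = integer(0),
                                     x_um = numeric(0), y_um = numeric(0))))
  df <- do.call(rbind, lapply(seq_along(tracks), function(k)
    cbind(track_id = k, tracks[[k]])))
  df <- df[order(df$track_id, df$frame), ]
  rownames(df) <- NULL
  as_track_table(df)
}

# Join end(f) -> start(f+2) pairs within max_link by one greedy LAP round.
close_gaps <- function(tracks, max_link_um) {
  ends <- data.frame(k = seq_along(tracks),
                     frame = vapply(tracks, function(t) t$frame[nrow(t)], numeric(1)),
                     x = vapply(tracks, function(t) t$x_um[nrow(t)], numeric(1)),
                     y = vapply(tracks, function(t) t$y_um[nrow(t)], numeric(1)))
  starts <- data.frame(k = seq_along(tracks),
                       frame = vapply(tracks, function(t) t$frame[1], numeric(1)),
                       x = vapply(tracks, function(t) t$x_um[1], numeric(1)),
                       y = vapply(tracks, function(t) t$y_um[1], numeric(1)))
  merged_into <- rep(NA_integer_, length(tracks))
  repeat {
    cand <- NULL
    for (e in seq_len(nrow(ends))) {
      ke <- ends$k[e]
      if (!is.na(merged_into[ke])) next
      for (s in seq_len(nrow(starts))) {
        ks <- starts$k[s]
        if (ks == ke || !is.na(merged_into[ks])) next
        if (starts$frame[s] - ends$frame[e] != 2) next
        d <- sqrt((ends$x[e] - starts$x[s])^2 + (ends$y[e] - starts$y[s])^2)
        if (d <= max_link_um && (is.null(cand) || d < cand$d))
          cand <- list(e = e, s = s, d = d)
      }
    }
    if (is.null(cand)) break
    ke <- ends$k[cand$e]; ks <- starts$k[cand$s]
    tracks[[ke]] <- rbind(tracks[[ke]], tracks[[ks]])
    merged_into[ks] <- ke
    ends[cand$e, c("frame", "x", "y")] <- ends[match(ks, ends$k), c("frame", "x", "y")]
  }
  tracks[is.na(merged_into)]
}

#' Per-track motion metrics
#'
#' The mean direction is the circular mean of per-step heading angles
#' (degrees, counter-clockwise from +x in `(-180, 180]`); net displacement is
#' the first-to-last distance; path length the sum of step lengths; mean
#' speed the path length divided by elapsed time.
#'
#' @param track Data frame with columns `frame, x_um, y_um` (>= 2 rows).
#' @param dt_min Frame interval, minutes.
#' @return A list: `theta_deg`, `net_displacement_um`, `path_length_um`,
#'   `mean_speed_um_per_min`, `n_spots`.
#' @export
track_metrics <- function(track, dt_min = 20) {
  if (nrow(track) < 2) stop("track needs at least 2 spots")
  dx <- diff(track$x_um); dy <- diff(track$y_um)
  steps <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  ok <- steps > 0
  theta <- if (any(ok))
    wrap_angle(atan2(mean(sin(ang[ok])), mean(cos(ang[ok]))) * 180 / pi)
  else NA_real_
  total_min <- (track$frame[nrow(track)] - track$frame[1]) * dt_min
  list(theta_deg = theta,
       net_displacement_um = sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
                                  (track$y_um[nrow(track)] - track$y_um[1])^2),
       path_length_um = sum(steps),
       mean_speed_um_per_min = if (total_min > 0) sum(steps) / total_min
         else NA_real_,
       n_spots = nrow(track))
}

#' Metrics for every track in a track table
#'
#' @param tracks A track table (see [as_track_table()]).
#' @param dt_min Frame interval, minutes.
#' @return A data frame with one row per track: `track_id, theta_deg,
#'   net_displacement_um, path_length_um, mean_speed_um_per_min, n_spots`.
#' @export
all_track_metrics <- function(tracks, dt_min = 20) {
  tracks <- as_track_table(as.data.frame(tracks))
  parts <- split(tracks, tracks$track_id)
  parts <- parts[vapply(parts, nrow, integer(1)) >= 2]
  if (!length(parts))
    return(data.frame(track_id = integer(0), theta_deg = numeric(0),
                      net_displacement_um = numeric(0),
                      path_length_um = numeric(0),
                      mean_speed_um_per_min = numeric(0), n_spots = integer(0)))
  do.call(rbind, lapply(parts, function(tr) {
    m <- track_metrics(tr, dt_min)
    data.frame(track_id = tr$track_id[1], theta_deg = m$theta_deg,
               net_displacement_um = m$net_displacement_um,
               path_length_um = m$path_length_um,
               mean_speed_um_per_min = m$mean_speed_um_per_min,
               n_spots = m$n_spots)
  }))
}

#' Directionality index over a set of tracks
#'
#' Each track contributes the unit vector of its mean direction; the mean
#' resultant length `R = |sum of unit vectors| / N` is 1 when all tracks
#' share one direction and 0 when opposite directions cancel (for uniform
#' random angles `E[R]` is about `0.886 / sqrt(N)`). Tracks with fewer than
#' `min_spots` detections are excluded as noise.
#'
#' @param tracks A track table or a data frame of per-track metrics (from
#'   [all_track_metrics()]), or a numeric vector of angles in degrees.
#' @param dt_min Frame interval (used when `tracks` is a track table).
#' @param min_spots Minimum spots per track for inclusion (default 3).
#' @return A list: `R`, `mean_angle_deg`, `n_tracks`, `angles_deg`.
#' @export
directionality_index <- function(tracks, dt_min = 20, min_spots = 3) {
  if (is.numeric(tracks)) {
    angles <- tracks
  } else {
    met <- if (is.data.frame(tracks) && "theta_deg" %in% names(tracks)) tracks
      else all_track_metrics(tracks, dt_min)
    met <- met[!is.na(met$theta_deg) & met$n_spots >= min_spots, , drop = FALSE]
    angles <- met$theta_deg
  }
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("no valid tracks for directionality")
  a <- angles * pi / 180
  cx <- mean(cos(a)); cy <- mean(sin(a))
  list(R = sqrt(cx^2 + cy^2),
       mean_angle_deg = wrap_angle(atan2(cy, cx) * 180 / pi),
       n_tracks = length(angles),
       angles_deg = angles)
}

#' Radial histogram of track directions
#'
#' Counts per angular bin over `(-180, 180]` with half-open bins; counts sum
#' to the number of tracks.
#'
#' @param tracks As in [directionality_index()].
#' @param n_bins Number of angular bins (>= 2).
#' @param dt_min Frame interval.
#' @param min_spots Minimum spots per track.
#' @return A data frame `bin_lo_deg, bin_hi_deg, count`.
#' @export
angle_distribution <- function(tracks, n_bins = 16, dt_min = 20, min_spots = 3) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  di <- directionality_index(tracks, dt_min, min_spots)
  breaks <- seq(-180, 180, length.out = n_bins + 1)
  bin <- cut(di$angles_deg, breaks, right = TRUE, include.lowest = FALSE)
  counts <- as.integer(table(bin))
  data.frame(bin_lo_deg = breaks[-(n_bins + 1)], bin_hi_deg = breaks[-1],
             count = counts)
}

#' Full tracking pipeline on a movie
#'
#' Preprocess, detect spots, link with the simple LAP tracker and summarise:
#' the image-level counterpart of the tracking analysis.
#'
#' @param seq A single-slice [image_sequence()].
#' @param diameter_um Expected spot (cell interior) diameter, micrometres.
#' @param max_link_um Maximum link distance, micrometres.
#' @param rolling_ball_radius_px Background-subtraction radius, pixels.
#' @param quality_threshold Spot quality threshold (see [detect_spots()]).
#' @param min_spots Minimum spots per track for the statistics.
#' @param allow_gap Gap-closing frames (see [link_spots_lap()]).
#' @param slice_z 1-based z-slice to track in (tracking is in-plane); the
#'   default takes the central slice of multi-slice stacks.
#' @return A list: `tracks` (track table), `metrics` (per-track data frame),
#'   `directionality` (list), `mean_speed_um_per_min`.
#' @export
track_movie <- function(seq, diameter_um = 8, max_link_um = 5,
                        rolling_ball_radius_px = 20,
                        quality_threshold = "auto", min_spots = 3,
                        allow_gap = 0, slice_z = NULL) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq$data)
  if (d[2] > 1) {
    z <- if (is.null(slice_z)) max(1L, round(d[2] / 2)) else slice_z
    seq <- image_sequence(array(seq$data[, z, , ], c(d[1], 1L, d[3], d[4])),
                          seq$geometry)
  }
  pp <- preprocess_for_tracking(seq, rolling_ball_radius_px)
  spots <- detect_spots_sequence(pp, diameter_um, quality_threshold)
  tracks <- link_spots_lap(spots, max_link_um, allow_gap)
  met <- all_track_metrics(tracks, seq$geometry$dt_min)
  keep <- met[met$n_spots >= min_spots, , drop = FALSE]
  di <- if (nrow(keep) > 0) directionality_index(keep, min_spots = min_spots)
    else NULL
  list(tracks = tracks, metrics = met, directionality = di,
       mean_speed_um_per_min = if (nrow(keep) > 0)
         mean(keep$mean_speed_um_per_min) else NA_real_)
}
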