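#' Circularity shape descriptor
#'
#' `4 * pi * Area / Perimeter^2`: 1 for a perfect disk, `pi/4` for a square,
#' smaller for elongated shapes. Discretized regions can measure slightly
#' above 1; values up to 1.1 are clipped to 1.
#'
#' @param area Region area (any consistent unit).
#' @param perimeter Region perimeter (same length unit).
#' @return Circularity in `(0, 1]`.
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("degenerate region: area and perimeter must be positive")
  c <- 4 * pi * area / perimeter^2
  pmin(c, 1)
}

# Shape statistics (area, sub-pixel perimeter, centroid, equivalent diameter,
# circularity) for every region of a 2D label matrix, in physical units.
# Regions below area_min_px are skipped without measuring perimeters.
region_shape_stats <- function(lab, geometry, area_min_px = 0) {
  st <- label_stats_2d(lab)
  if (nrow(st) == 0)
    return(data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), d_um = numeric(0), circ = numeric(0)))
  st <- st[st$area_px >= area_min_px, , drop = FALSE]
  if (nrow(st) == 0)
    return(data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), d_um = numeric(0), circ = numeric(0)))
  out <- lapply(seq_len(nrow(st)), function(i) {
    l <- st$label[i]
    idx <- which(lab == l, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - 2L); r1 <- min(nrow(lab), max(idx[, 1]) + 2L)
    c0 <- max(1L, min(idx[, 2]) - 2L); c1 <- min(ncol(lab), max(idx[, 2]) + 2L)
    sub <- lab[r0:r1, c0:c1, drop = FALSE] == l
    p_px <- mask_perimeter_px(sub)
    area_um2 <- st$area_px[i] * geometry$dx * geometry$dy
    p_um <- p_px * geometry$dx
    data.frame(label = l,
               x_um = (st$col[i] - 0.5) * geometry$dx,
               y_um = (st$row[i] - 0.5) * geometry$dy,
               area_um2 = area_um2,
               d_um = 2 * sqrt(area_um2 / pi),
               circ = if (p_um > 0) circularity(area_um2, p_um) else NA_real_)
  })
  do.call(rbind, out)
}

#' Detect rounded (dividing) cells in a 3D frame
#'
#' Per z-slice: Gaussian denoise, Otsu threshold, binary opening and
#' connected-component labelling,
#' then a gate keeping regions with equivalent diameter at least
#' `min_diameter_um` and circularity at least `circularity_min` (defaults 12
#' um and 0.85). Rounded mitotic cells appear as large bright disks and pass
#' the gate; thin membrane outlines and noise do not.
#'
#' @param frame A `(z, y, x)` array or a `(y, x)` matrix.
#' @param geometry A [voxel_geometry()].
#' @param min_diameter_um Minimum equivalent diameter, micrometres.
#' @param circularity_min Minimum circularity in `[0, 1]`.
#' @param smooth_sigma_px Gaussian denoising sigma (pixels); 0 disables.
#' @param median_radius_px Optional median-filter radius (pixels), applied
#'   instead of the Gaussian when > 0 (slower).
#' @param opening_radius_px Radius of a binary opening applied to the
#'   thresholded mask before labelling; it detaches thin membrane outlines
#'   touching a mitotic disk (0 disables). The default erases structures
#'   thinner than about 2.5 um at 0.25 um pixels, far below the 12 um gate.
#' @return A data frame `z, x_um, y_um, d_um, circ, area_um2` (one row per
#'   detection; possibly empty).
#' @export
detect_round_objects <- function(frame, geometry = voxel_geometry(),
                                 min_diameter_um = 12, circularity_min = 0.85,
                                 smooth_sigma_px = 1, median_radius_px = 0,
                                 opening_radius_px = 5) {
  if (circularity_min < 0 || circularity_min > 1)
    stop("circularity_min must lie in [0, 1]")
  if (is.matrix(frame)) frame <- array(frame, c(1L, dim(frame)))
  d <- dim(frame)
  area_min_px <- pi * (min_diameter_um / 2)^2 / (geometry$dx * geometry$dy)
  brush <- if (opening_radius_px > 0)
    EBImage::makeBrush(2 * opening_radius_px + 1, "disc") else NULL
  res <- list()
  for (z in seq_len(d[1])) {
    slice <- normalize01(matrix(frame[z, , ], d[2], d[3]))
    if (max(slice) == 0) next
    if (median_radius_px > 0)
      slice <- EBImage::medianFilter(slice, median_radius_px)
    else if (smooth_sigma_px > 0)
      slice <- blur2d(slice, smooth_sigma_px)
    thr <- otsu_threshold(slice)
    mask <- slice > thr
    if (!is.null(brush)) mask <- EBImage::opening(mask, brush) > 0
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask)
    st <- region_shape_stats(lab, geometry, area_min_px = 0.8 * area_min_px)
    if (nrow(st) == 0) next
    keep <- !is.na(st$circ) & st$d_um >= min_diameter_um &
      st$circ >= circularity_min
    if (any(keep)) {
      st <- st[keep, c("x_um", "y_um", "d_um", "circ", "area_um2")]
      st$z <- z
      res[[length(res) + 1]] <- st
    }
  }
  if (!length(res))
    return(data.frame(z = integer(0), x_um = numeric(0), y_um = numeric(0),
                      d_um = numeric(0), circ = numeric(0),
                      area_um2 = numeric(0)))
  out <- do.call(rbind, res)
  out[, c("z", "x_um", "y_um", "d_um", "circ", "area_um2")]
}

# Merge detections of the same object across z within one frame: greedy
# clustering by xy distance; representative = largest area.
merge_within_frame <- function(det, link_radius_um) {
  if (nrow(det) <= 1) return(det)
  det <- det[order(-det$area_um2), ]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!keep[i]) next
    if (i < nrow(det)) {
      j <- (i + 1):nrow(det)
      d <- sqrt((det$x_um[j] - det$x_um[i])^2 + (det$y_um[j] - det$y_um[i])^2)
      keep[j][d <= link_radius_um] <- FALSE
    }
  }
  det[keep, , drop = FALSE]
}

#' Merge per-frame detections into division events
#'
#' A 25-minute rounding phase sampled at 20-minute intervals appears in one
#' or two consecutive frames, so detections within `link_radius_um` of each
#' other in nearby frames (at most `max_gap_frames` missing frames between
#' them) are merged into a single event. The onset frame and the detection of
#' largest area represent the event.
#'
#' @param detections Data frame with columns `frame, x_um, y_um` (and
#'   typically `d_um, circ, area_um2, z`), sorted or not.
#' @param link_radius_um Maximum displacement between supporting detections.
#' @param max_gap_frames Maximum number of missing frames inside one event.
#' @param max_event_frames Maximum frames one event may span: a 25-minute
#'   rounding phase covers at most 2 frames at 20-minute sampling, so a third
#'   consecutive detection at the same place is a new event.
#' @return A data frame of events: `onset_frame, x_um, y_um, n_detections`.
#' @export
deduplicate_events <- function(detections, link_radius_um = 5,
                               max_gap_frames = 1, max_event_frames = 2) {
  if (nrow(detections) == 0)
    return(data.frame(onset_frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), n_detections = integer(0)))
  det <- detections[order(detections$frame), ]
  events <- list() # each: list(last_frame, x, y, onset, n, area)
  for (i in seq_len(nrow(det))) {
    fr <- det$frame[i]; x <- det$x_um[i]; y <- det$y_um[i]
    area <- if ("area_um2" %in% names(det)) det$area_um2[i] else 1
    attached <- FALSE
    for (k in seq_along(events)) {
      ev <- events[[k]]
      gap <- fr - ev$last_frame - 1
      if (gap < 0 || gap > max_gap_frames) next
      if (fr == ev$last_frame) next # same-frame detections are distinct objects
      if (fr - ev$onset + 1 > max_event_frames) next
      if (sqrt((x - ev$x)^2 + (y - ev$y)^2) <= link_radius_um) {
        ev$last_frame <- fr
        ev$n <- ev$n + 1L
        if (area > ev$area) { ev$x <- x; ev$y <- y; ev$area <- area }
        events[[k]] <- ev
        attached <- TRUE
        break
      }
    }
    if (!attached)
      events[[length(events) + 1]] <- list(last_frame = fr, x = x, y = y,
                                           onset = as.integer(fr), n = 1L,
                                           area = area)
  }
  data.frame(onset_frame = vapply(events, `[[`, integer(1), "onset"),
             x_um = vapply(events, `[[`, numeric(1), "x"),
             y_um = vapply(events, `[[`, numeric(1), "y"),
             n_detections = vapply(events, `[[`, integer(1), "n"))
}

#' Proliferation rate from division events
#'
#' @param events Event data frame (see [deduplicate_events()]) or an event
#'   count.
#' @param duration_min Observation window, minutes (> 0).
#' @return Events per hour.
#' @export
proliferation_rate <- function(events, duration_min) {
  if (duration_min <= 0) stop("duration must be positive")
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n * 60 / duration_min
}

#' Detect division events across a whole movie
#'
#' Runs [detect_round_objects()] on every frame, merges duplicate detections
#' of one object across z-slices within a frame, then merges across frames
#' with [deduplicate_events()] and reports the proliferation rate.
#'
#' @param seq An [image_sequence()].
#' @param min_diameter_um,circularity_min Detection gates.
#' @param link_radius_um,max_gap_frames Event-merging parameters.
#' @return A list: `detections`, `events`, `rate_per_hr`, `duration_min`.
#' @export
detect_divisions <- function(seq, min_diameter_um = 12, circularity_min = 0.85,
                             link_radius_um = 5, max_gap_frames = 1) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq$data)
  dets <- list()
  for (t in seq_len(d[1])) {
    det <- detect_round_objects(get_frame(seq, t), seq$geometry,
                                min_diameter_um, circularity_min)
    if (nrow(det) > 0) {
      det <- merge_within_frame(det, link_radius_um)
      det$frame <- t - 1L
      dets[[length(dets) + 1]] <- det
    }
  }
  detections <- if (length(dets)) do.call(rbind, dets) else
    data.frame(frame = integer(0), z = integer(0), x_um = numeric(0),
               y_um = numeric(0), d_um = numeric(0), circ = numeric(0),
               area_um2 = numeric(0))
  events <- deduplicate_events(detections, link_radius_um, max_gap_frames)
  duration <- (d[1] - 1) * seq$geometry$dt_min
  list(detections = detections, events = events,
       rate_per_hr = if (duration > 0) proliferation_rate(events, duration)
         else NA_real_,
       duration_min = duration)
}
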