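#' Random sphere packing for a synthetic tissue block
#'
#' Places `n_cells` spheres uniformly in a rectangular domain by random
#' sequential addition, allowing at most `max_overlap` of the summed radii to
#' overlap (membranes of neighbouring cells may share a wall, as in packed
#' epithelium). Radii are drawn from a (optionally two-component) Gaussian,
#' truncated to stay positive; a second component models the discrete
#' population of larger cells seen in the medial domain.
#'
#' @param n_cells Number of cells.
#' @param domain_um Length-3 numeric domain size `(x, y, z)` in micrometres.
#' @param radius_mean_um,radius_sd_um Radius distribution, micrometres.
#' @param radius_mean2_um Optional mean of a second (larger) component.
#' @param fraction2 Fraction of cells drawn from the second component.
#' @param max_overlap Allowed overlap as a fraction of summed radii.
#' @param seed Optional RNG seed; identical seeds give identical packings.
#' @param max_tries Placement attempts per cell before giving up.
#' @return A data frame with columns `cell_id, x, y, z, r` (micrometres).
#' @export
generate_cell_packing <- function(n_cells, domain_um = c(32, 41, 20),
                                  radius_mean_um = 1.5, radius_sd_um = 0.15,
                                  radius_mean2_um = NULL, fraction2 = 0,
                                  max_overlap = 0.1, seed = NULL,
                                  max_tries = 2000L) {
  check_seed(seed)
  stopifnot(n_cells >= 0, length(domain_um) == 3, all(domain_um > 0))
  n2 <- if (!is.null(radius_mean2_um)) stats::rbinom(1, n_cells, fraction2) else 0L
  mus <- c(rep(radius_mean_um, n_cells - n2), rep(radius_mean2_um %||% 0, n2))
  mus <- sample(mus)
  radii <- abs(stats::rnorm(n_cells, mus, radius_sd_um))
  radii <- pmax(radii, 0.2)
  pos <- matrix(NA_real_, n_cells, 3)
  for (i in seq_len(n_cells)) {
    r <- radii[i]
    # axes thinner than one cell hold a monolayer: centre the cell there
    thin <- domain_um < 2 * r
    if (all(thin))
      stop("domain too small for requested cell radii")
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- ifelse(thin, domain_um / 2,
                  stats::runif(3, min = pmin(r, domain_um / 2),
                               max = pmax(domain_um - r, domain_um / 2)))
      if (i == 1) { ok <- TRUE } else {
        prev <- pos[seq_len(i - 1), , drop = FALSE]
        dmin2 <- ((radii[seq_len(i - 1)] + r) * (1 - max_overlap))^2
        d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 + (prev[, 3] - p[3])^2
        ok <- all(d2 >= dmin2)
      }
      if (ok) { pos[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed)
      stop("packing infeasible: could not place cell ", i, " after ",
           max_tries, " tries")
  }
  data.frame(cell_id = seq_len(n_cells),
             x = pos[, 1], y = pos[, 2], z = pos[, 3], r = radii)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One motion step for all cells: truncated-normal step length, direction per
# model. Positions are reflected at the domain boundary.
motion_step <- function(pos, motion, dt_min, domain_um) {
  n <- nrow(pos)
  mu <- motion$mean_speed * dt_min
  sd <- motion$speed_sd * dt_min
  len <- stats::rnorm(n, mu, sd)
  while (any(len < 0)) {
    k <- len < 0
    len[k] <- stats::rnorm(sum(k), mu, sd)
  }
  phi <- stats::runif(n, -pi, pi)
  ur <- cbind(cos(phi), sin(phi))
  w <- switch(motion$mode, random = 0, directed = motion$drift_weight,
              inward = motion$drift_weight)
  if (w > 0) {
    sink <- if (motion$mode == "inward" || is.null(motion$sink))
      domain_um[1:2] / 2 else motion$sink
    to_sink <- cbind(sink[1] - pos[, 1], sink[2] - pos[, 2])
    nrm <- sqrt(rowSums(to_sink^2))
    nrm[nrm == 0] <- 1
    us <- to_sink / nrm
    v <- w * us + (1 - w) * ur
    vn <- sqrt(rowSums(v^2))
    # if drift and noise cancel exactly, keep the random direction
    zero <- vn < 1e-12
    v[zero, ] <- ur[zero, , drop = FALSE]
    vn[zero] <- 1
    u <- v / vn
  } else {
    u <- ur
  }
  newp <- pos
  newp[, 1] <- pos[, 1] + len * u[, 1]
  newp[, 2] <- pos[, 2] + len * u[, 2]
  for (j in 1:2) { # reflect at [0, L]
    L <- domain_um[j]
    x <- newp[, j] %% (2 * L)
    x <- ifelse(x > L, 2 * L - x, x)
    newp[, j] <- x
  }
  newp
}

#' Simulate cell motion over a movie
#'
#' Steps every cell of a packing through `n_frames - 1` intervals. Step
#' lengths are truncated-normal with mean `mean_speed * dt` and SD
#' `speed_sd * dt`; directions are uniform (`random`), a renormalised blend
#' of a unit vector to a sink and a uniform unit vector (`directed`,
#' weighted by `drift_weight`), or directed at the domain centre (`inward`).
#' Motion is in the dorsal xy-plane; z stays fixed.
#'
#' @param packing Output of [generate_cell_packing()].
#' @param motion Motion model list: `mode`, `mean_speed` (um/min),
#'   `speed_sd`, `sink` (xy in um), `drift_weight`.
#' @param n_frames Number of frames (>= 2).
#' @param geometry A [voxel_geometry()] (supplies the frame interval).
#' @param domain_um Length-3 domain size in micrometres.
#' @param seed Optional RNG seed.
#' @return A track table with one track per cell and `n_frames` rows each
#'   (columns `track_id, frame, x_um, y_um, z_um`), frames 0-based.
#' @export
simulate_motion <- function(packing, motion, n_frames,
                            geometry = voxel_geometry(),
                            domain_um = c(32, 41, 20), seed = NULL) {
  check_seed(seed)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (motion$mean_speed < 0) stop("mean_speed must be non-negative")
  if (motion$mode == "directed" && is.null(motion$sink))
    stop("directed motion requires a sink")
  pos <- as.matrix(packing[, c("x", "y")])
  out <- vector("list", n_frames)
  out[[1]] <- data.frame(track_id = packing$cell_id, frame = 0L,
                         x_um = pos[, 1], y_um = pos[, 2], z_um = packing$z)
  for (f in seq_len(n_frames - 1)) {
    pos <- motion_step(pos, motion, geometry$dt_min, domain_um)
    out[[f + 1]] <- data.frame(track_id = packing$cell_id, frame = f,
                               x_um = pos[, 1], y_um = pos[, 2],
                               z_um = packing$z)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$track_id, df$frame), ]
  rownames(df) <- NULL
  as_track_table(df)
}

#' Simulate a division schedule
#'
#' Division events follow a homogeneous Poisson process at `rate_per_hr` over
#' the movie duration. Each event marks one cell as rounded (bright, enlarged)
#' for `duration_min`, after which it is replaced by two daughters of half
#' its volume.
#'
#' @param packing Output of [generate_cell_packing()].
#' @param rate_per_hr Expected division events per hour (>= 0).
#' @param t_total_min Movie duration in minutes.
#' @param duration_min Length of the rounded phase, minutes (default 25).
#' @param seed Optional RNG seed.
#' @return A data frame `cell_id, t_start_min, t_end_min` sorted by onset.
#' @export
simulate_divisions <- function(packing, rate_per_hr, t_total_min,
                               duration_min = 25, seed = NULL) {
  check_seed(seed)
  if (rate_per_hr < 0) stop("rate must be non-negative")
  n_ev <- stats::rpois(1, rate_per_hr * t_total_min / 60)
  n_ev <- min(n_ev, nrow(packing))
  if (n_ev == 0)
    return(data.frame(cell_id = integer(0), t_start_min = numeric(0),
                      t_end_min = numeric(0)))
  t0 <- sort(stats::runif(n_ev, 0, t_total_min))
  cells <- sample(packing$cell_id, n_ev)
  data.frame(cell_id = cells, t_start_min = t0, t_end_min = t0 + duration_min)
}

# Add one cell's footprint into a (z, y, x) intensity array, in place-ish.
# style "shell": bright membrane at radius r; "filled": solid bright ball
# with sub-voxel anti-aliased edge (rounded dividing cells).
add_cell_intensity <- function(img, cx, cy, cz, r, geometry, shell_um, style) {
  d <- dim(img) # (z, y, x)
  pad <- shell_um + 3 * geometry$dx
  zi <- which(abs((seq_len(d[1]) - 0.5) * geometry$dz - cz) <= r + pad + geometry$dz)
  yi <- which(abs((seq_len(d[2]) - 0.5) * geometry$dy - cy) <= r + pad)
  xi <- which(abs((seq_len(d[3]) - 0.5) * geometry$dx - cx) <= r + pad)
  if (!length(zi) || !length(yi) || !length(xi)) return(img)
  dz2 <- ((zi - 0.5) * geometry$dz - cz)^2
  dy2 <- ((yi - 0.5) * geometry$dy - cy)^2
  dx2 <- ((xi - 0.5) * geometry$dx - cx)^2
  nz <- length(zi); ny <- length(yi); nx <- length(xi)
  D <- sqrt(array(dz2, c(nz, ny, nx)) +
            array(rep(dy2, each = nz), c(nz, ny, nx)) +
            array(rep(dx2, each = nz * ny), c(nz, ny, nx)))
  if (style == "shell") {
    w <- shell_um / 2
    I <- exp(-(D - r)^2 / (2 * w^2))
  } else {
    h <- geometry$dx # anti-aliasing width ~ one in-plane voxel
    I <- pmin(1, pmax(0, 0.5 + (r - D) / h))
  }
  img[zi, yi, xi] <- pmax(img[zi, yi, xi], I)
  img
}

#' Render one synthetic membrane-labelled frame
#'
#' Draws each cell as a bright spherical membrane shell (Gaussian radial
#' profile of width `shell_um`) with a dark interior; rounded dividing cells
#' are drawn as filled bright balls. The frame is then blurred by an
#' isotropic Gaussian PSF and corrupted with Poisson shot noise plus Gaussian
#' read noise scaled to the requested peak SNR.
#'
#' @param cells Data frame with columns `x, y, z, r` (micrometres) and
#'   optionally logical `dividing`.
#' @param geometry A [voxel_geometry()].
#' @param domain_um Length-3 domain size, micrometres.
#' @param psf_sigma_um PSF standard deviation, micrometres (0 disables blur).
#' @param shell_um Membrane shell thickness, micrometres.
#' @param peak Photon count at full signal.
#' @param snr Peak signal-to-noise ratio; `NULL` or `Inf` disables noise.
#' @param seed Optional RNG seed (noise only).
#' @return A `(z, y, x)` numeric array of non-negative intensities.
#' @export
render_membrane_frame <- function(cells, geometry = voxel_geometry(),
                                  domain_um = c(32, 41, 20),
                                  psf_sigma_um = 0.3, shell_um = 0.5,
                                  peak = 100, snr = 10, seed = NULL) {
  check_seed(seed)
  d <- c(max(1L, round(domain_um[3] / geometry$dz)),
         round(domain_um[2] / geometry$dy),
         round(domain_um[1] / geometry$dx))
  img <- array(0, d)
  if (nrow(cells) > 0) {
    dividing <- if ("dividing" %in% names(cells)) cells$dividing else
      rep(FALSE, nrow(cells))
    for (i in seq_len(nrow(cells))) {
      img <- add_cell_intensity(img, cells$x[i], cells$y[i], cells$z[i],
                                cells$r[i], geometry, shell_um,
                                if (dividing[i]) "filled" else "shell")
    }
  }
  if (psf_sigma_um > 0)
    img <- blur3d(img, psf_sigma_um / geometry$dx, psf_sigma_um / geometry$dz)
  img <- pmax(img, 0) * peak # blur ringing can leave tiny negatives
  if (!is.null(snr) && is.finite(snr)) {
    sd_total <- peak / snr
    sd_read <- sqrt(max(sd_total^2 - peak, 0))
    img <- array(stats::rpois(length(img), img), dim(img)) +
      array(stats::rnorm(length(img), 0, sd_read), dim(img))
    img <- pmax(img, 0)
  }
  img
}

#' Simulate a complete ground-truthed somite movie
#'
#' Composes packing, motion, Poisson divisions and linear volume growth into
#' a rendered 4D membrane movie plus its ground truth. Total true cell volume
#' grows linearly at `growth$rate_um3_per_hr` (enforced by rescaling radii),
#' divisions conserve volume at the split, and daughters inherit the parent
#' track position with a small separation.
#'
#' @param config A configuration list as returned by [load_config()] /
#'   [default_config()]; see that help page for the keys.
#' @param n_frames Number of frames to simulate.
#' @param render Logical; set `FALSE` to skip image rendering (ground truth
#'   only, much faster).
#' @return A list with elements `seq` (an [image_sequence()], or `NULL` when
#'   `render = FALSE`) and `truth`: a list with `tracks` (track table),
#'   `divisions` (`t_min, x_um, y_um, z_um`), `volumes`
#'   (`frame, t_min, volume_um3`), `cells` (per-frame cell states) and the
#'   `config`/`seed` that produced it.
#' @export
simulate_somite_movie <- function(config = default_config(), n_frames = 10,
                                  render = TRUE) {
  cfg <- validate_config(merge_config(default_config(), config))
  check_seed(cfg$seed)
  geom <- voxel_geometry(cfg$geometry$dx, cfg$geometry$dy, cfg$geometry$dz,
                         cfg$geometry$dt_min)
  dom <- cfg$tissue$domain_um
  t_total <- (n_frames - 1) * geom$dt_min
  pk <- generate_cell_packing(cfg$tissue$n_cells, dom,
                              cfg$tissue$radius_mean_um, cfg$tissue$radius_sd_um,
                              cfg$tissue$radius_mean2_um, cfg$tissue$fraction2,
                              cfg$tissue$max_overlap)
  sched <- simulate_divisions(pk, cfg$division$rate_per_hr, t_total,
                              cfg$division$duration_min)
  if (nrow(sched) > 0) { sched$done <- FALSE; sched$started <- FALSE }
  state <- data.frame(cell_id = pk$cell_id, x = pk$x, y = pk$y, z = pk$z,
                      r0 = pk$r, dividing = FALSE, alive = TRUE)
  next_id <- max(state$cell_id) + 1L
  v0 <- sum(4 / 3 * pi * state$r0^3)
  g <- cfg$growth$rate_um3_per_hr
  frames <- vector("list", n_frames)
  cells_rows <- list(); track_rows <- list(); vol_rows <- list()
  div_rows <- list()
  marg <- cfg$division$rounded_diameter_um / 2 + 1
  for (f in seq_len(n_frames)) {
    t_min <- (f - 1) * geom$dt_min
    # division phase bookkeeping first: rounded mitotic cells stop migrating
    was_dividing <- state$dividing
    state$dividing <- FALSE
    if (nrow(sched) > 0) {
      active <- sched$t_start_min <= t_min & t_min < sched$t_end_min
      # a cell cannot round up inside an already-rounded neighbour: move the
      # event to another quiescent cell when the chosen one is too close
      min_sep <- cfg$division$rounded_diameter_um + 1
      clamp_xy <- function(i) {
        state$x[i] <<- min(max(state$x[i], marg), dom[1] - marg)
        state$y[i] <<- min(max(state$y[i], marg), dom[2] - marg)
      }
      for (k in which(active)) {
        i <- match(sched$cell_id[k], state$cell_id)
        if (is.na(i)) next
        if (sched$started[k]) { state$dividing[i] <- TRUE; next }
        clamp_xy(i) # keep the rounded body inside the field of view
        cur <- which(state$dividing & state$alive)
        if (length(cur)) {
          sep <- function(j) min(sqrt((state$x[cur] - state$x[j])^2 +
                                      (state$y[cur] - state$y[j])^2))
          if (sep(i) < min_sep) {
            cand <- which(state$alive & !state$dividing &
                          !state$cell_id %in% sched$cell_id)
            ok <- cand[vapply(cand, function(j) sep(j) >= min_sep, logical(1))]
            if (length(ok)) {
              sched$cell_id[k] <- state$cell_id[ok[sample.int(length(ok), 1)]]
              i <- match(sched$cell_id[k], state$cell_id)
              clamp_xy(i)
            }
          }
        }
        state$dividing[i] <- TRUE
        sched$started[k] <- TRUE
      }
      state$dividing[!state$alive] <- FALSE
    }
    if (f > 1) {
      idx <- which(state$alive & !state$dividing)
      if (length(idx)) {
        pos <- motion_step(as.matrix(state[idx, c("x", "y")]), cfg$motion,
                           geom$dt_min, dom)
        state$x[idx] <- pos[, 1]; state$y[idx] <- pos[, 2]
      }
    }
    if (nrow(sched) > 0) {
      done <- sched$t_end_min <= t_min & !sched$done
      for (k in which(done)) {
        i <- match(sched$cell_id[k], state$cell_id)
        if (is.na(i) || !state$alive[i]) next
        rd <- state$r0[i] / 2^(1 / 3) # half volume each
        phi <- stats::runif(1, -pi, pi)
        off <- rd * c(cos(phi), sin(phi))
        dgt <- state[c(i, i), ]
        dgt$cell_id <- c(next_id, next_id + 1L)
        dgt$x <- pmin(pmax(dgt$x + c(off[1], -off[1]), 0.5), dom[1] - 0.5)
        dgt$y <- pmin(pmax(dgt$y + c(off[2], -off[2]), 0.5), dom[2] - 0.5)
        dgt$r0 <- rd
        dgt$dividing <- FALSE
        state$alive[i] <- FALSE
        state <- rbind(state, dgt)
        next_id <- next_id + 2L
        sched$done[k] <- TRUE
      }
    }
    live <- state[state$alive, ]
    # rescale radii so total volume tracks v0 + g * t exactly
    target <- v0 + g * t_min / 60
    s <- (target / sum(4 / 3 * pi * live$r0^3))^(1 / 3)
    live$r <- live$r0 * s
    live$r[live$dividing] <- pmax(live$r[live$dividing],
                                  cfg$division$rounded_diameter_um / 2)
    cells_rows[[f]] <- data.frame(frame = f - 1L, cell_id = live$cell_id,
                                  x_um = live$x, y_um = live$y, z_um = live$z,
                                  r_um = live$r, dividing = live$dividing,
                                  volume_um3 = 4 / 3 * pi * live$r^3)
    track_rows[[f]] <- data.frame(track_id = live$cell_id, frame = f - 1L,
                                  x_um = live$x, y_um = live$y, z_um = live$z)
    vol_rows[[f]] <- data.frame(frame = f - 1L, t_min = t_min,
                                volume_um3 = sum(4 / 3 * pi * live$r0^3 * s^3))
    if (render) {
      rc <- live[, c("x", "y", "z", "r", "dividing")]
      frames[[f]] <- render_membrane_frame(rc, geom, dom,
                                           cfg$render$psf_sigma_um,
                                           cfg$render$shell_um,
                                           cfg$render$peak, cfg$render$snr)
    }
  }
  seq_out <- NULL
  if (render) {
    d3 <- dim(frames[[1]])
    data <- array(0, c(n_frames, d3))
    for (f in seq_len(n_frames)) data[f, , , ] <- frames[[f]]
    seq_out <- image_sequence(data, geom)
  }
  tracks <- do.call(rbind, track_rows)
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  # every scheduled onset is a true event (position at the onset cell)
  divisions <- if (nrow(sched) > 0) {
    i <- match(sched$cell_id, pk$cell_id)
    data.frame(t_min = sched$t_start_min, x_um = pk$x[i], y_um = pk$y[i],
               z_um = pk$z[i])
  } else {
    data.frame(t_min = numeric(0), x_um = numeric(0), y_um = numeric(0),
               z_um = numeric(0))
  }
  truth <- list(
    tracks = as_track_table(tracks),
    divisions = divisions,
    volumes = do.call(rbind, vol_rows),
    cells = do.call(rbind, cells_rows),
    config = cfg, seed = cfg$seed)
  list(seq = seq_out, truth = truth)
}

#' Write ground truth to CSV files
#'
#' Writes `tracks.csv` (track-table schema), `divisions.csv`, `volumes.csv`
#' and `cells.csv` into a directory; [read_ground_truth()] reloads them
#' unchanged.
#'
#' @param truth The `truth` element of [simulate_somite_movie()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_ground_truth <- function(truth, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create directory ", dir)
  write_tracks(truth$tracks, file.path(dir, "tracks.csv"))
  utils::write.csv(truth$divisions, file.path(dir, "divisions.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$volumes, file.path(dir, "volumes.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' Reload ground truth written by [export_ground_truth()]
#' @param dir Directory containing the CSVs.
#' @return A list with `tracks`, `divisions`, `volumes`, `cells`.
#' @export
read_ground_truth <- function(dir) {
  list(tracks = read_tracks(file.path(dir, "tracks.csv")),
       divisions = utils::read.csv(file.path(dir, "divisions.csv")),
       volumes = utils::read.csv(file.path(dir, "volumes.csv")),
       cells = utils::read.csv(file.path(dir, "cells.csv")))
}
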