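#' Welch two-sample t-test
#'
#' Two-tailed t-test with unequal variances (Welch statistic, Satterthwaite
#' fractional degrees of freedom), the comparison used throughout the
#' pipeline's stage contrasts.
#'
#' @param a,b Numeric samples, each of length >= 2 with nonzero variance.
#' @return A list: `t`, `df`, `p`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("degenerate samples: both have zero variance")
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Stage presets for the three-stage synthetic scenario
#'
#' Motion and proliferation parameters for early (random walk,
#' 0.14 um/min, 1.7 divisions/hr), mid (directed towards the rostro-medial
#' sink, 0.21 um/min, 4.4 divisions/hr) and late (slow inward drift,
#' 0.06 um/min, 0.3 divisions/hr) stages.
#'
#' @return A named list of per-stage configuration fragments.
#' @export
stage_presets <- function() {
  list(
    early = list(motion = list(mode = "random", mean_speed = 0.14,
                               speed_sd = 0.08, drift_weight = 0),
                 division = list(rate_per_hr = 1.7)),
    mid = list(motion = list(mode = "directed", mean_speed = 0.21,
                             speed_sd = 0.11, drift_weight = 0.7),
               division = list(rate_per_hr = 4.4)),
    late = list(motion = list(mode = "inward", mean_speed = 0.06,
                              speed_sd = 0.03, drift_weight = 0.5),
                division = list(rate_per_hr = 0.3))
  )
}

#' Run the packaged three-stage synthetic scenario
#'
#' Simulates one movie per stage with [stage_presets()] applied on top of a
#' base configuration, runs the image-level tracking and division pipelines
#' and collects per-stage speed, directionality and proliferation summaries.
#'
#' @param seed Integer seed (one per-stage offset is derived from it).
#' @param n_cells Cells per movie.
#' @param domain_um Length-3 domain, micrometres. The default is a wide thin
#'   dorsal slab suited to in-plane tracking.
#' @param n_frames Frames per movie.
#' @param max_link_um Tracking link gate, micrometres.
#' @param snr Rendering peak SNR.
#' @return A list with per-stage results and a `summary` data frame
#'   (`stage, mean_speed_um_per_min, R, proliferation_per_hr, n_tracks`).
#' @export
run_three_stage_scenario <- function(seed = 1, n_cells = 60,
                                     domain_um = c(120, 120, 2),
                                     n_frames = 8, max_link_um = 12,
                                     snr = 10) {
  stages <- stage_presets()
  # sink for directed motion: rostro-medial corner (+x medial, +y rostral),
  # placed beyond the tracked subfield as the dermomyotome lip would be
  stages$mid$motion$sink <- c(1.5 * domain_um[1], 1.5 * domain_um[2])
  out <- list()
  for (i in seq_along(stages)) {
    nm <- names(stages)[i]
    cfg <- default_config()
    cfg$seed <- as.integer(seed) + i
    cfg$tissue$n_cells <- n_cells
    cfg$tissue$domain_um <- domain_um
    cfg$tissue$radius_mean_um <- 3.5
    cfg$tissue$radius_sd_um <- 0.3
    cfg$render$snr <- snr
    for (k in names(stages[[i]]$motion)) cfg$motion[[k]] <- stages[[i]]$motion[[k]]
    cfg$division$rate_per_hr <- stages[[i]]$division$rate_per_hr
    sim <- simulate_somite_movie(cfg, n_frames = n_frames)
    trk <- track_movie(sim$seq, diameter_um = 7, max_link_um = max_link_um)
    div <- detect_divisions(sim$seq)
    out[[nm]] <- list(tracking = trk, divisions = div, truth = sim$truth,
                      seed = cfg$seed)
  }
  summary <- do.call(rbind, lapply(names(out), function(nm) {
    trk <- out[[nm]]$tracking
    data.frame(stage = nm,
               mean_speed_um_per_min = trk$mean_speed_um_per_min,
               R = if (!is.null(trk$directionality)) trk$directionality$R
                 else NA_real_,
               proliferation_per_hr = out[[nm]]$divisions$rate_per_hr,
               n_tracks = if (!is.null(trk$directionality))
                 trk$directionality$n_tracks else 0L)
  }))
  out$summary <- summary
  out$seed <- seed
  out
}

report_section <- function(dir, file, reader) {
  path <- file.path(dir, file)
  if (!file.exists(path)) return(list(present = FALSE))
  c(list(present = TRUE), reader(path))
}

#' Aggregate module outputs into one report
#'
#' Scans a results directory for the standard per-module artifacts
#' (`growth.json`, `correlation.json`, `events.csv`, `tracks.csv`,
#' `cells.csv`, `stats.json`), aggregates whatever is present into a single
#' JSON report (missing modules are marked absent, not an error), and
#' optionally regenerates the summary figures.
#'
#' @param results_dir Directory of module outputs.
#' @param out Path of the JSON report to write.
#' @param seed Seed recorded in the report metadata.
#' @param figures If `TRUE`, writes `angles.png` (radial histogram),
#'   `length_vs_angle.png` and `correlation.png` next to the report when the
#'   corresponding section is present.
#' @return The report list, invisibly; the JSON is written to `out`.
#' @export
build_report <- function(results_dir, out = file.path(results_dir, "report.json"),
                         seed = NA, figures = FALSE) {
  if (!dir.exists(results_dir)) stop("no inputs found: ", results_dir)
  report <- list(
    meta = list(package = "somitedyn",
                version = as.character(utils::packageVersion("somitedyn")),
                seed = seed),
    growth = report_section(results_dir, "growth.json", function(p)
      jsonlite::read_json(p, simplifyVector = TRUE)),
    correlation = report_section(results_dir, "correlation.json", function(p)
      jsonlite::read_json(p, simplifyVector = TRUE)),
    divisions = report_section(results_dir, "events.csv", function(p) {
      ev <- utils::read.csv(p)
      list(n_events = nrow(ev))
    }),
    tracking = report_section(results_dir, "tracks.csv", function(p) {
      tr <- read_tracks(p)
      met <- all_track_metrics(tr)
      di <- try(directionality_index(met), silent = TRUE)
      list(n_tracks = length(unique(tr$track_id)),
           mean_speed_um_per_min = mean(met$mean_speed_um_per_min),
           R = if (inherits(di, "try-error")) NA else di$R,
           metrics = met)
    }),
    segmentation = report_section(results_dir, "cells.csv", function(p) {
      cs <- utils::read.csv(p)
      list(n_cells = nrow(cs),
           mean_volume_um3 = if ("volume_um3" %in% names(cs))
             mean(cs$volume_um3) else NA)
    }),
    stats = report_section(results_dir, "stats.json", function(p)
      jsonlite::read_json(p, simplifyVector = TRUE))
  )
  if (!any(vapply(report[-1], function(s) isTRUE(s$present), logical(1))))
    stop("no inputs found in ", results_dir)
  if (figures) write_report_figures(report, results_dir)
  fig_metrics <- report$tracking$metrics
  report$tracking$metrics <- NULL
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  report$tracking$metrics <- fig_metrics
  invisible(report)
}

write_report_figures <- function(report, dir) {
  met <- report$tracking$metrics
  if (isTRUE(report$tracking$present) && !is.null(met) && nrow(met) > 0) {
    hist_df <- angle_distribution(met)
    grDevices::png(file.path(dir, "angles.png"), 600, 600)
    mids <- (hist_df$bin_lo_deg + hist_df$bin_hi_deg) / 2 * pi / 180
    r <- hist_df$count
    graphics::plot(NULL, xlim = c(-1, 1) * max(r, 1), ylim = c(-1, 1) * max(r, 1),
                   asp = 1, xlab = "", ylab = "", main = "Track angle distribution")
    graphics::segments(0, 0, r * cos(mids), r * sin(mids), lwd = 6, col = "steelblue")
    grDevices::dev.off()
    grDevices::png(file.path(dir, "length_vs_angle.png"), 600, 450)
    graphics::plot(met$theta_deg, met$net_displacement_um, pch = 19,
                   xlab = "mean track angle (deg)",
                   ylab = "net displacement (um)", main = "Length versus angle")
    grDevices::dev.off()
  }
  cr <- report$correlation
  if (isTRUE(cr$present) && !is.null(cr$r)) {
    grDevices::png(file.path(dir, "correlation.png"), 600, 450)
    graphics::barplot(cr$r, names.arg = cr$depth, ylim = c(0, 1),
                      ylab = "correlation coefficient",
                      main = "Morphology correlation by depth")
    grDevices::dev.off()
  }
  invisible(NULL)
}
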