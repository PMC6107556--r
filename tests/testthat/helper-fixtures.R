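# Shared fixture builders: everything is generated in code at test time.

# Minimal movie configuration for fast image-level tests.
quick_config <- function(seed = 1, n_cells = 20, domain = c(48, 48, 0.5),
                         mode = "random", mean_speed = 0.1, speed_sd = 0.05,
                         sink = NULL, drift_weight = 0, division_rate = 0,
                         radius = 3, snr = 8) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$tissue$n_cells <- n_cells
  cfg$tissue$domain_um <- domain
  cfg$tissue$radius_mean_um <- radius
  cfg$tissue$radius_sd_um <- 0.2
  cfg$motion <- list(mode = mode, mean_speed = mean_speed, speed_sd = speed_sd,
                     sink = sink, drift_weight = drift_weight)
  cfg$division$rate_per_hr <- division_rate
  cfg$render$snr <- snr
  cfg
}

# Anti-aliased filled disk rendered into a (y, x) matrix (pixel size 1).
draw_disk <- function(ny, nx, cy, cx, r) {
  yy <- matrix(seq_len(ny) - 0.5, ny, nx)
  xx <- matrix(rep(seq_len(nx) - 0.5, each = ny), ny, nx)
  d <- sqrt((yy - cy)^2 + (xx - cx)^2)
  matrix(pmin(pmax(0.5 + (r - d), 0), 1), ny, nx)
}

# Anti-aliased filled axis-aligned ellipse (semi-axes a along x, b along y).
draw_ellipse <- function(ny, nx, cy, cx, a, b) {
  yy <- matrix(seq_len(ny) - 0.5, ny, nx)
  xx <- matrix(rep(seq_len(nx) - 0.5, each = ny), ny, nx)
  # signed approximate distance to the ellipse boundary
  d <- (sqrt(((xx - cx) / a)^2 + ((yy - cy) / b)^2) - 1) * min(a, b)
  matrix(pmin(pmax(0.5 - d, 0), 1), ny, nx)
}

# Rayleigh test p-value for circular uniformity of angles (degrees).
rayleigh_p <- function(angles_deg) {
  a <- angles_deg * pi / 180
  n <- length(a)
  R <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  z <- n * R^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# Brute-force optimal frame-pair linking: enumerates every one-to-one partial
# matching between spot sets a and b and minimises
#   sum(d^2 over links) + b2 * (#unmatched in a + #unmatched in b),
# links longer than sqrt(b2) forbidden. Independent of the LAP solver.
brute_force_links <- function(a, b, max_link) {
  n <- nrow(a); m <- nrow(b)
  b2 <- max_link^2
  D2 <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
  best <- list(cost = Inf, links = rep(NA_integer_, n))
  assign <- rep(NA_integer_, n)
  recurse <- function(i, used, cost) {
    if (cost >= best$cost) return()
    if (i > n) {
      total <- cost + b2 * (sum(is.na(assign)) + (m - sum(!is.na(assign))))
      if (total < best$cost) best <<- list(cost = total, links = assign)
      return()
    }
    assign[i] <<- NA_integer_
    recurse(i + 1, used, cost)
    for (j in seq_len(m)) {
      if (used[j] || D2[i, j] > b2) next
      assign[i] <<- j
      recurse(i + 1, `[<-`(used, j, TRUE), cost + D2[i, j])
      assign[i] <<- NA_integer_
    }
  }
  recurse(1, rep(FALSE, m), 0)
  best
}

# Cost of a set of links under the same objective.
link_cost <- function(a, b, links, max_link) {
  b2 <- max_link^2
  cost <- 0
  for (i in seq_along(links)) {
    if (is.na(links[i])) cost <- cost + b2
    else cost <- cost + (a$x_um[i] - b$x_um[links[i]])^2 +
        (a$y_um[i] - b$y_um[links[i]])^2
  }
  cost + b2 * (nrow(b) - sum(!is.na(links)))
}
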