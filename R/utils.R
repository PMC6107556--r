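# Internal numeric helpers shared across modules.

#' Otsu threshold of a numeric sample
#'
#' Histogram-based Otsu threshold (256 bins over the data range), maximising
#' between-class variance. Used as the default foreground/background split for
#' membrane images and preprocessed slices.
#'
#' @param x Numeric vector or array of intensities.
#' @param n_bins Number of histogram bins.
#' @return The threshold value; voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins))
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[n_bins]; mt <- m[n_bins]
  w1 <- w[-n_bins]; m1 <- m[-n_bins]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mt * w1[valid] - n * m1[valid])^2 / (w1[valid] * w2[valid])
  mids[which.max(bcv)]
}

# Gaussian kernel with odd support covering +-3 sigma.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a (z, y, x) array: xy via EBImage per slice,
# z via a small weighted sum of shifted arrays (replicated edges).
blur3d <- function(a, sigma_xy_px, sigma_z_px = 0) {
  d <- dim(a)
  if (sigma_xy_px > 0) {
    # EBImage filters the first two dims per frame: permute to (y, x, z)
    p <- aperm(a, c(2, 3, 1))
    rad <- 2 * ceiling(3 * sigma_xy_px) + 1
    lim <- 2 * floor((min(d[2:3]) - 1) / 2) + 1
    p <- EBImage::gblur(p, sigma = sigma_xy_px, radius = min(rad, lim),
                        boundary = "replicate")
    p <- array(p, c(d[2], d[3], d[1])) # gblur may drop a singleton frame dim
    a <- aperm(p, c(3, 1, 2))
  }
  if (sigma_z_px > 0 && d[1] > 1) {
    k <- gauss_kernel(sigma_z_px)
    h <- (length(k) - 1L) / 2L
    out <- array(0, d)
    for (j in seq_along(k)) {
      idx <- pmin(pmax(seq_len(d[1]) + (j - 1L - h), 1L), d[1])
      out <- out + k[j] * a[idx, , , drop = FALSE]
    }
    a <- out
  }
  a
}

# 2D Gaussian blur of a (y, x) matrix; replicated edges, kernel clamped to
# the image size.
blur2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  rad <- 2 * ceiling(3 * sigma_px) + 1
  lim <- 2 * floor((min(dim(m)[1:2]) - 1) / 2) + 1
  EBImage::gblur(m, sigma = sigma_px, radius = min(rad, lim),
                 boundary = "replicate")
}

# Perimeter of a 2D binary mask, measured as the length of the closed
# 0.5-level contour of the lightly blurred mask. Sub-pixel and close to exact
# for smooth convex shapes; the blur radius only rounds single-pixel corners.
mask_perimeter_px <- function(mask, smooth_sigma = 1) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  # pad so contours of border-touching regions still close
  pad <- max(3L, ceiling(3 * smooth_sigma))
  mp <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  mp[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  mp <- blur2d(mp, smooth_sigma)
  cl <- grDevices::contourLines(x = seq_len(nrow(mp)), y = seq_len(ncol(mp)),
                                z = mp, levels = 0.5)
  if (length(cl) == 0) return(0)
  lens <- vapply(cl, function(cc) {
    xs <- c(cc$x, cc$x[1]); ys <- c(cc$y, cc$y[1])
    sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }, numeric(1))
  max(lens)
}

# Centroids, areas and bounding boxes of a 2D integer label matrix.
label_stats_2d <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(0), area_px = numeric(0),
                      row = numeric(0), col = numeric(0)))
  l <- lab[idx]
  rows <- ((idx - 1) %% nrow(lab)) + 1
  cols <- ((idx - 1) %/% nrow(lab)) + 1
  data.frame(label = sort(unique(l)),
             area_px = as.numeric(tabulate(l)[sort(unique(l))]),
             row = as.numeric(tapply(rows, l, mean)),
             col = as.numeric(tapply(cols, l, mean)))
}

# Normalize an array to [0, 1]; constant input maps to 0.
normalize01 <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(x * 0)
  (x - r[1]) / diff(r)
}

# Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(theta) {
  w <- ((theta + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

check_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(seed)
}
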