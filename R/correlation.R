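#' Pixel-wise Pearson correlation of two images
#'
#' Plots (conceptually) each pixel of `a` against the corresponding pixel of
#' `b` and returns the Pearson correlation of that cloud: 1 for identical
#' images, lower values for greater morphological change, -1 for exact
#' anticorrelation. Invariant under positive affine intensity transforms of
#' either image.
#'
#' @param a,b Numeric matrices (or arrays) of identical shape.
#' @param mask Optional logical mask of the same shape; only `TRUE` pixels
#'   are compared.
#' @return The correlation coefficient.
#' @export
pearson_image_correlation <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  av <- as.numeric(a); bv <- as.numeric(b)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(a))) stop("mask must match the image shape")
    av <- av[mask]; bv <- bv[mask]
  }
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("zero variance: correlation undefined for a constant image")
  stats::cor(av, bv)
}

#' Morphology-change correlation at several depths
#'
#' Correlates the slice at each requested depth fraction between two time
#' points, replicating the overlay measurement of somite change: dorsal,
#' centre and ventral slices (fractions 0.25, 0.5, 0.75 of the z-extent) of
#' the frame at `t0` against the same slice at `t1`. No registration or
#' drift correction is applied.
#'
#' @param seq An [image_sequence()].
#' @param t0_min,t1_min Times in minutes; must map to existing frames via the
#'   frame interval (`t1 > t0`).
#' @param depth_fractions Fractions of the z-extent in `[0, 1]`, resolved to
#'   the nearest slice.
#' @param depth_labels Labels for the output rows.
#' @return A data frame with columns `depth, z_slice, t0_min, t1_min, r`.
#' @export
correlation_timecourse <- function(seq, t0_min = 0, t1_min = 180,
                                   depth_fractions = c(0.25, 0.5, 0.75),
                                   depth_labels = c("dorsal", "centre", "ventral")) {
  stopifnot(inherits(seq, "image_sequence"))
  if (t1_min <= t0_min) stop("t1 must be greater than t0")
  if (any(depth_fractions < 0 | depth_fractions > 1))
    stop("depth fractions must lie in [0, 1]")
  if (length(depth_labels) != length(depth_fractions))
    depth_labels <- paste0("depth_", depth_fractions)
  d <- dim(seq$data)
  dt <- seq$geometry$dt_min
  f0 <- round(t0_min / dt) + 1L
  f1 <- round(t1_min / dt) + 1L
  if (f0 < 1 || f0 > d[1] || f1 > d[1])
    stop("requested time is out of range of the sequence")
  zs <- pmin(pmax(round(depth_fractions * (d[2] - 1)) + 1L, 1L), d[2])
  r <- vapply(zs, function(z) {
    pearson_image_correlation(matrix(seq$data[f0, z, , ], d[3], d[4]),
                              matrix(seq$data[f1, z, , ], d[3], d[4]))
  }, numeric(1))
  data.frame(depth = depth_labels, z_slice = zs,
             t0_min = t0_min, t1_min = t1_min, r = r)
}
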