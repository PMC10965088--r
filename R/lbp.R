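# Local binary patterns, the radial-mean variant, and local ternary patterns.

#' Specification of a local binary pattern operator
#'
#' @param radius neighbourhood radius in pixels (>= 1).
#' @param points number of circular samples P (8 or 16).
#' @param mapping `"uniform_ri"` (rotation-invariant uniform codes, P + 2
#'   bins) or `"raw"` (all `2^P` codes).
#' @return an `lbp_spec` list.
#' @export
lbp_spec <- function(radius = 1, points = 8L, mapping = c("uniform_ri", "raw")) {
  mapping <- match.arg(mapping)
  points <- as.integer(points)
  if (radius < 1) abort_validation("lbp radius must be >= 1")
  if (!points %in% c(8L, 16L)) abort_validation("lbp points must be 8 or 16")
  structure(list(radius = radius, points = points, mapping = mapping),
            class = "lbp_spec")
}

# Comparison tolerance for thresholding interpolated neighbours against the
# centre: bilinear interpolation of a flat region can differ from the centre
# by floating-point round-off, so ties are resolved with a small slack.
LBP_EPS <- 1e-9

# sample positions counter-clockwise from angle 0 (east), y measured downward
lbp_offsets <- function(radius, points) {
  ang <- 2 * pi * (seq_len(points) - 1L) / points
  dx <- radius * cos(ang)
  dy <- -radius * sin(ang)
  dx[abs(dx - round(dx)) < 1e-9] <- round(dx[abs(dx - round(dx)) < 1e-9])
  dy[abs(dy - round(dy)) < 1e-9] <- round(dy[abs(dy - round(dy)) < 1e-9])
  list(dx = dx, dy = dy)
}

# Bilinearly interpolated neighbour plane at fixed offset (dy, dx) for all
# interior pixels rows r1..r2, cols c1..c2 of img.
shift_interp <- function(img, dy, dx, r1, r2, c1, c2) {
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  sub <- function(ddy, ddx) img[(r1 + ddy):(r2 + ddy), (c1 + ddx):(c2 + ddx), drop = FALSE]
  if (fy == 0 && fx == 0) return(sub(y0, x0))
  (1 - fy) * ((1 - fx) * sub(y0, x0) + fx * sub(y0, x0 + 1L)) +
    fy     * ((1 - fx) * sub(y0 + 1L, x0) + fx * sub(y0 + 1L, x0 + 1L))
}

# Per-pixel LBP codes over the interior of the image (margin = ceil(radius)).
lbp_codes <- function(img, spec = lbp_spec()) {
  assert_gray_image(img)
  m <- ceiling(spec$radius)
  if (nrow(img) < 2 * m + 1 || ncol(img) < 2 * m + 1) {
    abort_validation("image too small for the requested LBP radius")
  }
  r1 <- m + 1L; r2 <- nrow(img) - m
  c1 <- m + 1L; c2 <- ncol(img) - m
  center <- img[r1:r2, c1:c2, drop = FALSE]
  off <- lbp_offsets(spec$radius, spec$points)
  codes <- matrix(0, nrow(center), ncol(center))
  for (p in seq_len(spec$points)) {
    neigh <- shift_interp(img, off$dy[p], off$dx[p], r1, r2, c1, c2)
    codes <- codes + (neigh - center >= -LBP_EPS) * 2^(p - 1L)
  }
  codes
}

# map raw codes 0..2^P-1 to histogram bins under the spec's mapping
lbp_code_table <- function(spec) {
  P <- spec$points
  if (spec$mapping == "raw") return(seq_len(2^P))
  codes <- 0:(2^P - 1)
  bits <- t(vapply(codes, function(cd) as.integer(intToBits(cd))[seq_len(P)], integer(P)))
  trans <- rowSums(bits != bits[, c(2:P, 1), drop = FALSE])
  ones <- rowSums(bits)
  ifelse(trans <= 2, ones + 1L, P + 2L)  # bins 1..P+1 uniform, P+2 non-uniform
}

lbp_n_bins <- function(spec) {
  if (spec$mapping == "raw") 2^spec$points else spec$points + 2L
}

codes_to_histogram <- function(codes, spec) {
  tab <- lbp_code_table(spec)
  bins <- tab[codes + 1L]
  h <- tabulate(bins, nbins = lbp_n_bins(spec))
  h / sum(h)
}

#' Local binary pattern histogram
#'
#' For every interior pixel, each of the P circular neighbours (bilinearly
#' interpolated off-grid, counter-clockwise from angle 0) contributes bit 1
#' when it is at least as bright as the centre. Codes are pooled into a
#' normalized histogram under the spec's mapping.
#'
#' @param img grayscale image matrix.
#' @param spec an [lbp_spec()].
#' @return normalized histogram (sums to 1).
#' @export
lbp_histogram <- function(img, spec = lbp_spec()) {
  codes_to_histogram(lbp_codes(img, spec), spec)
}

# RLBP codes: each angular sample is the mean of interpolated values at radii
# 1..n_radii before thresholding against the centre.
rlbp_codes <- function(img, spec = lbp_spec(), n_radii = 3L) {
  assert_gray_image(img)
  n_radii <- as.integer(n_radii)
  if (n_radii < 1L) abort_validation("n_radii must be >= 1")
  m <- ceiling(n_radii)
  if (nrow(img) < 2 * m + 1 || ncol(img) < 2 * m + 1) {
    abort_validation("image too small for the requested radial extent")
  }
  r1 <- m + 1L; r2 <- nrow(img) - m
  c1 <- m + 1L; c2 <- ncol(img) - m
  center <- img[r1:r2, c1:c2, drop = FALSE]
  codes <- matrix(0, nrow(center), ncol(center))
  for (p in seq_len(spec$points)) {
    acc <- matrix(0, nrow(center), ncol(center))
    for (r in seq_len(n_radii)) {
      off <- lbp_offsets(r, spec$points)
      acc <- acc + shift_interp(img, off$dy[p], off$dx[p], r1, r2, c1, c2)
    }
    acc <- acc / n_radii
    codes <- codes + (acc - center >= -LBP_EPS) * 2^(p - 1L)
  }
  codes
}

#' Radial local binary pattern histogram
#'
#' LBP variant in which each angular sample is the mean of the interpolated
#' values at radii `1..n_radii` along that angle before thresholding; with
#' `n_radii = 1` it reduces exactly to [lbp_histogram()] at radius 1.
#'
#' @inheritParams lbp_histogram
#' @param n_radii number of radii averaged per angle.
#' @return normalized histogram.
#' @export
rlbp_histogram <- function(img, spec = lbp_spec(), n_radii = 3L) {
  codes_to_histogram(rlbp_codes(img, spec, n_radii), spec)
}

# upper/lower LTP code planes
ltp_codes <- function(img, spec = lbp_spec(), t = 0.1) {
  if (t <= 0 || t >= 1) abort_validation("ltp threshold t must be in (0, 1)")
  m <- ceiling(spec$radius)
  assert_gray_image(img)
  if (nrow(img) < 2 * m + 1 || ncol(img) < 2 * m + 1) {
    abort_validation("image too small for the requested LTP radius")
  }
  r1 <- m + 1L; r2 <- nrow(img) - m
  c1 <- m + 1L; c2 <- ncol(img) - m
  center <- img[r1:r2, c1:c2, drop = FALSE]
  off <- lbp_offsets(spec$radius, spec$points)
  upper <- matrix(0, nrow(center), ncol(center))
  lower <- matrix(0, nrow(center), ncol(center))
  for (p in seq_len(spec$points)) {
    neigh <- shift_interp(img, off$dy[p], off$dx[p], r1, r2, c1, c2)
    upper <- upper + (neigh - (center + t) >= -LBP_EPS) * 2^(p - 1L)
    lower <- lower + (neigh - (center - t) <= LBP_EPS) * 2^(p - 1L)
  }
  list(upper = upper, lower = lower)
}

#' Local ternary pattern histograms
#'
#' Neighbours are coded +1 when at least `t` above the centre, -1 when at
#' least `t` below, 0 otherwise. The +1 and -1 planes are binarized
#' separately and each histogrammed exactly as in [lbp_histogram()].
#'
#' @inheritParams lbp_histogram
#' @param t ternary tolerance on `[0, 1]` intensities.
#' @return list with normalized `upper` and `lower` histograms.
#' @export
ltp_histograms <- function(img, spec = lbp_spec(), t = 0.1) {
  cds <- ltp_codes(img, spec, t)
  list(upper = codes_to_histogram(cds$upper, spec),
       lower = codes_to_histogram(cds$lower, spec))
}
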