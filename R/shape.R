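# Binary-object shape features: segmentation, statistical-geometrical region
# metrics, boundary intersection signature, box-counting fractal dimension
# and the conventional shape-signature aspect ratio.

assert_mask <- function(mask, nonempty = TRUE) {
  if (!is.matrix(mask) || !(is.logical(mask) || is.numeric(mask))) {
    abort_validation("mask must be a logical or numeric matrix")
  }
  m <- mask != 0
  if (nonempty && !any(m)) abort_validation("mask has no object pixels")
  m
}

# Otsu threshold over a 256-bin histogram of [0,1] intensities; returns the
# upper edge of the chosen bin (object = strictly brighter pixels).
otsu_threshold <- function(img, bins = 256L) {
  q <- quantize_gray(img, bins)
  counts <- tabulate(q + 1L, nbins = bins)
  p <- counts / sum(counts)
  levels_mid <- (seq_len(bins) - 0.5) / bins
  omega <- cumsum(p)
  mu <- cumsum(p * levels_mid)
  mu_t <- mu[bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)     # first maximiser: deterministic tie-break
  k / bins                    # upper edge of bin k
}

# connected-component labelling by breadth-first flood fill
label_components <- function(mask, connectivity = 8L) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  offs <- if (connectivity == 8L) {
    cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
  labels <- matrix(0L, h, w)
  cur <- 0L
  for (seed in which(m)) {
    if (labels[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    labels[seed] <- cur
    while (length(frontier) > 0L) {
      r <- ((frontier - 1L) %% h) + 1L
      c <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
        ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        if (!any(ok)) next
        idx <- (cc[ok] - 1L) * h + rr[ok]
        idx <- idx[m[idx] & labels[idx] == 0L]
        if (length(idx) > 0L) {
          labels[idx] <- cur
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(labels = labels, n = cur)
}

#' Segment the dominant bright object of a grayscale image
#'
#' Thresholds the image with Otsu's method (256-bin histogram, object =
#' brighter side) and keeps the largest 8-connected component.
#'
#' @param img grayscale image matrix.
#' @return logical mask of the same dimensions.
#' @export
binarize_object <- function(img) {
  assert_gray_image(img)
  if (max(img) - min(img) < 1e-12) {
    abort_validation("constant image: no object to segment")
  }
  thr <- otsu_threshold(img)
  m <- img > thr
  if (!any(m)) abort_validation("segmentation produced no object pixels")
  lab <- label_components(m, 8L)
  sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  keep <- which.max(sizes)    # ties -> lowest label (first scan order)
  lab$labels == keep
}

# background 4-connected components not touching the image border = holes
find_holes <- function(m) {
  lab <- label_components(!m, 4L)
  if (lab$n == 0L) return(list(n = 0L, area = 0L))
  border_labels <- unique(c(lab$labels[1L, ], lab$labels[nrow(m), ],
                            lab$labels[, 1L], lab$labels[, ncol(m)]))
  border_labels <- border_labels[border_labels > 0L]
  hole_ids <- setdiff(seq_len(lab$n), border_labels)
  sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  list(n = length(hole_ids), area = sum(sizes[hole_ids]))
}

# Moore-neighbour contour tracing (Jacob's stopping criterion); returns the
# number of steps along the outer 8-connected contour of one component.
trace_contour_steps <- function(m) {
  h <- nrow(m); w <- ncol(m)
  dirs <- cbind(dr = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
                dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L))  # clockwise from east
  start <- which(m)[1L]                   # column-major scan: leftmost, then topmost
  sr <- ((start - 1L) %% h) + 1L
  sc <- ((start - 1L) %/% h) + 1L
  neighbors_obj <- function(r, c) {
    rr <- r + dirs[, 1L]; cc <- c + dirs[, 2L]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    found <- ok
    found[ok] <- m[(cc[ok] - 1L) * h + rr[ok]]
    found
  }
  if (!any(neighbors_obj(sr, sc))) return(0L)  # isolated pixel
  r <- sr; c <- sc
  b <- 5L  # backtrack direction index: we pretend we entered from the west
  steps <- 0L
  first_dir <- -1L
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((b + k) %% 8L) + 1L
      rr <- r + dirs[d, 1L]; cc <- c + dirs[d, 2L]
      if (rr >= 1L && rr <= h && cc >= 1L && cc <= w && m[rr, cc]) {
        # backtrack for next step: direction pointing back towards the
        # previous cell, advanced one position clockwise
        b <- (d - 1L + 4L + 1L) %% 8L
        r <- rr; c <- cc
        steps <- steps + 1L
        if (first_dir < 0L) first_dir <- d
        found <- TRUE
        break
      }
    }
    if (!found) break
    if (r == sr && c == sc && steps > 1L) break
    if (steps > 4L * (h * w)) break        # safety net; cannot trigger on valid masks
  }
  steps
}

perimeter_steps <- function(m) {
  lab <- label_components(m, 8L)
  total <- 0L
  for (id in seq_len(lab$n)) total <- total + trace_contour_steps(lab$labels == id)
  total
}

# convex hull area using pixel-corner points (a solid axis-aligned square of
# n x n pixels then has convex area exactly n^2)
convex_hull_area <- function(rows, cols) {
  pts <- rbind(cbind(rows - 0.5, cols - 0.5), cbind(rows - 0.5, cols + 0.5),
               cbind(rows + 0.5, cols - 0.5), cbind(rows + 0.5, cols + 0.5))
  pts <- unique(pts)
  if (nrow(pts) < 3L) return(0)
  hull <- grDevices::chull(pts[, 2L], pts[, 1L])
  x <- pts[hull, 2L]; y <- pts[hull, 1L]
  n <- length(hull)
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

#' Statistical-geometrical region metrics
#'
#' Sixteen scalar properties of a binary object, in fixed order: area,
#' centroid row, centroid column, convex area, equivalent diameter
#' `sqrt(4 area / pi)`, Euler number (8-connected objects minus 4-connected
#' holes), extent (area / bounding-box area), major and minor axis lengths,
#' orientation and eccentricity of the moment-equivalent ellipse, perimeter
#' (steps along the 8-connected outer contour), filled area, solidity
#' (area / convex area), bounding-box height and width.
#'
#' @param mask logical object mask (nonzero = object).
#' @return named numeric vector of length 16.
#' @export
region_metrics <- function(mask) {
  m <- assert_mask(mask)
  coords <- which(m, arr.ind = TRUE)
  rows <- coords[, 1L]; cols <- coords[, 2L]
  n <- nrow(coords)
  cr <- mean(rows); cc <- mean(cols)
  bbox_h <- max(rows) - min(rows) + 1L
  bbox_w <- max(cols) - min(cols) + 1L
  # second central moments with the 1/12 unit-pixel correction
  urr <- sum((rows - cr)^2) / n + 1 / 12
  ucc <- sum((cols - cc)^2) / n + 1 / 12
  urc <- sum((rows - cr) * (cols - cc)) / n
  common <- sqrt((urr - ucc)^2 + 4 * urc^2)
  major <- 2 * sqrt(2) * sqrt(ucc + urr + common)
  minor <- 2 * sqrt(2) * sqrt(max(ucc + urr - common, 0))
  orientation <- 0.5 * atan2(-2 * urc, ucc - urr)
  eccentricity <- if (major > 0) sqrt(max(1 - (minor / major)^2, 0)) else 0
  holes <- find_holes(m)
  n_obj <- label_components(m, 8L)$n
  conv_area <- convex_hull_area(rows, cols)
  c(area = n,
    centroid_row = cr,
    centroid_col = cc,
    convex_area = conv_area,
    equiv_diameter = sqrt(4 * n / pi),
    euler = n_obj - holes$n,
    extent = n / (bbox_h * bbox_w),
    major_axis = major,
    minor_axis = minor,
    orientation = orientation,
    eccentricity = eccentricity,
    perimeter = perimeter_steps(m),
    filled_area = n + holes$area,
    solidity = if (conv_area > 0) n / conv_area else 1,
    bbox_height = bbox_h,
    bbox_width = bbox_w)
}

#' Boundary intersection-based shape signature
#'
#' Casts `n_rays` rays from the object's centroid at angles `2*pi*m/n_rays`
#' (counter-clockwise from east) and records, per ray, the distance from the
#' centroid to the farthest object pixel crossed — the outermost boundary
#' intersection, which captures concave contours. The signature is divided
#' by its maximum (all-zeros if no ray meets the object).
#'
#' @param mask logical object mask.
#' @param n_rays number of rays (>= 4).
#' @return numeric vector of length `n_rays`, maximum 1 (or all zeros).
#' @export
bibs_signature <- function(mask, n_rays = 8L) {
  m <- assert_mask(mask)
  n_rays <- as.integer(n_rays)
  if (n_rays < 4L) abort_validation("n_rays must be >= 4")
  coords <- which(m, arr.ind = TRUE)
  cr <- mean(coords[, 1L]); cc <- mean(coords[, 2L])
  h <- nrow(m); w <- ncol(m)
  rmax <- sqrt(h^2 + w^2)
  steps <- seq(0, rmax, by = 0.25)
  sig <- numeric(n_rays)
  for (k in seq_len(n_rays)) {
    th <- 2 * pi * (k - 1L) / n_rays
    rr <- round(cr - steps * sin(th))
    cc2 <- round(cc + steps * cos(th))
    ok <- rr >= 1 & rr <= h & cc2 >= 1 & cc2 <= w
    hit <- ok
    hit[ok] <- m[cbind(rr[ok], cc2[ok])]
    sig[k] <- if (any(hit)) steps[max(which(hit))] else 0
  }
  mx <- max(sig)
  if (mx > 0) sig <- sig / mx
  sig
}

#' Box-counting fractal dimension of a binary mask
#'
#' The mask is padded into the next power-of-two square; `N(eps)` counts the
#' `eps x eps` grid boxes containing at least one object pixel for
#' `eps = 2, 4, ..., side/2`, and the dimension is the least-squares slope
#' of `log N` against `log(1/eps)`, clamped to `[0, 2]`.
#'
#' @param mask logical object mask.
#' @return scalar dimension estimate in `[0, 2]`.
#' @export
fractal_dimension <- function(mask) {
  m <- assert_mask(mask)
  side <- 2^ceiling(log2(max(dim(m))))
  side <- max(side, 8L)
  padded <- matrix(FALSE, side, side)
  padded[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  eps <- 2^seq_len(log2(side) - 1L)
  N <- vapply(eps, function(e) {
    g_r <- (seq_len(side) - 1L) %/% e
    by_r <- rowsum(padded * 1L, g_r)
    by_rc <- rowsum(t(by_r), g_r)
    sum(by_rc > 0)
  }, numeric(1))
  x <- log(1 / eps)
  slope <- sum((x - mean(x)) * (log(N) - mean(log(N)))) / sum((x - mean(x))^2)
  min(max(slope, 0), 2)
}

#' Conventional shape-signature aspect ratio
#'
#' Boundary pixels are object pixels with at least one background 4-neighbour
#' (image borders count as background). Returns the width/height ratio of
#' the boundary's bounding box.
#'
#' @param mask logical object mask.
#' @return positive scalar.
#' @export
shape_signature_aspect <- function(mask) {
  m <- assert_mask(mask)
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  inner <- pad[2:(h + 1L), 2:(w + 1L)]
  bg_neigh <- !pad[1:h, 2:(w + 1L)] | !pad[3:(h + 2L), 2:(w + 1L)] |
    !pad[2:(h + 1L), 1:w] | !pad[2:(h + 1L), 3:(w + 2L)]
  boundary <- inner & bg_neigh
  coords <- which(boundary, arr.ind = TRUE)
  bw <- max(coords[, 2L]) - min(coords[, 2L]) + 1L
  bh <- max(coords[, 1L]) - min(coords[, 1L]) + 1L
  bw / bh
}
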