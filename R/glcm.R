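# Gray-level co-occurrence matrices and Haralick-style summary statistics.

#' Specification of a gray-level co-occurrence computation
#'
#' @param levels number of quantization bins over `[0, 1]` (equal-width;
#'   intensity 1 falls in the top bin).
#' @param offsets list of integer `c(row_shift, col_shift)` displacements.
#'   The defaults are the four distance-1 directions 0, 45, 90 and 135
#'   degrees: `(0,1)`, `(-1,1)`, `(-1,0)`, `(-1,-1)`.
#' @param symmetric add the transpose so pairs count in both directions.
#' @param normalized divide each matrix by its total so entries sum to 1.
#' @return a `glcm_spec` list.
#' @export
glcm_spec <- function(levels = 8L,
                      offsets = list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L)),
                      symmetric = TRUE, normalized = TRUE) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) abort_validation("glcm levels must be >= 2")
  if (length(offsets) < 1L) abort_validation("at least one offset is required")
  for (off in offsets) {
    if (length(off) != 2L || all(off == 0L)) abort_validation("offsets must be nonzero length-2 shifts")
  }
  structure(list(levels = levels, offsets = lapply(offsets, as.integer),
                 symmetric = isTRUE(symmetric), normalized = isTRUE(normalized)),
            class = "glcm_spec")
}

# equal-width quantization of [0,1] into 0..levels-1; 1.0 goes to the top bin
quantize_gray <- function(img, levels) {
  q <- floor(img * levels)
  q[q > levels - 1L] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' Compute gray-level co-occurrence matrices
#'
#' Entry `(i, j)` of the matrix for displacement `(dr, dc)` counts pixel
#' pairs whose quantized values are `i - 1` at `(r, c)` and `j - 1` at
#' `(r + dr, c + dc)`.
#'
#' @param img grayscale image matrix.
#' @param spec a [glcm_spec()].
#' @return list of `levels x levels` matrices, one per offset.
#' @export
compute_glcm <- function(img, spec = glcm_spec()) {
  assert_gray_image(img)
  L <- spec$levels
  q <- quantize_gray(img, L)
  h <- nrow(q); w <- ncol(q)
  out <- vector("list", length(spec$offsets))
  for (oi in seq_along(spec$offsets)) {
    off <- spec$offsets[[oi]]
    dr <- off[1L]; dc <- off[2L]
    if (abs(dr) >= h || abs(dc) >= w) {
      abort_validation(sprintf("image %dx%d too small for offset (%d,%d)", h, w, dr, dc))
    }
    r0 <- max(1L, 1L - dr):min(h, h - dr)
    c0 <- max(1L, 1L - dc):min(w, w - dc)
    a <- q[r0, c0, drop = FALSE]
    b <- q[r0 + dr, c0 + dc, drop = FALSE]
    counts <- tabulate(a * L + b + 1L, nbins = L * L)
    m <- matrix(counts, L, L, byrow = TRUE)  # row index = first pixel's level
    if (spec$symmetric) m <- m + t(m)
    if (spec$normalized) {
      s <- sum(m)
      if (s > 0) m <- m / s
    }
    out[[oi]] <- m
  }
  out
}

#' Summary statistics of a normalized co-occurrence matrix
#'
#' Returns contrast, correlation, energy, homogeneity and entropy:
#' \deqn{contrast = \sum (i-j)^2 p_{ij}, \quad energy = \sum p_{ij}^2,}
#' \deqn{homogeneity = \sum p_{ij} / (1 + |i-j|), \quad
#'       entropy = -\sum p_{ij} \log_2 p_{ij}}
#' and the Pearson correlation of row and column indices under `p` (defined
#' as 0 when either marginal standard deviation vanishes).
#'
#' @param glcm nonnegative matrix summing to 1.
#' @return named numeric vector of the five statistics.
#' @export
glcm_stats <- function(glcm) {
  if (!is.matrix(glcm) || any(glcm < 0) || abs(sum(glcm) - 1) > 1e-8) {
    abort_validation("glcm_stats requires a nonnegative matrix summing to 1")
  }
  L <- nrow(glcm)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  contrast <- sum((i - j)^2 * glcm)
  energy <- sum(glcm^2)
  homogeneity <- sum(glcm / (1 + abs(i - j)))
  p_nz <- glcm[glcm > 0]
  entropy <- -sum(p_nz * log2(p_nz))
  mu_i <- sum(i * glcm); mu_j <- sum(j * glcm)
  var_i <- sum((i - mu_i)^2 * glcm); var_j <- sum((j - mu_j)^2 * glcm)
  correlation <- if (var_i <= 0 || var_j <= 0) 0 else
    sum((i - mu_i) * (j - mu_j) * glcm) / sqrt(var_i * var_j)
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy)
}

# 20 GLCM features: 5 statistics for each of the 4 default offsets
glcm_features <- function(img, spec = glcm_spec()) {
  mats <- compute_glcm(img, spec)
  out <- unlist(lapply(seq_along(mats), function(oi) {
    s <- glcm_stats(mats[[oi]])
    names(s) <- sprintf("glcm_%s_o%d", names(s), oi)
    s
  }))
  out
}
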