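# Assembly of the 90-feature hybrid vector.
#
# Default budget per extractor: GLCM 20, LBP 10, RLBP 10, LTP 10 (5 upper +
# 5 lower, uniform bins merged pairwise), region metrics 16, BIBS 8, Gabor 8,
# log-energy 4, PCA-filter 1, ICA-filter 1, fractal dimension 1, shape
# signature 1 — 90 in total.

#' Default configuration of the hybrid feature extractor
#'
#' @param enable character vector of extractor names to enable (default all
#'   twelve).
#' @param glcm,lbp,gabor,log_energy component specs.
#' @param ltp_t ternary threshold for the LTP extractor.
#' @param rlbp_n_radii radii averaged by the radial LBP.
#' @param bibs_rays rays of the boundary signature.
#' @param filter_patch tile size of the PCA/ICA filter features.
#' @param filter_seed seed of the ICA filter feature's random start.
#' @return a `feature_config` list.
#' @export
feature_config <- function(enable = c("glcm", "lbp", "rlbp", "ltp", "sgm",
                                      "bibs", "gabor", "log_energy",
                                      "pca_filter", "ica_filter", "fractal",
                                      "shape_signature"),
                           glcm = glcm_spec(), lbp = lbp_spec(),
                           gabor = gabor_spec(),
                           log_energy = log_energy_spec(),
                           ltp_t = 0.1, rlbp_n_radii = 3L, bibs_rays = 8L,
                           filter_patch = 8L, filter_seed = 0L) {
  structure(list(enable = enable, glcm = glcm, lbp = lbp, gabor = gabor,
                 log_energy = log_energy, ltp_t = ltp_t,
                 rlbp_n_radii = as.integer(rlbp_n_radii),
                 bibs_rays = as.integer(bibs_rays),
                 filter_patch = as.integer(filter_patch),
                 filter_seed = as.integer(filter_seed)),
            class = "feature_config")
}

# merge a P+2-bin uniform histogram pairwise into 5 bins (LTP compression)
merge_bins_pairwise <- function(h) {
  n <- length(h)
  grp <- (seq_len(n) - 1L) %/% 2L
  as.numeric(tapply(h, grp, sum))
}

#' Names of the features produced under a configuration
#'
#' @param config a [feature_config()].
#' @return character vector of unique, stable feature names in extraction
#'   order.
#' @export
feature_names <- function(config = feature_config()) {
  nb <- lbp_n_bins(config$lbp)
  reg <- list(
    glcm = as.vector(t(outer(seq_along(config$glcm$offsets),
                             c("contrast", "correlation", "energy", "homogeneity", "entropy"),
                             function(o, s) sprintf("glcm_%s_o%d", s, o)))),
    lbp = sprintf("lbp_b%02d", seq_len(nb)),
    rlbp = sprintf("rlbp_b%02d", seq_len(nb)),
    ltp = c(sprintf("ltp_up_m%d", 1:5), sprintf("ltp_lo_m%d", 1:5)),
    sgm = paste0("sgm_", c("area", "centroid_row", "centroid_col", "convex_area",
                           "equiv_diameter", "euler", "extent", "major_axis",
                           "minor_axis", "orientation", "eccentricity", "perimeter",
                           "filled_area", "solidity", "bbox_height", "bbox_width")),
    bibs = sprintf("bibs_r%d", seq_len(config$bibs_rays)),
    gabor = as.vector(t(outer(seq_along(config$gabor$frequencies),
                              seq_along(config$gabor$orientations),
                              function(f, t) sprintf("gabor_f%d_t%d", f, t)))),
    log_energy = c("le_RA", "le_RH", "le_RV", "le_RD"),
    pca_filter = "pca_filter",
    ica_filter = "ica_filter",
    fractal = "fractal_dim",
    shape_signature = "shape_aspect"
  )
  unlist(reg[config$enable], use.names = FALSE)
}

#' Extract the hybrid feature vector of one image
#'
#' Runs every enabled extractor and concatenates the results in fixed
#' registry order (90 values under the default configuration). Non-finite
#' values are substituted by 0 with a warning, so degenerate images do not
#' break batch pipelines.
#'
#' @param img grayscale image matrix (at least 16x16 under the defaults).
#' @param config a [feature_config()].
#' @return named numeric vector of features.
#' @export
extract_feature_vector <- function(img, config = feature_config()) {
  assert_gray_image(img, min_dim = 8L)
  need_mask <- any(c("sgm", "bibs", "fractal", "shape_signature") %in% config$enable)
  mask <- NULL
  run <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("feature extractor '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (need_mask) mask <- run("binarize", function() binarize_object(img))
  pieces <- list()
  for (ex in config$enable) {
    pieces[[ex]] <- switch(ex,
      glcm = run(ex, function() glcm_features(img, config$glcm)),
      lbp = run(ex, function() lbp_histogram(img, config$lbp)),
      rlbp = run(ex, function() rlbp_histogram(img, config$lbp, config$rlbp_n_radii)),
      ltp = run(ex, function() {
        hs <- ltp_histograms(img, config$lbp, config$ltp_t)
        c(merge_bins_pairwise(hs$upper), merge_bins_pairwise(hs$lower))
      }),
      sgm = run(ex, function() region_metrics(mask)),
      bibs = run(ex, function() bibs_signature(mask, config$bibs_rays)),
      gabor = run(ex, function() gabor_features(img, config$gabor)),
      log_energy = run(ex, function() log_energy(img, config$log_energy)),
      pca_filter = run(ex, function() pca_filter_feature(img, config$filter_patch,
                                                         config$filter_seed)),
      ica_filter = run(ex, function() ica_filter_feature(img, config$filter_patch,
                                                         config$filter_seed)),
      fractal = run(ex, function() fractal_dimension(mask)),
      shape_signature = run(ex, function() shape_signature_aspect(mask)),
      abort_validation(sprintf("unknown extractor '%s'", ex))
    )
  }
  v <- unlist(pieces, use.names = FALSE)
  names(v) <- feature_names(config)
  bad <- !is.finite(v)
  if (any(bad)) {
    warning(sprintf("non-finite features substituted by 0: %s",
                    paste(names(v)[bad], collapse = ", ")))
    v[bad] <- 0
  }
  v
}

#' Extract the feature matrix of a labelled dataset
#'
#' @param ds a `labeled_dataset`.
#' @param config a [feature_config()].
#' @param verbose log a progress line every 100 images (to stderr).
#' @return list with `X` (n x d feature matrix with registry column names)
#'   and `y` (integer labels).
#' @export
extract_feature_matrix <- function(ds, config = feature_config(), verbose = FALSE) {
  if (length(ds) == 0L) abort_validation("dataset is empty")
  nms <- feature_names(config)
  X <- matrix(NA_real_, length(ds), length(nms), dimnames = list(NULL, nms))
  for (i in seq_len(length(ds))) {
    X[i, ] <- tryCatch(extract_feature_vector(ds$images[[i]], config),
                       error = function(e) {
                         stop(sprintf("image %d: %s", i, conditionMessage(e)), call. = FALSE)
                       })
    if (verbose && i %% 100L == 0L) {
      message(sprintf("extracted %d / %d images", i, length(ds)))
    }
  }
  zero_var <- apply(X, 2L, stats::var) < 1e-24
  if (verbose && any(zero_var)) {
    message(sprintf("zero-variance columns: %s", paste(nms[zero_var], collapse = ", ")))
  }
  list(X = X, y = ds$labels)
}
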