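#' @keywords internal
"_PACKAGE"

# Shared validation helpers and seeded-RNG scaffolding.

severity_class_names <- function() {
  c("NonDemented", "VeryMild", "Mild", "Moderate")
}

n_severity_classes <- function() 4L

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("mrigrade_validation_error", "error")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("mrigrade_io_error", "error")))
}

#' Validate a grayscale image matrix
#'
#' A `GrayImage` in this package is a plain numeric matrix with intensities in
#' `[0, 1]`, rows indexing image rows from the top. Most feature extractors
#' require at least 8 pixels along each side.
#'
#' @param img numeric matrix.
#' @param min_dim minimum number of rows and columns required.
#' @return `img`, invisibly, after validation.
#' @export
assert_gray_image <- function(img, min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort_validation("image must be a numeric matrix")
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    abort_validation(sprintf("image must be at least %dx%d pixels", min_dim, min_dim))
  }
  if (any(!is.finite(img))) abort_validation("image contains non-finite values")
  if (min(img) < 0 || max(img) > 1) {
    abort_validation("image intensities must lie in [0, 1]")
  }
  invisible(img)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a global seed by a fixed offset, kept within the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# round-half-up for split bookkeeping (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
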