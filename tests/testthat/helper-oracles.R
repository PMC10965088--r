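# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with plain loops and definitions, sharing no code
# with the package internals beyond the documented tie-break conventions.

random_image <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

# --- LBP family: per-pixel loop with its own bilinear interpolation -------

oracle_bilinear <- function(img, y, x) {
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  y1 <- min(y0 + 1, nrow(img)); x1 <- min(x0 + 1, ncol(img))
  (1 - fy) * ((1 - fx) * img[y0, x0] + fx * img[y0, x1]) +
    fy * ((1 - fx) * img[y1, x0] + fx * img[y1, x1])
}

oracle_lbp_codes <- function(img, radius = 1, P = 8) {
  m <- ceiling(radius)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h - 2 * m, w - 2 * m)
  for (r in (m + 1):(h - m)) {
    for (c in (m + 1):(w - m)) {
      code <- 0
      for (p in 0:(P - 1)) {
        a <- 2 * pi * p / P
        yy <- r - radius * sin(a)
        xx <- c + radius * cos(a)
        if (abs(yy - round(yy)) < 1e-9) yy <- round(yy)
        if (abs(xx - round(xx)) < 1e-9) xx <- round(xx)
        v <- oracle_bilinear(img, yy, xx)
        if (v - img[r, c] >= -1e-9) code <- code + 2^p
      }
      out[r - m, c - m] <- code
    }
  }
  out
}

oracle_rlbp_codes <- function(img, n_radii = 3, P = 8) {
  m <- n_radii
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h - 2 * m, w - 2 * m)
  for (r in (m + 1):(h - m)) {
    for (c in (m + 1):(w - m)) {
      code <- 0
      for (p in 0:(P - 1)) {
        a <- 2 * pi * p / P
        acc <- 0
        for (rad in 1:n_radii) {
          yy <- r - rad * sin(a)
          xx <- c + rad * cos(a)
          if (abs(yy - round(yy)) < 1e-9) yy <- round(yy)
          if (abs(xx - round(xx)) < 1e-9) xx <- round(xx)
          acc <- acc + oracle_bilinear(img, yy, xx)
        }
        if (acc / n_radii - img[r, c] >= -1e-9) code <- code + 2^p
      }
      out[r - m, c - m] <- code
    }
  }
  out
}

oracle_ltp_codes <- function(img, t, radius = 1, P = 8) {
  m <- ceiling(radius)
  h <- nrow(img); w <- ncol(img)
  up <- lo <- matrix(NA_real_, h - 2 * m, w - 2 * m)
  for (r in (m + 1):(h - m)) {
    for (c in (m + 1):(w - m)) {
      cu <- cl <- 0
      for (p in 0:(P - 1)) {
        a <- 2 * pi * p / P
        yy <- r - radius * sin(a)
        xx <- c + radius * cos(a)
        if (abs(yy - round(yy)) < 1e-9) yy <- round(yy)
        if (abs(xx - round(xx)) < 1e-9) xx <- round(xx)
        v <- oracle_bilinear(img, yy, xx)
        if (v - (img[r, c] + t) >= -1e-9) cu <- cu + 2^p
        if (v - (img[r, c] - t) <= 1e-9) cl <- cl + 2^p
      }
      up[r - m, c - m] <- cu
      lo[r - m, c - m] <- cl
    }
  }
  list(upper = up, lower = lo)
}

# --- GLCM by explicit pair enumeration ------------------------------------

oracle_glcm <- function(img, levels, offset, symmetric = TRUE, normalized = TRUE) {
  q <- pmin(floor(img * levels), levels - 1)
  h <- nrow(img); w <- ncol(img)
  m <- matrix(0, levels, levels)
  for (r in 1:h) {
    for (c in 1:w) {
      rr <- r + offset[1]; cc <- c + offset[2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
        m[q[r, c] + 1, q[rr, cc] + 1] <- m[q[r, c] + 1, q[rr, cc] + 1] + 1
      }
    }
  }
  if (symmetric) m <- m + t(m)
  if (normalized && sum(m) > 0) m <- m / sum(m)
  m
}

# --- exhaustive best twoing split -----------------------------------------

oracle_best_split <- function(X, y, n_classes) {
  best <- list(score = -Inf)
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (v in seq_len(length(vals) - 1)) {
      thr <- (vals[v] + vals[v + 1]) / 2
      left <- X[, j] <= thr
      lc <- tabulate(y[left], n_classes)
      rc <- tabulate(y[!left], n_classes)
      sc <- twoing_score(lc, rc)
      if (sc > best$score + 1e-15) best <- list(feature = j, threshold = thr, score = sc)
    }
  }
  best
}

# --- brute-force KNN ------------------------------------------------------

oracle_knn <- function(Xtr, ytr, Xte, k, metric, n_classes = 4) {
  pred <- integer(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    d <- numeric(nrow(Xtr))
    for (j in seq_len(nrow(Xtr))) {
      if (metric == "euclidean") {
        d[j] <- sqrt(sum((Xte[i, ] - Xtr[j, ])^2))
      } else {
        sx <- sd(Xte[i, ]); sy <- sd(Xtr[j, ])
        d[j] <- if (sx < 1e-12 || sy < 1e-12) 1 else 1 - cor(Xte[i, ], Xtr[j, ])
      }
    }
    nb <- order(d, seq_along(d))[1:k]
    votes <- tabulate(ytr[nb], n_classes)
    pred[i] <- which.max(votes)
  }
  pred
}

# --- straight-line transliteration of the log-energy pseudo-code ----------

oracle_log_energy <- function(img, level, epsilon = 1e-12) {
  fftshift <- function(x) {
    h <- nrow(x); w <- ncol(x)
    x[c((floor(h / 2) + 1):h, seq_len(floor(h / 2))),
      c((floor(w / 2) + 1):w, seq_len(floor(w / 2)))]
  }
  dwt_haar <- function(x) {
    h <- nrow(x) - nrow(x) %% 2; w <- ncol(x) - ncol(x) %% 2
    x <- x[1:h, 1:w]
    o <- seq(1, h, 2); e <- seq(2, h, 2)
    lo <- (x[o, , drop = FALSE] + x[e, , drop = FALSE]) / sqrt(2)
    hi <- (x[o, , drop = FALSE] - x[e, , drop = FALSE]) / sqrt(2)
    oc <- seq(1, w, 2); ec <- seq(2, w, 2)
    list(a = (lo[, oc, drop = FALSE] + lo[, ec, drop = FALSE]) / sqrt(2),
         h = (hi[, oc, drop = FALSE] + hi[, ec, drop = FALSE]) / sqrt(2),
         v = (lo[, oc, drop = FALSE] - lo[, ec, drop = FALSE]) / sqrt(2),
         d = (hi[, oc, drop = FALSE] - hi[, ec, drop = FALSE]) / sqrt(2))
  }
  A <- H <- V <- D <- numeric(level)
  im <- img
  for (i in 1:level) {
    s <- dwt_haar(im)
    A[i] <- mean(log(abs(fftshift(fft(s$a))) + epsilon))
    H[i] <- mean(log(abs(fftshift(fft(s$h))) + epsilon))
    V[i] <- mean(log(abs(fftshift(fft(s$v))) + epsilon))
    D[i] <- mean(log(abs(fftshift(fft(s$d))) + epsilon))
    im <- s$a
  }
  c(sum(diff(A)), sum(diff(H)), sum(diff(V)), sum(diff(D)))
}

# 4-class well-separated Gaussian blobs for classifier checks
make_blobs <- function(n_per_class = 50, d = 2, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, 4, d)
  centers[2, 1] <- sep; centers[3, 2] <- sep; centers[4, 1:2] <- sep
  X <- do.call(rbind, lapply(1:4, function(cc) {
    sweep(matrix(rnorm(n_per_class * d), n_per_class, d), 2, centers[cc, ], "+")
  }))
  list(X = X, y = rep(1:4, each = n_per_class))
}
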