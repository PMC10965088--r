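# A compact 20-layer convolutional network for four-class severity grading,
# implemented directly on base R arrays: convolutions are im2col gathers
# followed by BLAS matrix multiplies, so training stays practical on one CPU.

#' Build the 20-layer CNN architecture
#'
#' Layer order: image input; three blocks of
#' `conv(3x3) -> batchnorm -> ReLU -> maxpool(2x2, stride 2)` with 8/16/32
#' filters; a fourth `conv(3x3, 64) -> batchnorm -> ReLU` block without
#' pooling; dropout(0.5); a fully-connected layer with `n_classes` outputs;
#' softmax; classification output — 20 layers in total (4 convolutional,
#' 4 normalization, 4 activation, 3 max-pooling).
#'
#' @param input_size input image side length (square), at least 32 and
#'   divisible by 8 (three 2x2 poolings).
#' @param n_classes number of output classes.
#' @param filters filter counts of the four convolutional layers.
#' @param dropout_rate dropout probability before the dense layer.
#' @return a `cnn_arch`: list with `layers` (ordered layer descriptors),
#'   `input_size`, `n_classes`.
#' @export
build_architecture <- function(input_size = 128L, n_classes = 4L,
                               filters = c(8L, 16L, 32L, 64L),
                               dropout_rate = 0.5) {
  input_size <- as.integer(input_size)
  if (is.na(input_size) || input_size < 32L) {
    abort_validation("input_size must be at least 32 pixels")
  }
  if (input_size %% 8L != 0L) {
    abort_validation("input_size must be divisible by 8 (three 2x2 poolings)")
  }
  stopifnot(length(filters) == 4L)
  ly <- list()
  add <- function(kind, ...) ly[[length(ly) + 1L]] <<- c(list(kind = kind), list(...))
  add("input", size = c(input_size, input_size, 1L))
  ch <- 1L
  for (b in 1:4) {
    add("conv", kernel = 3L, filters = as.integer(filters[b]), in_channels = ch)
    add("batchnorm", channels = as.integer(filters[b]))
    add("relu")
    if (b <= 3L) add("maxpool", size = 2L, stride = 2L)
    ch <- as.integer(filters[b])
  }
  add("dropout", rate = dropout_rate)
  fc_in <- as.integer((input_size / 8L)^2 * filters[4L])
  add("fc", units = as.integer(n_classes), in_features = fc_in)
  add("softmax")
  add("classoutput", classes = as.integer(n_classes))
  structure(list(layers = ly, input_size = input_size,
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate),
            class = "cnn_arch")
}

#' @export
print.cnn_arch <- function(x, ...) {
  kinds <- vapply(x$layers, `[[`, character(1), "kind")
  cat(sprintf("<cnn_arch> %d layers (%s), input %dx%dx1, %d classes\n",
              length(x$layers),
              paste(sprintf("%s:%d", names(table(kinds)), table(kinds)), collapse = " "),
              x$input_size, x$input_size, x$n_classes))
  invisible(x)
}

#' Count CNN layers by kind
#'
#' @param arch a `cnn_arch`.
#' @return named integer vector of layer-kind counts.
#' @export
count_layers <- function(arch) {
  kinds <- vapply(arch$layers, `[[`, character(1), "kind")
  tab <- table(factor(kinds, levels = c("input", "conv", "batchnorm", "relu",
                                        "maxpool", "dropout", "fc", "softmax",
                                        "classoutput")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Training configuration for the CNN
#'
#' @param epochs maximum training epochs.
#' @param train_fraction stratified fraction used for training; 1 disables
#'   the internal holdout.
#' @param learning_rate SGD step size.
#' @param batch_size mini-batch size.
#' @param seed integer seed for the split, weight init, shuffling, dropout.
#' @param stop_at_accuracy optional early stop once the evaluation-mode
#'   training accuracy reaches this value.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 13L, train_fraction = 0.7,
                         learning_rate = 0.01, batch_size = 10L, seed = 0L,
                         stop_at_accuracy = NULL) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) abort_validation("epochs must be >= 1")
  if (train_fraction <= 0 || train_fraction > 1) {
    abort_validation("train_fraction must be in (0, 1]")
  }
  structure(list(epochs = epochs, train_fraction = train_fraction,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 stop_at_accuracy = stop_at_accuracy),
            class = "train_config")
}

# ---- parameter initialisation -------------------------------------------

cnn_init_params <- function(arch) {
  params <- list()
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$kind == "conv") {
      fan_in <- 9L * ly$in_channels
      params[[as.character(i)]] <- list(
        W = matrix(stats::rnorm(fan_in * ly$filters, 0, sqrt(2 / fan_in)),
                   fan_in, ly$filters),
        b = numeric(ly$filters))
    } else if (ly$kind == "batchnorm") {
      params[[as.character(i)]] <- list(
        gamma = rep(1, ly$channels), beta = numeric(ly$channels),
        run_mean = numeric(ly$channels), run_var = rep(1, ly$channels))
    } else if (ly$kind == "fc") {
      params[[as.character(i)]] <- list(
        W = matrix(stats::rnorm(ly$in_features * ly$units, 0,
                                sqrt(2 / ly$in_features)),
                   ly$in_features, ly$units),
        b = numeric(ly$units))
    }
  }
  params
}

# ---- conv via im2col -----------------------------------------------------

# index matrix (H*W*N) x (9*C) into the zero-padded array (H+2, W+2, C, N)
make_im2col_idx <- function(H, W, C, N) {
  Hp <- H + 2L; Wp <- W + 2L
  pix_r <- rep(seq_len(H), times = W)
  pix_c <- rep(seq_len(W), each = H)
  cols <- vector("list", 9L * C)
  j <- 0L
  for (ch in seq_len(C)) {
    for (kc in 1:3) {
      for (kr in 1:3) {
        j <- j + 1L
        cols[[j]] <- (pix_r + kr - 1L) + (pix_c + kc - 2L) * Hp +
          (ch - 1L) * Hp * Wp
      }
    }
  }
  base <- do.call(cbind, cols)
  if (N == 1L) return(base)
  per_img <- Hp * Wp * C
  base[rep(seq_len(H * W), N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * per_img, each = H * W)
}

# memoised per (layer, H, W, C, N) index cache living in the net object
get_idx <- function(cache, H, W, C, N) {
  key <- sprintf("%d_%d_%d_%d", H, W, C, N)
  if (is.null(cache[[key]])) cache[[key]] <- make_im2col_idx(H, W, C, N)
  cache[[key]]
}

pad_batch <- function(X) {
  d <- dim(X)
  Xp <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L], d[4L]))
  Xp[2:(d[1L] + 1L), 2:(d[2L] + 1L), , ] <- X
  Xp
}

conv_forward <- function(X, W, b, cache_env) {
  d <- dim(X)  # H, W, C, N
  idx <- get_idx(cache_env, d[1L], d[2L], d[3L], d[4L])
  Xp <- pad_batch(X)
  col <- matrix(Xp[idx], nrow = nrow(idx))
  out <- col %*% W
  out <- sweep(out, 2L, b, "+")
  Fn <- ncol(W)
  out_arr <- aperm(array(out, c(d[1L], d[2L], d[4L], Fn)), c(1L, 2L, 4L, 3L))
  list(out = out_arr, col = col, idx = idx, in_dim = d)
}

conv_backward <- function(dOut, fwd, W) {
  d <- fwd$in_dim
  Fn <- ncol(W)
  dM <- aperm(dOut, c(1L, 2L, 4L, 3L))      # H, W, N, F
  dim(dM) <- c(d[1L] * d[2L] * d[4L], Fn)
  dW <- crossprod(fwd$col, dM)
  db <- colSums(dM)
  dcol <- dM %*% t(W)
  dXp <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L], d[4L]))
  for (j in seq_len(ncol(dcol))) {
    jj <- fwd$idx[, j]
    dXp[jj] <- dXp[jj] + dcol[, j]
  }
  dX <- dXp[2:(d[1L] + 1L), 2:(d[2L] + 1L), , , drop = FALSE]
  dim(dX) <- d
  list(dX = dX, dW = dW, db = db)
}

# ---- batchnorm / relu / pool / dropout ----------------------------------

bn_forward <- function(X, p, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(X)  # H, W, C, N
  Xm <- aperm(X, c(1L, 2L, 4L, 3L))
  dim(Xm) <- c(d[1L] * d[2L] * d[4L], d[3L])   # rows: positions, cols: channels
  if (training) {
    mu <- colMeans(Xm)
    va <- colMeans(sweep(Xm, 2L, mu)^2)
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
    p$run_var <- (1 - momentum) * p$run_var + momentum * va
  } else {
    mu <- p$run_mean
    va <- p$run_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(Xm, 2L, mu), 2L, istd, "*")
  out <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  out_arr <- aperm(array(out, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
  list(out = out_arr, xhat = xhat, istd = istd, dim = d, params = p)
}

bn_backward <- function(dOut, fwd, p) {
  d <- fwd$dim
  dY <- aperm(dOut, c(1L, 2L, 4L, 3L))
  dim(dY) <- c(d[1L] * d[2L] * d[4L], d[3L])
  m <- nrow(dY)
  dgamma <- colSums(dY * fwd$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, p$gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(fwd$xhat, 2L, colSums(dxhat * fwd$xhat) / m, "*")
  dXm <- sweep(t1 - t2, 2L, fwd$istd, "*")
  dX <- aperm(array(dXm, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_forward <- function(X) {
  d <- dim(X)
  ro <- seq(1L, d[1L], 2L); co <- seq(1L, d[2L], 2L)
  a <- X[ro, co, , , drop = FALSE]
  b <- X[ro, co + 1L, , , drop = FALSE]
  cc <- X[ro + 1L, co, , , drop = FALSE]
  dd <- X[ro + 1L, co + 1L, , , drop = FALSE]
  m <- a; which_q <- array(1L, dim(a))
  upd <- b > m; m[upd] <- b[upd]; which_q[upd] <- 2L
  upd <- cc > m; m[upd] <- cc[upd]; which_q[upd] <- 3L
  upd <- dd > m; m[upd] <- dd[upd]; which_q[upd] <- 4L
  list(out = m, which_q = which_q, in_dim = d)
}

pool_backward <- function(dOut, fwd) {
  d <- fwd$in_dim
  dX <- array(0, d)
  ro <- seq(1L, d[1L], 2L); co <- seq(1L, d[2L], 2L)
  q <- fwd$which_q
  tmp <- array(0, dim(q))
  for (k in 1:4) {
    tmp[] <- 0
    sel <- q == k
    tmp[sel] <- dOut[sel]
    if (k == 1L) dX[ro, co, , ] <- tmp
    else if (k == 2L) dX[ro, co + 1L, , ] <- tmp
    else if (k == 3L) dX[ro + 1L, co, , ] <- tmp
    else dX[ro + 1L, co + 1L, , ] <- tmp
  }
  dX
}

# ---- full forward / backward --------------------------------------------

# X: array (H, W, 1, N). Returns logits (N x K) and per-layer caches when
# training (for the backward pass).
cnn_forward <- function(arch, params, X, training = FALSE, cache_env = NULL,
                        keep = FALSE) {
  caches <- if (keep) vector("list", length(arch$layers))
  cur <- X
  flat_dim <- NULL
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    key <- as.character(i)
    if (ly$kind == "conv") {
      fw <- conv_forward(cur, params[[key]]$W, params[[key]]$b, cache_env)
      if (keep) caches[[i]] <- fw
      cur <- fw$out
    } else if (ly$kind == "batchnorm") {
      fw <- bn_forward(cur, params[[key]], training)
      params[[key]] <- fw$params
      if (keep) caches[[i]] <- fw
      cur <- fw$out
    } else if (ly$kind == "relu") {
      mask <- cur > 0
      if (keep) caches[[i]] <- mask
      cur <- cur * mask
    } else if (ly$kind == "maxpool") {
      fw <- pool_forward(cur)
      if (keep) caches[[i]] <- fw
      cur <- fw$out
    } else if (ly$kind == "dropout") {
      flat_dim <- dim(cur)
      N <- flat_dim[4L]
      Xf <- matrix(aperm(cur, c(4L, 1L, 2L, 3L)), nrow = N)  # N x features
      if (training && ly$rate > 0) {
        mask <- matrix(stats::runif(length(Xf)) >= ly$rate, nrow(Xf), ncol(Xf)) /
          (1 - ly$rate)
        Xf <- Xf * mask
        if (keep) caches[[i]] <- list(mask = mask, flat_dim = flat_dim)
      } else if (keep) {
        caches[[i]] <- list(mask = NULL, flat_dim = flat_dim)
      }
      cur <- Xf
    } else if (ly$kind == "fc") {
      if (keep) caches[[i]] <- cur
      cur <- sweep(cur %*% params[[key]]$W, 2L, params[[key]]$b, "+")
    }
    # softmax / classoutput handled by the loss and argmax below
  }
  list(logits = cur, caches = caches, params = params)
}

softmax_rows <- function(Z) {
  m <- apply(Z, 1L, max)
  e <- exp(Z - m)
  e / rowSums(e)
}

cnn_backward <- function(arch, params, fwd, y_onehot, lr) {
  N <- nrow(fwd$logits)
  P <- softmax_rows(fwd$logits)
  dcur <- (P - y_onehot) / N
  for (i in rev(seq_along(arch$layers))) {
    ly <- arch$layers[[i]]
    key <- as.character(i)
    if (ly$kind == "fc") {
      Xin <- fwd$caches[[i]]
      dW <- crossprod(Xin, dcur)
      db <- colSums(dcur)
      dcur <- dcur %*% t(params[[key]]$W)
      params[[key]]$W <- params[[key]]$W - lr * dW
      params[[key]]$b <- params[[key]]$b - lr * db
    } else if (ly$kind == "dropout") {
      ca <- fwd$caches[[i]]
      if (!is.null(ca$mask)) dcur <- dcur * ca$mask
      d <- ca$flat_dim
      dcur <- aperm(array(t(dcur), c(d[1L], d[2L], d[3L], d[4L])),
                    c(1L, 2L, 3L, 4L))
      # t(dcur) columns are per-image flattened (H,W,C); rebuild (H,W,C,N)
      dim(dcur) <- d
    } else if (ly$kind == "maxpool") {
      dcur <- pool_backward(dcur, fwd$caches[[i]])
    } else if (ly$kind == "relu") {
      dcur <- dcur * fwd$caches[[i]]
    } else if (ly$kind == "batchnorm") {
      bk <- bn_backward(dcur, fwd$caches[[i]], params[[key]])
      params[[key]]$gamma <- params[[key]]$gamma - lr * bk$dgamma
      params[[key]]$beta <- params[[key]]$beta - lr * bk$dbeta
      dcur <- bk$dX
    } else if (ly$kind == "conv") {
      bk <- conv_backward(dcur, fwd$caches[[i]], params[[key]]$W)
      params[[key]]$W <- params[[key]]$W - lr * bk$dW
      params[[key]]$b <- params[[key]]$b - lr * bk$db
      dcur <- bk$dX
    }
  }
  params
}

# stack dataset images into an input array, rescaling to the network size
dataset_to_array <- function(images, input_size) {
  N <- length(images)
  X <- array(0, c(input_size, input_size, 1L, N))
  for (i in seq_len(N)) {
    X[, , 1L, i] <- rescale(images[[i]], input_size)
  }
  X
}

cnn_eval_forward <- function(arch, params, X, cache_env, chunk = 32L) {
  N <- dim(X)[4L]
  out <- matrix(0, N, arch$n_classes)
  for (s in seq(1L, N, chunk)) {
    e <- min(s + chunk - 1L, N)
    fw <- cnn_forward(arch, params, X[, , , s:e, drop = FALSE],
                      training = FALSE, cache_env = cache_env)
    out[s:e, ] <- fw$logits
  }
  out
}

#' Train the CNN on a labelled image dataset
#'
#' Performs an internal stratified split (unless `train_fraction = 1`),
#' rescales images to the architecture's input size, and minimises the
#' softmax cross-entropy with plain mini-batch stochastic gradient descent.
#' All randomness (split, weight init, shuffling, dropout) derives from
#' `cfg$seed`, so runs are reproducible.
#'
#' @param ds a `labeled_dataset`.
#' @param arch a [build_architecture()] result.
#' @param cfg a [train_config()].
#' @param verbose print a line per epoch.
#' @return a `severity_cnn`: list with `params`, `arch`, `cfg`, `curves`
#'   (per-epoch data.frame of mean batch loss and evaluation-mode training
#'   accuracy), `train` and `test` (the internal split as
#'   `labeled_dataset`s; `test` is `NULL` without holdout).
#' @export
train_cnn <- function(ds, arch = build_architecture(), cfg = train_config(),
                      verbose = FALSE) {
  if (length(unique(ds$labels)) < arch$n_classes) {
    abort_validation("every class must be present in the training data")
  }
  if (cfg$train_fraction < 1) {
    sp <- stratified_split(ds, cfg$train_fraction, seed = derive_seed(cfg$seed, 11L))
    train_ds <- sp$train; test_ds <- sp$test
  } else {
    train_ds <- ds; test_ds <- NULL
  }
  X <- dataset_to_array(train_ds$images, arch$input_size)
  y <- train_ds$labels
  n <- length(y)
  K <- arch$n_classes
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  cache_env <- new.env(parent = emptyenv())
  curves <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  params <- NULL
  with_seed(derive_seed(cfg$seed, 23L), {
    params <- cnn_init_params(arch)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (s in seq(1L, n, cfg$batch_size)) {
        e <- min(s + cfg$batch_size - 1L, n)
        bi <- ord[s:e]
        fw <- cnn_forward(arch, params, X[, , , bi, drop = FALSE],
                          training = TRUE, cache_env = cache_env, keep = TRUE)
        params <- fw$params
        P <- softmax_rows(fw$logits)
        ep_loss <- ep_loss - mean(log(pmax(P[cbind(seq_along(bi), y[bi])], 1e-12)))
        n_batches <- n_batches + 1L
        params <- cnn_backward(arch, params, fw,
                               Y[bi, , drop = FALSE], cfg$learning_rate)
      }
      logits <- cnn_eval_forward(arch, params, X, cache_env)
      acc <- mean(max.col(logits, ties.method = "first") == y)
      curves <- rbind(curves, data.frame(epoch = ep, loss = ep_loss / n_batches,
                                         accuracy = acc))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  train acc %.3f",
                        ep, ep_loss / n_batches, acc))
      }
      if (!is.null(cfg$stop_at_accuracy) && acc >= cfg$stop_at_accuracy) break
    }
  })
  structure(list(params = params, arch = arch, cfg = cfg, curves = curves,
                 train = train_ds, test = test_ds),
            class = c("severity_cnn", "severity_classifier"))
}

#' Predict severity classes with a trained CNN
#'
#' @param object a `severity_cnn`.
#' @param newdata a `labeled_dataset`, a list of grayscale image matrices,
#'   or a single matrix; images are rescaled to the network's input size.
#' @param type `"class"` for integer labels (argmax of the softmax scores,
#'   ties towards the lowest label) or `"score"` for the n x K softmax
#'   matrix (rows sum to 1).
#' @param ... unused.
#' @return integer labels or a score matrix.
#' @export
predict.severity_cnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  images <- if (inherits(newdata, "labeled_dataset")) newdata$images
            else if (is.matrix(newdata)) list(newdata)
            else newdata
  X <- dataset_to_array(images, object$arch$input_size)
  cache_env <- new.env(parent = emptyenv())
  logits <- cnn_eval_forward(object$arch, object$params, X, cache_env)
  if (type == "score") return(softmax_rows(logits))
  max.col(softmax_rows(logits), ties.method = "first")
}

#' @export
print.severity_cnn <- function(x, ...) {
  last <- x$curves[nrow(x$curves), ]
  cat(sprintf("<severity_cnn> input %dx%d, %d epochs trained, final train acc %.3f\n",
              x$arch$input_size, x$arch$input_size, nrow(x$curves), last$accuracy))
  invisible(x)
}

#' Save / load CNN weights as JSON
#'
#' @param net a `severity_cnn`.
#' @param path output path.
#' @return `path` (save) or a `severity_cnn` (load).
#' @export
save_cnn <- function(net, path) {
  obj <- list(arch = list(input_size = net$arch$input_size,
                          n_classes = net$arch$n_classes,
                          filters = vapply(Filter(function(l) l$kind == "conv",
                                                  net$arch$layers),
                                           `[[`, integer(1), "filters"),
                          dropout_rate = net$arch$dropout_rate),
              params = lapply(net$params, function(p) lapply(p, as.vector)),
              param_dims = lapply(net$params, function(p)
                lapply(p, function(v) if (is.matrix(v)) dim(v) else length(v))),
              curves = net$curves)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- build_architecture(obj$arch$input_size, obj$arch$n_classes,
                             obj$arch$filters, obj$arch$dropout_rate)
  params <- obj$params
  for (key in names(params)) {
    for (nm in names(params[[key]])) {
      d <- obj$param_dims[[key]][[nm]]
      v <- as.numeric(params[[key]][[nm]])
      params[[key]][[nm]] <- if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v
    }
  }
  structure(list(params = params, arch = arch, cfg = NULL,
                 curves = as.data.frame(obj$curves), train = NULL, test = NULL),
            class = c("severity_cnn", "severity_classifier"))
}
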