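# CNN architecture, training dynamics, and prediction contracts.

test_that("the built architecture has 20 layers with the 4/4/4/3 kind counts", {
  arch <- build_architecture(64)
  expect_length(arch$layers, 20)
  counts <- count_layers(arch)
  expect_equal(unname(counts[c("conv", "batchnorm", "relu", "maxpool")]),
               c(4L, 4L, 4L, 3L))
  expect_equal(unname(counts["dropout"]), 1L)
  kinds <- vapply(arch$layers, `[[`, character(1), "kind")
  expect_identical(kinds[c(1, 18, 19, 20)], c("input", "fc", "softmax", "classoutput"))
  fc <- arch$layers[[which(kinds == "fc")]]
  expect_equal(fc$units, 4L)
  expect_error(build_architecture(24), class = "mrigrade_validation_error")
})

test_that("a gradient step decreases the loss on a fixed batch", {
  ds <- generate_dataset(2, 32, seed = 3)   # 8 images
  arch <- build_architecture(32)
  X <- mrigrade:::dataset_to_array(ds$images, 32L)
  y <- ds$labels
  Y <- matrix(0, 8, 4); Y[cbind(1:8, y)] <- 1
  cache <- new.env(parent = emptyenv())
  params <- mrigrade:::with_seed(1, mrigrade:::cnn_init_params(arch))
  loss_of <- function(p) {
    fw <- mrigrade:::cnn_forward(arch, p, X, training = TRUE, cache_env = cache,
                                 keep = TRUE)
    P <- mrigrade:::softmax_rows(fw$logits)
    list(loss = -mean(log(pmax(P[cbind(1:8, y)], 1e-12))), fw = fw)
  }
  set.seed(11)  # fixes the dropout mask stream
  l0 <- loss_of(params)
  params2 <- mrigrade:::cnn_backward(arch, l0$fw$params, l0$fw, Y, lr = 1e-3)
  set.seed(11)
  l1 <- loss_of(params2)
  expect_lt(l1$loss, l0$loss)
})

test_that("training is seed-deterministic and overfits a small phantom set", {
  ds <- generate_dataset(10, 32, seed = 5)  # 40 images
  arch <- build_architecture(32)
  cfg1 <- train_config(epochs = 1, train_fraction = 1, seed = 7)
  n1 <- train_cnn(ds, arch, cfg1)
  n2 <- train_cnn(ds, arch, cfg1)
  expect_equal(n1$curves$loss[1], n2$curves$loss[1])   # identical first-epoch loss

  cfg <- train_config(epochs = 100, train_fraction = 1, seed = 7,
                      stop_at_accuracy = 1.0)
  net <- train_cnn(ds, arch, cfg)
  final <- net$curves[nrow(net$curves), ]
  expect_equal(final$accuracy, 1.0)
  expect_lt(final$loss, net$curves$loss[1])            # descent sanity

  # prediction contracts
  sc <- predict(net, ds, type = "score")
  expect_equal(rowSums(sc), rep(1, 40), tolerance = 1e-6)
  lbl <- predict(net, ds)
  expect_identical(lbl, max.col(sc, ties.method = "first"))
  # batch prediction equals per-image prediction
  one <- predict(net, ds$images[[13]], type = "score")
  expect_equal(drop(one), sc[13, ], tolerance = 1e-9)

  # weights survive a JSON round trip
  f <- withr::local_tempfile(fileext = ".json")
  save_cnn(net, f)
  back <- load_cnn(f)
  expect_equal(predict(back, ds, type = "score"), sc, tolerance = 1e-7)
})

test_that("training errors out when a class is absent", {
  ds <- generate_dataset(3, 32, seed = 2)
  ds3 <- mrigrade:::subset_dataset(ds, which(ds$labels != 4L))
  expect_error(train_cnn(ds3, build_architecture(32), train_config(epochs = 1)),
               class = "mrigrade_validation_error")
})
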