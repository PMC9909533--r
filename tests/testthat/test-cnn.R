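small_cfg <- function(iterations = 50L, ...) {
  cnn_config(conv1_filters = 4L, conv2_filters = 6L, fc_width = 16L,
             iterations = iterations, log_every = 10L, batch_size = NULL,
             ...)
}

test_that("feature grids place standardized values row-major with zero padding", {
  X <- matrix(rnorm(50), 5, 10)
  nz <- fit_feature_normalizer(X)
  G <- features_to_grid(X, nz)
  expect_identical(dim(G), c(5L, 36L))
  expect_true(all(G[, 11:36] == 0))
  Z <- scale(X)
  expect_equal(G[, 1:10], unclass(Z), ignore_attr = TRUE)
  # a lone unit feature lands in its own cell
  nz1 <- structure(list(mean = rep(0, 10), sd = rep(1, 10),
                        n_features = 10L), class = "feature_normalizer")
  for (k in c(1, 7, 10)) {
    v <- rep(0, 10); v[k] <- 1
    g <- features_to_grid(matrix(v, 1), nz1)
    expect_equal(which(g != 0), k)
  }
  # batch order preserved
  expect_equal(features_to_grid(X[3, , drop = FALSE], nz), G[3, , drop = FALSE])
  expect_error(features_to_grid(X, list()), "normalizer")
})

test_that("the parameter count matches layer-shape arithmetic", {
  # conv(2x2x1 -> 16) + conv(2x2x16 -> 32) + dense(3*3*32 -> 512) + out
  expected <- (2 * 2 * 1 * 16 + 16) + (2 * 2 * 16 * 32 + 32) +
    (3 * 3 * 32 * 512 + 512) + (512 + 1)
  expect_identical(cnn_parameter_count(cnn_config()), as.integer(expected))
  expect_identical(expected, 150641)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- small_cfg(seed = 20)
  geom <- leafspec:::cnn_geometry(cfg$input_side)
  set.seed(20)
  params <- leafspec:::cnn_init_params(cfg)
  G <- matrix(rnorm(4 * 36), 4, 36)
  y <- rnorm(4)
  loss_fn <- function(p) {
    pred <- leafspec:::cnn_forward(p, G, geom)
    mean((pred - y)^2)
  }
  fw <- leafspec:::cnn_forward(params, G, geom, keep = TRUE)
  gr <- leafspec:::cnn_backward(params, fw, geom,
                                2 * (fw$pred - y) / length(y))
  eps <- 1e-6
  for (nm in c("W1", "W2", "Wf", "Wo", "b1", "bf")) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (j in idx) {
      up <- params; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- params; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      expect_equal(gr[[nm]][j], num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  set.seed(21)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20, 1, 0.5)
  f1 <- residue_cnn(X, y, small_cfg(seed = 5))
  f2 <- residue_cnn(X, y, small_cfg(seed = 5))
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1, X), predict(f2, X))
})

test_that("training reduces the loss on a learnable signal", {
  set.seed(22)
  X <- matrix(rnorm(300), 30, 10)
  y <- 1 + 0.8 * X[, 2] - 0.5 * X[, 5]
  fit <- residue_cnn(X, y, small_cfg(iterations = 400, seed = 9))
  expect_lt(tail(fit$log$loss, 1), fit$log$loss[1])
  expect_identical(fit$log$iteration,
                   c(seq(10L, 400L, by = 10L)))
  expect_true(all(fit$log$loss >= 0))
})

test_that("predictions are pure per-row functions, independent of the batch", {
  set.seed(23)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  fit <- residue_cnn(X, y, small_cfg(seed = 2))
  batch <- predict(fit, X)
  solo <- vapply(seq_len(20), function(i)
    predict(fit, X[i, , drop = FALSE]), numeric(1))
  expect_equal(solo, batch)
  expect_length(predict(fit, X[1, , drop = FALSE]), 1L)
  expect_equal(predict(fit), fit$fitted.values)
})

test_that("model save/load round trips to identical predictions", {
  set.seed(24)
  X <- matrix(rnorm(150), 15, 10)
  y <- rnorm(15)
  fit <- residue_cnn(X, y, small_cfg(seed = 3))
  path <- tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict(back, X), predict(fit, X))
  expect_error(load_model(tempfile()), "not found")
  junk <- tempfile(); writeLines("not a model", junk)
  expect_error(load_model(junk), "corrupt|container")
})

test_that("a saved model is loadable in a fresh R process", {
  set.seed(25)
  X <- matrix(rnorm(120), 12, 10)
  y <- rnorm(12)
  fit <- residue_cnn(X, y, small_cfg(seed = 4))
  mpath <- tempfile(fileext = ".rds"); save_model(fit, mpath)
  xpath <- tempfile(fileext = ".rds"); saveRDS(X, xpath)
  opath <- tempfile(fileext = ".txt")
  code <- sprintf(
    "m <- leafspec::load_model('%s'); x <- readRDS('%s'); writeLines(format(stats::predict(m, x), digits = 15), '%s')",
    mpath, xpath, opath)
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c("--vanilla", "-e", shQuote(code)),
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(opath))
  expect_equal(as.numeric(readLines(opath)), predict(fit, X),
               tolerance = 1e-12)
})

test_that("shuffled labels yield no held-out skill on synthetic features", {
  set.seed(26)
  X <- matrix(rnorm(1200), 120, 10)
  y <- 1 + X[, 1]
  ysh <- sample(y)
  fit <- residue_cnn(X, ysh, small_cfg(iterations = 300, seed = 6))
  expect_lte(fit$metrics$r2[fit$metrics$split == "testing"], 0.3)
})

test_that("invalid inputs are rejected", {
  X <- matrix(rnorm(50), 5, 10)
  expect_error(residue_cnn(X, rnorm(5)), "at least 10")
  X2 <- matrix(rnorm(120), 12, 10)
  expect_error(residue_cnn(X2, c(rnorm(11), NA)), "finite")
  expect_error(cnn_config(train_fraction = 1.2), "train_fraction")
  expect_error(cnn_config(input_side = 5), "even")
})
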