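#' CNN regressor configuration
#'
#' Architecture and training protocol of the residue regressor: a 6 x 6
#' single-channel feature grid passes through conv(2 x 2, 16 filters) +
#' ReLU, max pooling (2 x 2 window, stride 2), conv(2 x 2, 32 filters) +
#' ReLU, a flatten to 288 values, a dense ReLU layer of width 512, and a
#' single linear output (mg/kg). Weights start from Normal(0, 0.1) draws
#' and biases from the constant 0.1; training minimizes mean squared error
#' by gradient descent at learning rate 0.01 for 10,000 iterations on an
#' 8:2 train/test split, logging the loss every 100 iterations.
#'
#' @param input_side side of the square input grid (6).
#' @param conv1_filters,conv2_filters filter counts of the two 2 x 2
#'   convolution layers.
#' @param fc_width width of the dense hidden layer.
#' @param weight_init_sd sd of the Normal weight initialization.
#' @param bias_init constant bias initialization.
#' @param learning_rate gradient-descent step size.
#' @param iterations number of training iterations.
#' @param log_every iterations between loss-log entries.
#' @param train_fraction fraction of samples in the training split.
#' @param batch_size mini-batch size per iteration; `NULL` uses the full
#'   training set every step.
#' @param optimizer `"gd"` for plain gradient descent (default) or
#'   `"adam"`.
#' @param seed integer seed governing the split, the weight init and the
#'   mini-batch draws.
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(input_side = 6L, conv1_filters = 16L,
                       conv2_filters = 32L, fc_width = 512L,
                       weight_init_sd = 0.1, bias_init = 0.1,
                       learning_rate = 0.01, iterations = 10000L,
                       log_every = 100L, train_fraction = 0.8,
                       batch_size = 128L, optimizer = c("gd", "adam"),
                       seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (input_side < 2L) stop("`input_side` must be >= 2")
  if (input_side %% 2L != 0L)
    stop("`input_side` must be even (2 x 2 pooling at stride 2)")
  if (any(c(conv1_filters, conv2_filters, fc_width, iterations,
            log_every) < 1L))
    stop("all layer sizes and iteration counts must be positive")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)")
  structure(list(
    input_side = as.integer(input_side),
    conv1_filters = as.integer(conv1_filters),
    conv2_filters = as.integer(conv2_filters),
    fc_width = as.integer(fc_width),
    weight_init_sd = weight_init_sd, bias_init = bias_init,
    learning_rate = learning_rate, iterations = as.integer(iterations),
    log_every = as.integer(log_every), train_fraction = train_fraction,
    batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
    optimizer = optimizer, seed = as.integer(seed)),
    class = "cnn_config")
}

#' Feature standardization state
#'
#' Column means and sds fitted on training features only; applied to every
#' grid fed to the network. Zero-sd columns are scaled by 1.
#'
#' @param features numeric matrix or data frame of training feature rows.
#' @return list of class `feature_normalizer` with `mean` and `sd`.
#' @export
fit_feature_normalizer <- function(features) {
  X <- as_feature_matrix(features)
  s <- apply(X, 2L, stats::sd)
  s[s == 0] <- 1
  structure(list(mean = colMeans(X), sd = s, n_features = ncol(X)),
            class = "feature_normalizer")
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features))
    features <- features[, setdiff(names(features), "sample_id"),
                         drop = FALSE]
  X <- as.matrix(features)
  if (!is.numeric(X)) stop("features must be numeric")
  X
}

#' Embed standardized features into square input grids
#'
#' Standardizes each feature with the fitted normalizer and places the
#' values row-major into the first cells of a `side x side` grid; the
#' remaining cells are zero.
#'
#' @param features n x k feature matrix (or data frame; a `sample_id`
#'   column is dropped).
#' @param normalizer a [fit_feature_normalizer()] result.
#' @param side grid side length (default 6).
#' @return n x side^2 matrix; column `j` is row-major grid cell `j`.
#' @export
features_to_grid <- function(features, normalizer, side = 6L) {
  if (!inherits(normalizer, "feature_normalizer"))
    stop("`normalizer` must be fitted with fit_feature_normalizer()")
  X <- as_feature_matrix(features)
  if (ncol(X) != normalizer$n_features)
    stop("feature count does not match the fitted normalizer")
  if (ncol(X) > side^2) stop("more features than grid cells")
  Z <- sweep(sweep(X, 2L, normalizer$mean), 2L, normalizer$sd, `/`)
  G <- matrix(0, nrow(X), side^2)
  G[, seq_len(ncol(Z))] <- Z
  G
}

## ---- internal geometry -------------------------------------------------
## Activations live in (n * S) x C matrices: row (s - 1) * n + i holds
## spatial cell s (row-major) of sample i. Convolutions use 'same' padding
## (bottom/right for the even 2 x 2 kernel), stride 1; pooling is 2 x 2 at
## stride 2 without padding.

# map output cell -> input cell for one kernel offset; NA = padded
offset_map <- function(h_in, w_in, h_out, w_out, dr, dc, stride = 1L) {
  grid <- expand.grid(c = seq_len(w_out), r = seq_len(h_out))  # row-major
  ri <- (grid$r - 1L) * stride + 1L + dr
  ci <- (grid$c - 1L) * stride + 1L + dc
  ifelse(ri <= h_in & ci <= w_in, (ri - 1L) * w_in + ci, NA_integer_)
}

cnn_geometry <- function(side) {
  s2 <- side %/% 2L
  offs <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  list(
    side = side, s_in = side^2, s_pool = s2^2,
    conv1 = lapply(offs, function(o)
      offset_map(side, side, side, side, o[1L], o[2L])),
    pool = lapply(offs, function(o)
      offset_map(side, side, s2, s2, o[1L], o[2L], stride = 2L)),
    conv2 = lapply(offs, function(o)
      offset_map(s2, s2, s2, s2, o[1L], o[2L])))
}

# expand an output->input cell map into long row indices for batch size n;
# padded cells point at the appended zero row (n * s_in + 1)
gather_rows <- function(s_map, n, s_in) {
  idx <- rep((s_map - 1L) * n, each = n) + rep.int(seq_len(n),
                                                   length(s_map))
  idx[is.na(idx)] <- n * s_in + 1L
  idx
}

# im2col: gather the 4 kernel-offset views of A ((n*s_in) x C) into
# (n*s_out) x (4*C), column blocks ordered by offset
conv_patches <- function(A, maps, n, s_in) {
  Aaug <- rbind(A, 0)
  do.call(cbind, lapply(maps, function(m)
    Aaug[gather_rows(m, n, s_in), , drop = FALSE]))
}

conv_scatter <- function(dP, maps, n, s_in, c_in) {
  dA <- matrix(0, n * s_in, c_in)
  for (o in seq_along(maps)) {
    idx <- gather_rows(maps[[o]], n, s_in)
    keep <- idx <= n * s_in
    block <- dP[, ((o - 1L) * c_in + 1L):(o * c_in), drop = FALSE]
    dA[idx[keep], ] <- dA[idx[keep], ] + block[keep, , drop = FALSE]
  }
  dA
}

relu <- function(x) pmax(x, 0)

cnn_init_params <- function(cfg) {
  g <- cnn_geometry(cfg$input_side)
  sd <- cfg$weight_init_sd; b0 <- cfg$bias_init
  flat <- g$s_pool * cfg$conv2_filters
  list(
    W1 = matrix(stats::rnorm(4L * cfg$conv1_filters, 0, sd),
                4L, cfg$conv1_filters),
    b1 = rep(b0, cfg$conv1_filters),
    W2 = matrix(stats::rnorm(4L * cfg$conv1_filters * cfg$conv2_filters,
                             0, sd), 4L * cfg$conv1_filters,
                cfg$conv2_filters),
    b2 = rep(b0, cfg$conv2_filters),
    Wf = matrix(stats::rnorm(flat * cfg$fc_width, 0, sd),
                flat, cfg$fc_width),
    bf = rep(b0, cfg$fc_width),
    Wo = matrix(stats::rnorm(cfg$fc_width, 0, sd), cfg$fc_width, 1L),
    bo = b0)
}

cnn_forward <- function(params, G, geom, keep = FALSE) {
  n <- nrow(G)
  A0 <- matrix(as.vector(G), ncol = 1L)               # (n*s_in) x 1
  P1 <- conv_patches(A0, geom$conv1, n, geom$s_in)
  Z1 <- sweep(P1 %*% params$W1, 2L, params$b1, `+`)
  A1 <- relu(Z1)                                       # (n*s_in) x c1
  # max pool: first-max-wins over the 4 window positions
  A1aug <- rbind(A1, -Inf)
  views <- lapply(geom$pool, function(m)
    A1aug[gather_rows(m, n, geom$s_in), , drop = FALSE])
  cur <- views[[1L]]; am <- matrix(1L, nrow(cur), ncol(cur))
  for (o in 2:4) {
    upd <- views[[o]] > cur
    am[upd] <- o
    cur[upd] <- views[[o]][upd]
  }
  Ap <- cur                                            # (n*s_pool) x c1
  P2 <- conv_patches(Ap, geom$conv2, n, geom$s_pool)
  Z2 <- sweep(P2 %*% params$W2, 2L, params$b2, `+`)
  A2 <- relu(Z2)                                       # (n*s_pool) x c2
  FL <- matrix(A2, nrow = n)                           # n x (s_pool*c2)
  Zf <- sweep(FL %*% params$Wf, 2L, params$bf, `+`)
  Af <- relu(Zf)
  pred <- as.numeric(Af %*% params$Wo) + params$bo
  if (!keep) return(pred)
  list(pred = pred, n = n, P1 = P1, Z1 = Z1, am = am, Ap = Ap,
       P2 = P2, Z2 = Z2, FL = FL, Zf = Zf, Af = Af)
}

cnn_backward <- function(params, fw, geom, dpred) {
  n <- fw$n
  dAf <- matrix(dpred, n, 1L) %*% t(params$Wo)
  gWo <- crossprod(fw$Af, matrix(dpred, n, 1L))
  gbo <- sum(dpred)
  dZf <- dAf * (fw$Zf > 0)
  gWf <- crossprod(fw$FL, dZf)
  gbf <- colSums(dZf)
  dFL <- dZf %*% t(params$Wf)
  dA2 <- matrix(dFL, nrow = n * geom$s_pool)
  dZ2 <- dA2 * (fw$Z2 > 0)
  gW2 <- crossprod(fw$P2, dZ2)
  gb2 <- colSums(dZ2)
  dP2 <- dZ2 %*% t(params$W2)
  dAp <- conv_scatter(dP2, geom$conv2, n, geom$s_pool,
                      ncol(params$W1))
  # pool backward: route to the argmax window position
  dA1 <- matrix(0, n * geom$s_in, ncol(params$W1))
  for (o in 1:4) {
    idx <- gather_rows(geom$pool[[o]], n, geom$s_in)
    contrib <- dAp * (fw$am == o)
    dA1[idx, ] <- dA1[idx, ] + contrib
  }
  dZ1 <- dA1 * (fw$Z1 > 0)
  gW1 <- crossprod(fw$P1, dZ1)
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       Wf = gWf, bf = gbf, Wo = gWo, bo = gbo)
}

#' Number of trainable parameters of the residue CNN
#'
#' @param cfg a [cnn_config()].
#' @return integer parameter count over both convolution layers, the dense
#'   hidden layer and the output neuron.
#' @export
cnn_parameter_count <- function(cfg = cnn_config()) {
  p <- (4L + 0L) * cfg$conv1_filters + cfg$conv1_filters +    # conv1 W + b
    4L * cfg$conv1_filters * cfg$conv2_filters + cfg$conv2_filters +
    (cfg$input_side %/% 2L)^2 * cfg$conv2_filters * cfg$fc_width +
    cfg$fc_width +
    cfg$fc_width + 1L
  as.integer(p)
}

#' Fit the residue CNN regressor
#'
#' The package's central estimator: maps the 10 leaf-image features to
#' residue concentration (mg/kg) through the small convolutional network
#' described in [cnn_config()]. The sample is split 8:2 into training and
#' testing sets, the feature normalizer is fitted on the training split
#' only, and the network is trained by (mini-batch) gradient descent on
#' the mean squared error. The loss on the full training split is logged
#' every `log_every` iterations together with the training R-squared (the
#' accuracy-curve analog for a regression output).
#'
#' @param x n x 10 feature matrix or the data frame produced by
#'   [extract_features_dir()] (a `sample_id` column is ignored).
#' @param y residue concentrations, mg/kg, length n.
#' @param config a [cnn_config()].
#' @return An object of class `residue_cnn` with components `config`,
#'   `normalizer`, `params` (fitted weights), `log` (data frame of
#'   iteration, loss, r2), `split` (train/test row indices), `metrics`
#'   (an [eval_report()] over both splits), `fitted.values`, `residuals`
#'   and `y`.
#' @examples
#' \donttest{
#' set.seed(1)
#' x <- matrix(rnorm(200), 20, 10)
#' y <- 1 + x[, 2] * 0.5
#' fit <- residue_cnn(x, y, cnn_config(iterations = 200, seed = 3))
#' fit
#' }
#' @export
residue_cnn <- function(x, y, config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  X <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of `x` must match length of `y`")
  if (nrow(X) < 10L) stop("need at least 10 samples")
  if (!all(is.finite(y))) stop("labels must be finite")
  sp <- calibration_split(nrow(X), config$train_fraction, config$seed)
  normalizer <- fit_feature_normalizer(X[sp$train, , drop = FALSE])
  G_train <- features_to_grid(X[sp$train, , drop = FALSE], normalizer,
                              config$input_side)
  G_test <- features_to_grid(X[sp$test, , drop = FALSE], normalizer,
                             config$input_side)
  y_train <- y[sp$train]; y_test <- y[sp$test]

  geom <- cnn_geometry(config$input_side)
  set.seed(config$seed)
  params <- cnn_init_params(config)
  state <- NULL
  if (config$optimizer == "adam")
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0), t = 0L)
  n_train <- nrow(G_train)
  bs <- if (is.null(config$batch_size)) n_train else
    min(config$batch_size, n_train)
  lr <- config$learning_rate
  log_it <- integer(0); log_loss <- numeric(0); log_r2 <- numeric(0)

  for (it in seq_len(config$iterations)) {
    rows <- if (bs == n_train) seq_len(n_train) else
      sample.int(n_train, bs)
    fw <- cnn_forward(params, G_train[rows, , drop = FALSE], geom,
                      keep = TRUE)
    err <- fw$pred - y_train[rows]
    if (!all(is.finite(err)))
      stop("training diverged (non-finite loss) at iteration ", it)
    gr <- cnn_backward(params, fw, geom, 2 * err / length(err))
    if (config$optimizer == "gd") {
      for (nm in names(params))
        params[[nm]] <- params[[nm]] - lr * gr[[nm]]
    } else {
      state$t <- state$t + 1L
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      for (nm in names(params)) {
        state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr[[nm]]
        state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr[[nm]]^2
        mh <- state$m[[nm]] / (1 - b1^state$t)
        vh <- state$v[[nm]] / (1 - b2^state$t)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    if (it %% config$log_every == 0L || it == config$iterations) {
      pred_tr <- cnn_forward(params, G_train, geom)
      log_it <- c(log_it, it)
      log_loss <- c(log_loss, mean((pred_tr - y_train)^2))
      log_r2 <- c(log_r2, r2(y_train, pred_tr))
    }
  }
  pred_tr <- cnn_forward(params, G_train, geom)
  pred_te <- cnn_forward(params, G_test, geom)
  fitted_all <- numeric(length(y))
  fitted_all[sp$train] <- pred_tr; fitted_all[sp$test] <- pred_te
  structure(list(
    config = config, normalizer = normalizer, params = params,
    log = data.frame(iteration = log_it, loss = log_loss, r2 = log_r2),
    split = sp,
    metrics = eval_report(y_train, pred_tr, y_test, pred_te),
    fitted.values = fitted_all, residuals = y - fitted_all, y = y),
    class = "residue_cnn")
}

#' @export
print.residue_cnn <- function(x, ...) {
  cat(sprintf(
    "Residue CNN regressor: %s parameters, %d training / %d testing samples\n",
    format(cnn_parameter_count(x$config), big.mark = ","),
    length(x$split$train), length(x$split$test)))
  m <- x$metrics
  cat(sprintf("  final loss %.4g; test RMSE %.4g mg/kg, test R2 %.3f\n",
              utils::tail(x$log$loss, 1L),
              m$rmse[m$split == "testing"], m$r2[m$split == "testing"]))
  invisible(x)
}

#' @export
summary.residue_cnn <- function(object, ...) {
  cat("Residue CNN regressor\n")
  cfg <- object$config
  cat(sprintf(
    "  architecture: %dx%dx1 -> conv(2x2,%d)+ReLU -> maxpool(2x2,2) -> conv(2x2,%d)+ReLU -> dense(%d)+ReLU -> 1\n",
    cfg$input_side, cfg$input_side, cfg$conv1_filters, cfg$conv2_filters,
    cfg$fc_width))
  cat(sprintf("  training: %s, lr %g, %d iterations, batch %s, seed %d\n",
              cfg$optimizer, cfg$learning_rate, cfg$iterations,
              if (is.null(cfg$batch_size)) "full" else cfg$batch_size,
              cfg$seed))
  print(object$metrics)
  invisible(object)
}

#' @export
fitted.residue_cnn <- function(object, ...) object$fitted.values

#' @export
residuals.residue_cnn <- function(object, ...) object$residuals

#' Predict residue concentration from image features
#'
#' @param object a fitted [residue_cnn()] model.
#' @param newdata feature matrix / data frame with the training feature
#'   count (a `sample_id` column is ignored); defaults to the training
#'   fitted values when missing.
#' @param ... unused.
#' @return numeric vector of concentrations, mg/kg, one per row.
#' @export
predict.residue_cnn <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  G <- features_to_grid(newdata, object$normalizer,
                        object$config$input_side)
  cnn_forward(object$params, G, cnn_geometry(object$config$input_side))
}

#' Training-curve plot
#'
#' Plots the logged training loss (and R-squared) against iteration.
#'
#' @param x a fitted [residue_cnn()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.residue_cnn <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$log$iteration, x$log$loss, type = "l",
                 xlab = "iteration", ylab = "training loss (MSE)",
                 main = "Training loss", ...)
  graphics::plot(x$log$iteration, x$log$r2, type = "l",
                 xlab = "iteration", ylab = expression(R^2),
                 main = "Training fit", ...)
  invisible(x)
}

#' Save and load a fitted residue CNN
#'
#' The model file is a versioned RDS container holding the configuration,
#' the feature normalizer and the fitted weights; a reloaded model gives
#' identical predictions.
#'
#' @param model a fitted [residue_cnn()].
#' @param path file path for the model container.
#' @return `load_model()` returns the `residue_cnn` object.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "residue_cnn"))
    stop("`model` must be a fitted residue_cnn")
  saveRDS(list(format = "leafspec_cnn", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt model file: ", path))
  if (!is.list(obj) || !identical(obj$format, "leafspec_cnn"))
    stop("not a leafspec model container: ", path)
  obj$model
}
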