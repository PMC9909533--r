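#' PLS1 regression (NIPALS)
#'
#' Fits a univariate partial least squares model by the NIPALS algorithm:
#' predictors and response are mean-centred, then for each latent variable
#' the weight vector `w = X'y / ||X'y||` is extracted, scores `t = X w`,
#' loadings `p = X't / t't`, regression `q = y't / t't`, and `X`, `y` are
#' deflated. Regression coefficients on the original scale follow from
#' `W (P'W)^-1 q`. With as many components as (full-rank) predictors the
#' model coincides with ordinary least squares.
#'
#' @param X predictor matrix (samples x wavelengths) or [spectra_matrix].
#' @param y response vector (residue concentration, mg/kg), non-constant.
#' @param ncomp number of latent variables, at most
#'   `min(samples - 1, predictors)`.
#' @return An object of class `pls1`: list with `coefficients` (per
#'   predictor), `intercept`, `x_means`, `y_mean`, `weights`, `loadings`,
#'   `scores`, `y_loadings`, `ncomp`, `fitted.values` and `residuals`.
#' @seealso [predict.pls1()], [calib_metrics()]
#' @examples
#' X <- matrix(rnorm(100), 20, 5)
#' y <- X %*% runif(5) + rnorm(20, 0, 0.1)
#' fit <- pls1(X, y, ncomp = 3)
#' fit
#' @export
pls1 <- function(X, y, ncomp = 5L) {
  if (inherits(X, "spectra_matrix")) X <- X$reflectance
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("rows of `X` must match length of `y`")
  if (stats::sd(y) == 0) stop("`y` is constant; PLS undefined")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(nrow(X) - 1L, ncol(X)))
    stop("`ncomp` must be in 1..min(samples - 1, predictors)")
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2L, xm); f <- y - ym
  p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  TT <- matrix(0, nrow(X), ncomp); qv <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- h - 1L; break }  # residual exhausted
    w <- w / nw
    tt <- E %*% w
    tt2 <- sum(tt^2)
    ph <- crossprod(E, tt) / tt2
    qh <- sum(f * tt) / tt2
    E <- E - tt %*% t(ph)
    f <- f - qh * tt
    W[, h] <- w; P[, h] <- ph; TT[, h] <- tt; qv[h] <- qh
  }
  if (ncomp < 1L) stop("no usable PLS component (X'y is zero)")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  TT <- TT[, seq_len(ncomp), drop = FALSE]
  qv <- qv[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), qv)
  fitted <- as.numeric(sweep(X, 2L, xm) %*% B) + ym
  structure(list(
    coefficients = as.numeric(B), intercept = ym - sum(xm * B),
    x_means = xm, y_mean = ym, weights = W, loadings = P, scores = TT,
    y_loadings = qv, ncomp = ncomp,
    fitted.values = fitted, residuals = y - fitted, y = y),
    class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("PLS1 model: %d component(s), %d predictors\n",
              x$ncomp, length(x$coefficients)))
  cat(sprintf("  training RMSE %.4g, R %.4f\n",
              sqrt(mean(x$residuals^2)),
              stats::cor(x$y, x$fitted.values)))
  invisible(x)
}

#' @export
coef.pls1 <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' Predict from a fitted PLS1 model
#'
#' @param object a [pls1] fit.
#' @param newdata matrix (or [spectra_matrix]) with the training predictor
#'   count; defaults to the training fitted values when missing.
#' @param ... unused.
#' @return numeric vector of predictions, one per row.
#' @export
predict.pls1 <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  if (inherits(newdata, "spectra_matrix")) newdata <- newdata$reflectance
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("`newdata` must have the training predictor count")
  as.numeric(sweep(newdata, 2L, object$x_means) %*% object$coefficients) +
    object$y_mean
}

#' Calibration and prediction metrics
#'
#' Rc/Rp are the Pearson correlations of observed against fitted values on
#' the calibration and prediction sets; SEC/SEP are the corresponding root
#' mean squared residuals (population form, denominator n). A constant
#' fitted vector yields a correlation of 0 with a warning.
#'
#' @param y_cal,yhat_cal observed and fitted values, calibration set.
#' @param y_pred,yhat_pred observed and fitted values, prediction set.
#' @return data frame with columns `Rc`, `SEC`, `Rp`, `SEP`.
#' @export
calib_metrics <- function(y_cal, yhat_cal, y_pred, yhat_pred) {
  safe_cor <- function(a, b) {
    if (length(a) != length(b)) stop("paired vectors must match in length")
    if (length(a) < 2L) stop("need at least 2 paired values")
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant vector; correlation reported as 0")
      return(0)
    }
    stats::cor(a, b)
  }
  data.frame(
    Rc = safe_cor(y_cal, yhat_cal),
    SEC = sqrt(mean((y_cal - yhat_cal)^2)),
    Rp = safe_cor(y_pred, yhat_pred),
    SEP = sqrt(mean((y_pred - yhat_pred)^2)))
}

# deterministic 8:2 split of n samples given a seed
calibration_split <- function(n, train_fraction = 0.8, seed = 1L) {
  set.seed(seed)
  n_train <- max(2L, round(train_fraction * n))
  if (n_train >= n) stop("split leaves no prediction samples")
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Compare preprocessing schemes by PLS calibration
#'
#' Applies each preprocessing scheme to the raw spectra, fits a PLS1 model
#' on a shared calibration/prediction split, and tabulates Rc/SEC/Rp/SEP
#' per scheme, sorted by prediction-set correlation Rp.
#'
#' @param M raw [spectra_matrix].
#' @param y concentration vector, mg/kg.
#' @param methods subset of [preprocess_methods()].
#' @param split_seed seed of the 8:2 calibration/prediction split.
#' @param sg an [sg_filter_spec] for SG-based schemes.
#' @param ncomp PLS components.
#' @param train_fraction calibration fraction (default 0.8).
#' @return data frame, one row per method, sorted by decreasing Rp.
#' @export
compare_preprocessing <- function(M, y, methods = preprocess_methods(),
                                  split_seed = 1L, sg = sg_filter_spec(),
                                  ncomp = 5L, train_fraction = 0.8) {
  stopifnot(inherits(M, "spectra_matrix"))
  methods <- match.arg(methods, preprocess_methods(), several.ok = TRUE)
  sp <- calibration_split(nrow(M$reflectance), train_fraction, split_seed)
  rows <- lapply(methods, function(meth) {
    Mp <- apply_method(M, meth, sg)$reflectance
    nc <- min(ncomp, length(sp$train) - 1L, ncol(Mp))
    fit <- pls1(Mp[sp$train, , drop = FALSE], y[sp$train], nc)
    cbind(data.frame(method = meth),
          calib_metrics(y[sp$train], fit$fitted.values,
                        y[sp$test],
                        predict(fit, Mp[sp$test, , drop = FALSE])))
  })
  out <- do.call(rbind, rows)
  out[order(out$Rp, decreasing = TRUE), , drop = FALSE]
}

#' Full-band versus characteristic-band PLS comparison
#'
#' Fits PLS1 on all wavelengths and on the selected bands only, with the
#' same calibration/prediction split, and returns both metric rows.
#'
#' @param M a [spectra_matrix] (already preprocessed as desired).
#' @param y concentration vector, mg/kg.
#' @param bands wavelengths (nm) to keep; each must lie on the axis.
#' @param split_seed split seed.
#' @param ncomp PLS components (capped by the band count for the
#'   characteristic-band model).
#' @param train_fraction calibration fraction.
#' @return data frame with rows `full_band` and `characteristic_band`.
#' @export
compare_bands <- function(M, y, bands, split_seed = 1L, ncomp = 5L,
                          train_fraction = 0.8) {
  stopifnot(inherits(M, "spectra_matrix"))
  if (length(bands) == 0L) stop("`bands` must be non-empty")
  idx <- match(bands, M$wavelengths)
  if (anyNA(idx))
    stop("band(s) off the wavelength axis: ",
         paste(bands[is.na(idx)], collapse = ", "))
  sp <- calibration_split(nrow(M$reflectance), train_fraction, split_seed)
  fit_one <- function(R) {
    nc <- min(ncomp, length(sp$train) - 1L, ncol(R))
    fit <- pls1(R[sp$train, , drop = FALSE], y[sp$train], nc)
    calib_metrics(y[sp$train], fit$fitted.values,
                  y[sp$test], predict(fit, R[sp$test, , drop = FALSE]))
  }
  out <- rbind(fit_one(M$reflectance),
               fit_one(M$reflectance[, idx, drop = FALSE]))
  cbind(data.frame(model = c("full_band", "characteristic_band")), out)
}
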