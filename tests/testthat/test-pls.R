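test_that("PLS1 with full components equals ordinary least squares", {
  set.seed(11)
  X <- matrix(rnorm(150), 30, 5)
  y <- X %*% runif(5) + rnorm(30, 0, 0.2)
  fit <- pls1(X, y, ncomp = 5)
  ols <- lm(y ~ X)
  expect_equal(fit$fitted.values, unname(fitted(ols)), tolerance = 1e-8)
  Xnew <- matrix(rnorm(25), 5, 5)
  expect_equal(predict(fit, Xnew),
               unname(cbind(1, Xnew) %*% coef(ols))[, 1], tolerance = 1e-8)
})

test_that("NIPALS matches the SIMPLS oracle on random problems", {
  set.seed(12)
  for (rep in 1:5) {
    X <- matrix(rnorm(200), 20, 10)
    y <- rnorm(20)
    for (nc in c(2, 4)) {
      fit <- pls1(X, y, ncomp = nc)
      oracle <- simpls_oracle(X, y, nc)
      expect_equal(fit$coefficients, oracle$coefficients, tolerance = 1e-8)
      expect_equal(fit$fitted.values, oracle$predict(X), tolerance = 1e-8)
    }
  }
})

test_that("PLS training variance explained is non-decreasing in components", {
  set.seed(13)
  X <- matrix(rnorm(300), 30, 10)
  y <- X %*% runif(10) + rnorm(30)
  rss <- sapply(1:6, function(nc) sum(pls1(X, y, nc)$residuals^2))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("PLS rejects degenerate input and predicts consistently", {
  X <- matrix(rnorm(60), 20, 3)
  expect_error(pls1(X, rep(1, 20)), "constant")
  expect_error(pls1(X, rnorm(20), ncomp = 10), "ncomp")
  y <- rnorm(20)
  fit <- pls1(X, y, 2)
  expect_equal(predict(fit, X), fit$fitted.values)
  expect_length(predict(fit, X[1, , drop = FALSE]), 1L)
  perm <- sample(20)
  expect_equal(predict(fit, X[perm, ]), fit$fitted.values[perm])
  expect_error(predict(fit, matrix(1, 2, 5)), "predictor count")
})

test_that("calibration metrics match hand-computed values", {
  m <- calib_metrics(c(1, 2, 3), c(1, 2, 3), c(1, 2), c(1.5, 2.5))
  expect_equal(m$Rc, 1)
  expect_equal(m$SEC, 0)
  y <- c(1, 2, 3, 4); yhat <- c(1.1, 1.9, 3.2, 3.8)
  m2 <- calib_metrics(y, yhat, y, yhat)
  expect_equal(m2$Rc, cor(y, yhat))
  expect_equal(m2$SEC, sqrt(mean((y - yhat)^2)))
  expect_warning(m3 <- calib_metrics(y, rep(mean(y), 4), y, yhat),
                 "constant")
  expect_equal(m3$Rc, 0)
  expect_error(calib_metrics(1:3, 1:4, 1:2, 1:2), "length")
})

test_that("band comparison with all wavelengths collapses to one model", {
  set.seed(14)
  setd <- generate_spectra(spectra_sim_config(n_samples = 40, seed = 14,
                                              wavelength_grid = 650:730))
  tab <- compare_bands(setd$spectra, setd$concentrations,
                       bands = setd$spectra$wavelengths, ncomp = 3)
  expect_equal(tab[1, -1], tab[2, -1], ignore_attr = TRUE)
  expect_error(compare_bands(setd$spectra, setd$concentrations, 1234),
               "off the wavelength axis")
  expect_error(compare_bands(setd$spectra, setd$concentrations, numeric(0)),
               "non-empty")
})

test_that("preprocessing comparison is deterministic and handles one method", {
  setd <- generate_spectra(spectra_sim_config(n_samples = 40, seed = 15,
                                              wavelength_grid = 650:730))
  tab <- compare_preprocessing(setd$spectra, setd$concentrations,
                               methods = "msc", ncomp = 3, split_seed = 4)
  expect_identical(nrow(tab), 1L)
  tab2 <- compare_preprocessing(setd$spectra, setd$concentrations,
                                ncomp = 3, split_seed = 4)
  expect_identical(nrow(tab2), 8L)
  expect_true(all(diff(tab2$Rp) <= 0))          # sorted by Rp
  tab3 <- compare_preprocessing(setd$spectra, setd$concentrations,
                                ncomp = 3, split_seed = 4)
  expect_identical(tab2, tab3)
})
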