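test_that("min-max normalization maps onto [0, 1] and rejects constants", {
  expect_equal(minmax_normalize(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 10)), c(0, 1))
  set.seed(1)
  x <- rnorm(50)
  y <- minmax_normalize(x)
  expect_equal(y, (x - min(x)) / (max(x) - min(x)))
  expect_equal(range(y), c(0, 1))
  expect_identical(order(y), order(x))          # order preserved
  expect_equal(minmax_normalize(y), y)          # idempotent once normalized
  expect_error(minmax_normalize(rep(2, 5)), "constant")
  expect_error(minmax_normalize(1), "length")
})

test_that("SG projection matrix matches dense evaluation and is a projection", {
  # classical quadratic window of width 5
  B <- sg_filter_matrix(sg_filter_spec(2, 2))
  expect_equal(B[3, ], c(-3, 12, 17, 12, -3) / 35)
  # independent dense evaluation of X (X'X)^-1 X'
  X <- outer(-2:2, 0:2, `^`)
  expect_equal(B, X %*% solve(t(X) %*% X) %*% t(X))
  for (m in c(2, 4, 7)) {
    for (ord in 2:3) {
      B <- sg_filter_matrix(sg_filter_spec(m, ord))
      expect_equal(B, t(B))                       # symmetric
      expect_equal(B %*% B, B, tolerance = 1e-10) # idempotent
      x <- seq(-m, m)
      for (d in 0:ord)                            # reproduces monomials
        expect_equal(as.numeric(B %*% x^d), x^d)
      expect_equal(as.numeric(B %*% rep(3, 2 * m + 1)), rep(3, 2 * m + 1))
    }
  }
  expect_error(sg_filter_spec(1, 3), "underdetermined")
})

test_that("SG smoothing reproduces polynomials and matches the polyfit oracle", {
  x <- seq(0, 10, length.out = 60)
  quad <- 1 + 2 * x + 3 * x^2
  expect_equal(sg_smooth(quad, sg_filter_spec(4, 2)), quad)
  expect_equal(sg_smooth(rep(5, 40), sg_filter_spec(5, 3)), rep(5, 40))
  set.seed(2)
  noisy <- sin(x) + rnorm(60, 0, 0.1)
  sm <- sg_smooth(noisy, sg_filter_spec(5, 3))
  oracle <- polyfit_window_oracle(noisy, 5, 3)
  interior <- 6:55
  expect_equal(sm[interior], oracle[interior], tolerance = 1e-9)
  expect_equal(sm[c(1:5, 56:60)], noisy[c(1:5, 56:60)])  # copy-through edges
  expect_error(sg_smooth(1:5, sg_filter_spec(5, 3)), "shorter")
})

test_that("SG smoothing agrees with the signal package's filter", {
  skip_if_not_installed("signal")
  set.seed(3)
  y <- cumsum(rnorm(80))
  sm <- sg_smooth(y, sg_filter_spec(5, 3))
  ref <- signal::sgolayfilt(y, p = 3, n = 11)
  expect_equal(sm[6:75], ref[6:75], tolerance = 1e-8)
})

test_that("derivatives are analytic on polynomials and match the oracle", {
  x <- seq_len(50)
  lin <- 2.5 * x + 1
  expect_equal(spectral_derivative(lin, 1L), rep(2.5, 50))
  sg <- sg_filter_spec(4, 3)
  expect_equal(spectral_derivative(lin, 1L, sg), rep(2.5, 50))
  quad <- 3 * x^2
  d2 <- spectral_derivative(quad, 2L, sg)
  expect_equal(d2[5:46], rep(6, 42))
  set.seed(4)
  y <- rnorm(50)
  for (ord in 1:2) {
    d <- spectral_derivative(y, ord, sg)
    oracle <- polyfit_window_oracle(y, 4, 3, derivative = ord)
    expect_equal(d[5:46], oracle[5:46], tolerance = 1e-9)
  }
  # plain finite difference, 2 nm step
  expect_equal(spectral_derivative(lin, 1L, delta = 2)[-1], rep(1.25, 49))
  expect_error(spectral_derivative(y, 3), "must be 1 or 2")
})

test_that("MSC removes affine scatter exactly and matches the lm oracle", {
  set.seed(5)
  ref <- runif(20)
  M <- t(sapply(1:5, function(i) 1.2^i * ref + 0.1 * i))
  corr <- msc_correct(M, reference = ref)
  for (i in 1:5) expect_equal(corr[i, ], ref)
  # fixed point: re-regressing a corrected row gives slope 1, intercept 0
  M2 <- matrix(rnorm(100), 5, 20)
  out <- msc_correct(M2)
  mref <- colMeans(M2)
  for (i in 1:5) {
    fit <- lm(out[i, ] ~ mref)
    expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-8)
  }
  expect_equal(out, msc_oracle(M2), tolerance = 1e-10)
  # scatter-free matrix is left unchanged
  flat <- matrix(rep(ref, 3), 3, byrow = TRUE)
  expect_equal(msc_correct(flat), flat)
  expect_error(msc_correct(M2[1, , drop = FALSE]), "2 samples")
})

test_that("mean centering zeroes column means and is idempotent", {
  M <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(mean_center(M), matrix(c(-1, 1, -1, 1), 2, 2))
  set.seed(6)
  M2 <- matrix(rnorm(60), 6, 10)
  out <- mean_center(M2)
  expect_equal(colMeans(out), rep(0, 10))
  expect_equal(mean_center(out), out)
})

test_that("apply_method dispatches all eight schemes and preserves shape", {
  expect_setequal(preprocess_methods(),
                  c("raw", "standard_normalization", "msc",
                    "first_derivative", "sg_first_derivative",
                    "sg_second_derivative", "sg_smoothing", "mean_center"))
  set.seed(7)
  M <- spectra_matrix(matrix(runif(500, 0.2, 0.8), 10, 50), 401:450)
  expect_identical(apply_method(M, "raw")$reflectance, M$reflectance)
  const <- spectra_matrix(matrix(0.5, 10, 50), 401:450)
  expect_equal(apply_method(const, "sg_smoothing")$reflectance,
               const$reflectance)
  for (meth in preprocess_methods()) {
    out <- apply_method(M, meth, sg_filter_spec(4, 3))
    expect_identical(dim(out$reflectance), dim(M$reflectance))
    expect_true(all(is.finite(out$reflectance)))
    # determinism
    expect_identical(out$reflectance,
                     apply_method(M, meth, sg_filter_spec(4, 3))$reflectance)
  }
  expect_error(apply_method(M, "wavelet"))
})
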