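# Independent brute-force oracles, deliberately implemented with different
# machinery than the package (lm fits, dense SVD, explicit pixel loops).

# Savitzky-Golay by per-window polynomial least squares: fit lm() in every
# sliding window and evaluate the fitted polynomial (or its derivative) at
# the window centre.
polyfit_window_oracle <- function(y, m, order, derivative = 0, delta = 1) {
  n <- length(y)
  out <- rep(NA_real_, n)
  xs <- seq(-m, m)
  for (i in seq.int(m + 1, n - m)) {
    fit <- stats::lm(y[(i - m):(i + m)] ~ poly(xs, order, raw = TRUE))
    cf <- coef(fit)
    out[i] <- factorial(derivative) * cf[derivative + 1] / delta^derivative
  }
  out
}

# two-parameter least squares of each row on the reference, via lm()
msc_oracle <- function(M, ref = colMeans(M)) {
  out <- M
  for (i in seq_len(nrow(M))) {
    fit <- stats::lm(M[i, ] ~ ref)
    out[i, ] <- (M[i, ] - coef(fit)[1]) / coef(fit)[2]
  }
  out
}

# Pearson r from the raw covariance/sd formula, column by column
pearson_oracle <- function(M, y) {
  apply(M, 2, function(col) {
    num <- sum((col - mean(col)) * (y - mean(y)))
    den <- sqrt(sum((col - mean(col))^2) * sum((y - mean(y))^2))
    if (den == 0) 0 else num / den
  })
}

# SIMPLS for univariate y (known to coincide with NIPALS PLS1): weight
# basis from the projected cross-covariance; scores come out orthonormal,
# so the regression step is a plain inner product.
simpls_oracle <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  s <- crossprod(E, f)
  p <- ncol(X)
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, 0)
  for (h in seq_len(ncomp)) {
    r <- s
    t <- E %*% r
    nt <- sqrt(sum(t^2))
    r <- r / nt; t <- t / nt
    ph <- crossprod(E, t)
    v <- ph
    if (ncol(V) > 0) v <- v - V %*% crossprod(V, ph)
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, h] <- r
    V <- cbind(V, v)
  }
  Tm <- E %*% R                    # orthonormal scores
  B <- R %*% crossprod(Tm, f)
  list(coefficients = as.numeric(B),
       predict = function(newX)
         as.numeric(sweep(as.matrix(newX), 2, xm) %*% B) + ym)
}

# brute-force foreground statistics by explicit pixel loops
pixel_loop_features <- function(img, mask) {
  g <- numeric(0); r <- numeric(0); gr <- numeric(0); b <- numeric(0)
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j]) {
      r <- c(r, img[i, j, 1]); gr <- c(gr, img[i, j, 2])
      b <- c(b, img[i, j, 3])
      g <- c(g, round(0.299 * img[i, j, 1] + 0.587 * img[i, j, 2] +
                        0.114 * img[i, j, 3]))
    }
  }
  psd <- function(v) sqrt(sum((v - mean(v))^2) / length(v))
  c(avg_gray = mean(g),
    mean_R = mean(r), mean_G = mean(gr), mean_B = mean(b),
    sd_R = psd(r), sd_G = psd(gr), sd_B = psd(b),
    cv_R = psd(r) / mean(r), cv_G = psd(gr) / mean(gr),
    cv_B = psd(b) / mean(b))
}

# brute-force rasterized disk pixel count
disk_area_oracle <- function(width, height, radius) {
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  count <- 0L
  for (x in seq_len(width)) for (y in seq_len(height))
    if ((x - cx)^2 + (y - cy)^2 <= radius^2) count <- count + 1L
  count
}
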