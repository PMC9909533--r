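#' Min-max normalization
#'
#' Maps a vector linearly onto \[0, 1\]: `y = (x - min) / (max - min)`.
#' Applied per spectrum, this is the "standard normalization" preprocessing
#' scheme.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return vector in \[0, 1\]; the minimum maps to 0 and the maximum to 1.
#' @examples
#' minmax_normalize(c(1, 2, 3))
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2L) stop("`x` must have length >= 2")
  rng <- range(x)
  if (rng[1L] == rng[2L])
    stop("min-max normalization undefined for a constant vector (max = min)")
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Savitzky-Golay filter specification
#'
#' The filter window has width `n = 2 * half_width + 1` and fits a
#' polynomial of degree `poly_order` in each window; the window must
#' overdetermine the fit (`n > poly_order`, i.e. `n >= poly_order + 1`
#' with at least one spare point).
#'
#' @param half_width m; window width is 2m + 1.
#' @param poly_order polynomial degree fitted in each window.
#' @return list of class `sg_filter_spec`.
#' @export
sg_filter_spec <- function(half_width = 5L, poly_order = 3L) {
  half_width <- as.integer(half_width); poly_order <- as.integer(poly_order)
  if (half_width < 1L) stop("`half_width` must be >= 1")
  if (poly_order < 0L) stop("`poly_order` must be >= 0")
  if (2L * half_width + 1L <= poly_order + 1L)
    stop("window 2m+1 must exceed poly_order + 1 (underdetermined fit)")
  structure(list(half_width = half_width, poly_order = poly_order),
            class = "sg_filter_spec")
}

# Vandermonde design on the centred abscissa (-m, ..., m)
sg_design <- function(spec) {
  x <- seq(-spec$half_width, spec$half_width)
  outer(x, 0:spec$poly_order, `^`)
}

#' Savitzky-Golay projection matrix
#'
#' Builds `B = X (X'X)^-1 X'`, the least-squares projection onto the span
#' of polynomials up to `poly_order` on the centred window abscissa.
#' `B` is symmetric and idempotent, and its centre row holds the classical
#' smoothing convolution coefficients.
#'
#' @param spec an [sg_filter_spec].
#' @return the (2m+1) x (2m+1) projection matrix.
#' @examples
#' B <- sg_filter_matrix(sg_filter_spec(2, 2))
#' B[3, ] * 35  # the classical (-3, 12, 17, 12, -3) window
#' @export
sg_filter_matrix <- function(spec) {
  stopifnot(inherits(spec, "sg_filter_spec"))
  X <- sg_design(spec)
  X %*% solve(crossprod(X), t(X))
}

# Convolution coefficients for the d-th derivative at the window centre:
# row of (X'X)^-1 X' for the degree-d coefficient, times d!.
sg_coefficients <- function(spec, derivative = 0L) {
  if (derivative > spec$poly_order)
    stop("derivative order exceeds the fitted polynomial degree")
  X <- sg_design(spec)
  A <- solve(crossprod(X), t(X))          # (poly_order+1) x n
  factorial(derivative) * A[derivative + 1L, ]
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Slides the filter window along the spectrum and replaces each interior
#' point with the fitted-polynomial value at the window centre (the centre
#' row of the projection matrix applied to the window). The first and last
#' `half_width` points are copied through unchanged; the wavelength axis is
#' untouched.
#'
#' @param reflectance numeric vector (one spectrum), longer than the window.
#' @param spec an [sg_filter_spec].
#' @param derivative 0 for smoothing; 1 or 2 for the derivative of the
#'   fitted window polynomial at the centre, per unit of the wavelength
#'   step (`delta`).
#' @param delta wavelength step in nm (scales derivatives only).
#' @return numeric vector, same length as the input.
#' @export
sg_apply <- function(reflectance, spec, derivative = 0L, delta = 1) {
  stopifnot(inherits(spec, "sg_filter_spec"))
  n <- length(reflectance)
  m <- spec$half_width
  if (n <= 2L * m + 1L) stop("spectrum shorter than the filter window")
  cf <- sg_coefficients(spec, derivative) / delta^derivative
  out <- if (derivative == 0L) reflectance else
    c(rep(NA_real_, m), rep(0, n - 2L * m), rep(NA_real_, m))
  for (i in seq.int(m + 1L, n - m))
    out[i] <- sum(cf * reflectance[(i - m):(i + m)])
  if (derivative > 0L) {
    # edge policy: replicate nearest interior derivative value
    out[seq_len(m)] <- out[m + 1L]
    out[seq.int(n - m + 1L, n)] <- out[n - m]
  }
  out
}

#' @rdname sg_apply
#' @export
sg_smooth <- function(reflectance, spec = sg_filter_spec()) {
  sg_apply(reflectance, spec, derivative = 0L)
}

#' Spectral derivative
#'
#' Either the plain adjacent finite difference over the wavelength step
#' ("first derivative method") or the Savitzky-Golay convolution derivative
#' (derivative of the fitted window polynomial at the centre).
#'
#' @param reflectance numeric vector.
#' @param order derivative order, 1 or 2.
#' @param spec an [sg_filter_spec] for the SG variant, or `NULL` for the
#'   plain finite difference (first order only pads the leading value;
#'   second order pads both ends).
#' @param delta wavelength step, nm.
#' @return numeric vector, same length as the input.
#' @export
spectral_derivative <- function(reflectance, order = 1L, spec = NULL,
                                delta = 1) {
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2")
  if (is.null(spec)) {
    n <- length(reflectance)
    if (n < 3L) stop("need at least 3 points for a finite difference")
    if (order == 1L) {
      d <- diff(reflectance) / delta
      c(d[1L], d)                      # pad to original length
    } else {
      d <- diff(reflectance, differences = 2L) / delta^2
      c(d[1L], d, d[length(d)])
    }
  } else {
    if (order > spec$poly_order)
      stop("SG derivative order exceeds the polynomial degree")
    sg_apply(reflectance, spec, derivative = order, delta = delta)
  }
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on the mean spectrum (OLS slope `b_i`,
#' intercept `a_i`) and returns `(row - a_i) / b_i`, removing per-sample
#' multiplicative and additive scatter.
#'
#' @param M a [spectra_matrix] (or plain matrix) with >= 2 samples.
#' @param reference optional reference spectrum; defaults to the
#'   column-wise mean.
#' @return object of the same type as `M`.
#' @export
msc_correct <- function(M, reference = NULL) {
  R <- if (inherits(M, "spectra_matrix")) M$reflectance else as.matrix(M)
  if (nrow(R) < 2L) stop("MSC needs at least 2 samples")
  ref <- if (is.null(reference)) colMeans(R) else as.numeric(reference)
  if (stats::var(ref) == 0) stop("zero-variance reference spectrum")
  refc <- ref - mean(ref)
  denom <- sum(refc^2)
  out <- R
  for (i in seq_len(nrow(R))) {
    b <- sum(refc * (R[i, ] - mean(R[i, ]))) / denom
    a <- mean(R[i, ]) - b * mean(ref)
    out[i, ] <- (R[i, ] - a) / b
  }
  if (inherits(M, "spectra_matrix")) set_reflectance(M, out) else out
}

#' Mean centering
#'
#' Subtracts the column mean from every column, so each wavelength has
#' mean zero across samples.
#'
#' @param M a [spectra_matrix] or plain matrix with >= 2 samples.
#' @return object of the same type as `M`.
#' @export
mean_center <- function(M) {
  R <- if (inherits(M, "spectra_matrix")) M$reflectance else as.matrix(M)
  if (nrow(R) < 2L) stop("mean centering needs at least 2 samples")
  out <- sweep(R, 2L, colMeans(R))
  if (inherits(M, "spectra_matrix")) set_reflectance(M, out) else out
}

#' The eight preprocessing schemes
#'
#' @return character vector naming the eight supported schemes, in the
#'   order they are compared: raw spectra, per-spectrum min-max
#'   normalization, multiplicative scatter correction, plain first
#'   derivative, SG convolution first and second derivatives, SG
#'   convolution smoothing, and mean centering.
#' @export
preprocess_methods <- function() {
  c("raw", "standard_normalization", "msc", "first_derivative",
    "sg_first_derivative", "sg_second_derivative", "sg_smoothing",
    "mean_center")
}

#' Apply a preprocessing scheme to a spectra matrix
#'
#' Dispatches to the individual operations; `"raw"` is the identity.
#' Row-wise schemes (normalization, smoothing, derivatives) are applied
#' per spectrum; `"msc"` and `"mean_center"` act across samples.
#'
#' @param M a [spectra_matrix].
#' @param method one of [preprocess_methods()].
#' @param sg an [sg_filter_spec] for the SG-based schemes.
#' @return a [spectra_matrix] of identical shape.
#' @export
apply_method <- function(M, method, sg = sg_filter_spec()) {
  stopifnot(inherits(M, "spectra_matrix"))
  method <- match.arg(method, preprocess_methods())
  delta <- if (length(M$wavelengths) > 1L)
    M$wavelengths[2L] - M$wavelengths[1L] else 1
  R <- M$reflectance
  out <- switch(method,
    raw = R,
    standard_normalization = t(apply(R, 1L, minmax_normalize)),
    msc = msc_correct(R),
    first_derivative =
      t(apply(R, 1L, spectral_derivative, order = 1L, delta = delta)),
    sg_first_derivative =
      t(apply(R, 1L, spectral_derivative, order = 1L, spec = sg,
              delta = delta)),
    sg_second_derivative =
      t(apply(R, 1L, spectral_derivative, order = 2L, spec = sg,
              delta = delta)),
    sg_smoothing = t(apply(R, 1L, sg_smooth, spec = sg)),
    mean_center = mean_center(R))
  set_reflectance(M, out)
}
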