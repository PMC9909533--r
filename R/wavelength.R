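#' Absorbance-like log transform
#'
#' Replaces each reflectance value R by `log10(1/R)`, the standard
#' absorbance proxy used before correlating spectra with an analyte.
#'
#' @param M a [spectra_matrix] or plain matrix; all values must be > 0.
#' @return object of the same type, transformed elementwise.
#' @export
log_inverse_transform <- function(M) {
  R <- if (inherits(M, "spectra_matrix")) M$reflectance else as.matrix(M)
  if (any(R <= 0))
    stop("log(1/R) requires strictly positive reflectance")
  out <- log10(1 / R)
  if (inherits(M, "spectra_matrix")) set_reflectance(M, out) else out
}

#' Correlation curve of reflectance against concentration
#'
#' Pearson correlation of every wavelength column against the residue
#' concentration vector, with r^2 reported alongside. A constant column is
#' assigned r = 0 with a warning.
#'
#' @param M a [spectra_matrix].
#' @param y concentration vector (mg/kg), non-constant, >= 3 samples.
#' @return A list of class `correlation_curve` with `wavelengths`, `r`
#'   and `r_squared`.
#' @export
correlation_curve <- function(M, y) {
  stopifnot(inherits(M, "spectra_matrix"))
  R <- M$reflectance
  if (nrow(R) < 3L) stop("need at least 3 samples")
  y <- as.numeric(y)
  if (length(y) != nrow(R)) stop("one concentration per sample required")
  if (stats::sd(y) == 0) stop("`y` is constant; correlation undefined")
  sds <- apply(R, 2L, stats::sd)
  r <- rep(0, ncol(R))
  ok <- sds > 0
  if (any(!ok))
    warning(sum(!ok), " constant wavelength column(s); r set to 0")
  if (any(ok)) r[ok] <- as.numeric(stats::cor(R[, ok, drop = FALSE], y))
  structure(list(wavelengths = M$wavelengths, r = r, r_squared = r^2),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  i <- which.max(abs(x$r))
  cat(sprintf("<correlation_curve> %d wavelengths; max |r| = %.3f at %g nm\n",
              length(x$r), abs(x$r[i]), x$wavelengths[i]))
  invisible(x)
}

#' PCA scoring coefficients per wavelength
#'
#' Standardizes every wavelength column (mean 0, sd 1), performs PCA and
#' returns the loadings ("scoring coefficients") of each wavelength on the
#' first `q` components, together with explained-variance ratios.
#' Zero-variance columns are dropped with a warning; their loadings are
#' reported as 0.
#'
#' @param M a [spectra_matrix].
#' @param q number of components, at most `min(samples - 1, wavelengths)`.
#' @return A list of class `pca_loadings` with `wavelengths`, `loadings`
#'   (wavelengths x q), and `explained_variance` (length q, ratios of the
#'   total variance).
#' @export
pca_loadings <- function(M, q = 3L) {
  stopifnot(inherits(M, "spectra_matrix"))
  R <- M$reflectance
  if (nrow(R) < 2L) stop("need at least 2 samples")
  q <- as.integer(q)
  if (q < 1L || q > min(nrow(R) - 1L, ncol(R)))
    stop("`q` must be in 1..min(samples - 1, wavelengths)")
  sds <- apply(R, 2L, stats::sd)
  ok <- sds > 0
  if (!any(ok)) stop("all wavelength columns have zero variance")
  if (any(!ok))
    warning(sum(!ok), " zero-variance column(s) dropped from PCA")
  pc <- stats::prcomp(R[, ok, drop = FALSE], center = TRUE, scale. = TRUE)
  q <- min(q, ncol(pc$rotation))
  L <- matrix(0, ncol(R), q)
  L[ok, ] <- pc$rotation[, seq_len(q), drop = FALSE]
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(q)]
  structure(list(wavelengths = M$wavelengths, loadings = L,
                 explained_variance = ev),
            class = "pca_loadings")
}

#' @export
print.pca_loadings <- function(x, ...) {
  cat(sprintf("<pca_loadings> %d wavelengths x %d components; cumulative EV %.1f%%\n",
              nrow(x$loadings), ncol(x$loadings),
              100 * sum(x$explained_variance)))
  invisible(x)
}

#' Screen characteristic wavelengths
#'
#' Combines the correlation curve with the first-component PCA scoring
#' coefficients into the product score
#' `score = (r^2 / max r^2) * (|loading_1| / max |loading_1|)`,
#' finds its local maxima, and greedily keeps the `n_bands` highest-scoring
#' peaks that are pairwise at least `min_separation` nm apart. The primary
#' band is the selected peak with the highest score (ties broken toward
#' larger r^2) — the wavelength with both the highest correlation and the
#' highest scoring coefficient.
#'
#' @param curve a [correlation_curve].
#' @param loadings a [pca_loadings] on the same wavelength axis.
#' @param n_bands number of bands requested (>= 1). If fewer qualifying
#'   peaks exist, the shorter list is returned with a warning.
#' @param min_separation minimum pairwise distance between selected bands,
#'   nm.
#' @return A list of class `band_selection` with `bands` (nm, ordered by
#'   score), `primary` (nm), and `evidence` (data frame of r, r_squared,
#'   loading magnitude and score per selected band).
#' @export
screen_bands <- function(curve, loadings, n_bands = 7L,
                         min_separation = 30) {
  stopifnot(inherits(curve, "correlation_curve"),
            inherits(loadings, "pca_loadings"))
  if (!isTRUE(all.equal(curve$wavelengths, loadings$wavelengths)))
    stop("correlation curve and loadings use different wavelength axes")
  if (n_bands < 1L) stop("`n_bands` must be >= 1")
  w <- curve$wavelengths
  r2 <- curve$r_squared
  l1 <- abs(loadings$loadings[, 1L])
  score <- (r2 / max(r2)) * (l1 / max(l1))
  p <- length(score)
  # local maxima (plateau edges count once)
  left  <- c(TRUE,  score[-1L] >  score[-p])
  right <- c(score[-p] >= score[-1L], TRUE)
  peaks <- which(left & right)
  peaks <- peaks[order(score[peaks], r2[peaks], decreasing = TRUE)]
  sel <- integer(0)
  for (i in peaks) {
    if (length(sel) == n_bands) break
    if (all(abs(w[i] - w[sel]) >= min_separation)) sel <- c(sel, i)
  }
  if (length(sel) < n_bands)
    warning(sprintf("only %d of %d requested bands found", length(sel),
                    n_bands))
  primary <- sel[1L]  # highest score, ties already broken toward larger r^2
  structure(list(
    bands = w[sel], primary = w[primary],
    evidence = data.frame(wavelength = w[sel], r = curve$r[sel],
                          r_squared = r2[sel], loading = l1[sel],
                          score = score[sel])),
    class = "band_selection")
}

#' One-call characteristic-band selection
#'
#' The full screening workflow: optionally transform the (preprocessed)
#' reflectance to the absorbance proxy log10(1/R) (values outside (0, 1]
#' are first shifted and rescaled into it, since derivative and centered
#' preprocessing schemes can produce non-positive values), compute the
#' correlation curve against concentration and the PCA scoring
#' coefficients, and screen bands with [screen_bands()].
#'
#' @param M a [spectra_matrix] (preprocessed as desired).
#' @param y concentration vector, mg/kg.
#' @param n_bands,min_separation see [screen_bands()].
#' @param transform apply the log10(1/R) transform first (default TRUE).
#' @param q PCA components retained for the evidence (default 3).
#' @return list with `selection` (a `band_selection`), `curve` and
#'   `loadings`.
#' @export
select_characteristic_bands <- function(M, y, n_bands = 7L,
                                        min_separation = 30,
                                        transform = TRUE, q = 3L) {
  stopifnot(inherits(M, "spectra_matrix"))
  A <- if (transform) log_inverse_transform(clip_positive(M)) else M
  curve <- correlation_curve(A, y)
  loads <- pca_loadings(A, q = q)
  list(selection = screen_bands(curve, loads, n_bands, min_separation),
       curve = curve, loadings = loads)
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("<band_selection> %d band(s): %s nm; primary %g nm\n",
              length(x$bands), paste(round(x$bands), collapse = ", "),
              x$primary))
  invisible(x)
}
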