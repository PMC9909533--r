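#' Spectra matrix container
#'
#' A `spectra_matrix` holds a rectangular grid of reflectance values, one row
#' per sample, over a single shared wavelength axis (nm, strictly increasing).
#' All preprocessing and wavelength-selection functions act on this container.
#'
#' @param reflectance numeric matrix, samples x wavelengths; values are
#'   unitless reflectance (or a transform of it).
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, one per column of `reflectance`.
#' @param ids optional character vector of sample ids (defaults to
#'   `"s1" ... "sn"`).
#'
#' @return An object of class `spectra_matrix`: a list with elements
#'   `reflectance`, `wavelengths` and `ids`.
#' @examples
#' m <- spectra_matrix(matrix(runif(20), 4, 5), 500:504)
#' dim(m)
#' @export
spectra_matrix <- function(reflectance, wavelengths, ids = NULL) {
  reflectance <- as.matrix(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(reflectance) != length(wavelengths))
    stop("`reflectance` must have one column per wavelength")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (!all(is.finite(reflectance)))
    stop("`reflectance` must be finite")
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(reflectance)))
  if (length(ids) != nrow(reflectance))
    stop("`ids` must have one entry per sample")
  dimnames(reflectance) <- NULL
  structure(
    list(reflectance = reflectance, wavelengths = wavelengths,
         ids = as.character(ids)),
    class = "spectra_matrix"
  )
}

#' @export
dim.spectra_matrix <- function(x) dim(x$reflectance)

#' @export
as.matrix.spectra_matrix <- function(x, ...) {
  m <- x$reflectance
  dimnames(m) <- list(x$ids, format(x$wavelengths, trim = TRUE))
  m
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d wavelengths (%g-%g nm)\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# replace the reflectance grid, keeping axis + ids
set_reflectance <- function(x, R) {
  stopifnot(inherits(x, "spectra_matrix"),
            nrow(R) == nrow(x$reflectance),
            ncol(R) == ncol(x$reflectance))
  x$reflectance <- as.matrix(R)
  x
}

#' Read and write labeled spectra as CSV
#'
#' The on-disk layout is one row per sample: first column the sample id,
#' second column the residue concentration in mg/kg, remaining columns one
#' reflectance value per wavelength, with a header row carrying the
#' wavelengths in nm.
#'
#' @param path file path.
#' @return `read_spectra_csv()` returns a list with elements `spectra`
#'   (a [spectra_matrix]) and `concentrations` (numeric, mg/kg).
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("spectra CSV not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L)
    stop("spectra CSV needs id, concentration and at least one wavelength column")
  wl <- suppressWarnings(as.numeric(names(df)[-(1:2)]))
  if (anyNA(wl))
    stop("spectra CSV header must carry numeric wavelengths from column 3 on")
  m <- spectra_matrix(as.matrix(df[, -(1:2), drop = FALSE]), wl,
                      ids = as.character(df[[1L]]))
  list(spectra = m, concentrations = as.numeric(df[[2L]]))
}

#' @rdname read_spectra_csv
#' @param spectra a [spectra_matrix].
#' @param concentrations numeric vector of residue concentrations (mg/kg),
#'   one per sample.
#' @export
write_spectra_csv <- function(spectra, concentrations, path) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  n <- nrow(spectra$reflectance)
  if (length(concentrations) != n)
    stop("one concentration per spectrum required")
  df <- data.frame(sample_id = spectra$ids,
                   concentration = as.numeric(concentrations),
                   check.names = FALSE)
  R <- spectra$reflectance
  colnames(R) <- format(spectra$wavelengths, trim = TRUE)
  utils::write.csv(cbind(df, as.data.frame(R, check.names = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write image labels as CSV
#'
#' Two columns: `sample_id` (matching image file stems) and `concentration`
#' in mg/kg.
#' @param path file path.
#' @keywords internal
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop("labels CSV not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("sample_id", "concentration") %in% names(df)))
    stop("labels CSV must have columns sample_id, concentration")
  df$sample_id <- as.character(df$sample_id)
  df$concentration <- as.numeric(df$concentration)
  df
}

#' @rdname read_labels_csv
#' @param ids character sample ids.
#' @param concentrations numeric mg/kg labels.
#' @export
write_labels_csv <- function(ids, concentrations, path) {
  utils::write.csv(
    data.frame(sample_id = ids, concentration = concentrations),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
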