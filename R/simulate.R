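#' Configuration for the synthetic spectra generator
#'
#' Defines the statistical model from which labeled reflectance spectra are
#' drawn: a fixed green-leaf baseline curve minus a concentration-dependent
#' Gaussian absorption feature planted at `planted_band`, distorted by
#' per-spectrum multiplicative scatter and additive channel noise.
#'
#' The defaults describe the study conditions the rest of the package is
#' exercised under: a 320-1100 nm axis at 1 nm resolution, an absorption
#' band at 709 nm (sigma 15 nm) whose depth grows by `effect_size`
#' reflectance units per mg/kg, multiplicative scatter with slope sd 0.10
#' and offset sd 0.02, and iid noise with sd 0.01.
#'
#' @param n_samples number of spectra to generate (>= 2).
#' @param wavelength_grid wavelength axis in nm, strictly increasing.
#' @param planted_band nm position of the residue absorption band; must lie
#'   on `wavelength_grid`.
#' @param band_width_sigma Gaussian sigma of the band, nm.
#' @param effect_size band depth per unit concentration, reflectance units
#'   per (mg/kg); 0 gives a null model with no residue signal.
#' @param scatter_slope_sd,scatter_offset_sd standard deviations of the
#'   per-spectrum multiplicative slope `(1 + a)` and additive offset `b`.
#' @param noise_sd sd of iid additive noise per channel, reflectance units.
#' @param concentration_range mg/kg interval for uniformly drawn labels.
#' @param seed integer seed; fixed seed gives bit-reproducible output.
#'
#' @return A list of class `spectra_sim_config`.
#' @export
spectra_sim_config <- function(n_samples = 200,
                               wavelength_grid = 320:1100,
                               planted_band = 709,
                               band_width_sigma = 15,
                               effect_size = 0.03,
                               scatter_slope_sd = 0.10,
                               scatter_offset_sd = 0.02,
                               noise_sd = 0.01,
                               concentration_range = c(0, 2.5),
                               seed = 1L) {
  if (n_samples < 2) stop("`n_samples` must be at least 2")
  wavelength_grid <- as.numeric(wavelength_grid)
  if (any(diff(wavelength_grid) <= 0))
    stop("`wavelength_grid` must be strictly increasing")
  if (!planted_band %in% wavelength_grid)
    stop("`planted_band` must lie on `wavelength_grid`")
  if (noise_sd < 0 || scatter_slope_sd < 0 || scatter_offset_sd < 0)
    stop("noise and scatter sds must be non-negative")
  if (band_width_sigma <= 0) stop("`band_width_sigma` must be positive")
  structure(list(
    n_samples = as.integer(n_samples), wavelength_grid = wavelength_grid,
    planted_band = planted_band, band_width_sigma = band_width_sigma,
    effect_size = effect_size, scatter_slope_sd = scatter_slope_sd,
    scatter_offset_sd = scatter_offset_sd, noise_sd = noise_sd,
    concentration_range = as.numeric(concentration_range),
    seed = as.integer(seed)), class = "spectra_sim_config")
}

#' Deterministic green-leaf baseline reflectance
#'
#' A fixed piecewise-smooth curve with the qualitative shape of a healthy
#' leaf spectrum: low UV/blue reflectance, a green bump near 550 nm, a red
#' chlorophyll absorption dip near 670 nm, the red-edge rise over
#' 690-750 nm to a NIR plateau, and a shallow water feature near 970 nm.
#' The planted 709 nm band therefore sits on a realistic slope.
#'
#' @param wavelengths nm vector.
#' @return reflectance in \[0, 1\], same length as `wavelengths`.
#' @export
leaf_baseline <- function(wavelengths) {
  w <- as.numeric(wavelengths)
  base <- 0.05 +
    0.07 * exp(-((w - 550)^2) / (2 * 40^2)) -       # green bump
    0.03 * exp(-((w - 670)^2) / (2 * 25^2)) +       # chlorophyll dip
    0.45 / (1 + exp(-(w - 715) / 12)) -             # red edge to NIR plateau
    0.05 * exp(-((w - 970)^2) / (2 * 30^2))         # water feature
  pmin(pmax(base, 0), 1)
}

#' Generate labeled synthetic spectra
#'
#' Each spectrum is built as
#' `(1 + a_i) * (baseline - c_i * effect_size * g(lambda)) + b_i + noise`,
#' where `g` is a unit-height Gaussian centred on the planted band,
#' `c_i` the sample's concentration, `a_i, b_i` per-spectrum scatter draws
#' and the noise iid per channel. Reflectance is clipped to \[0, 1\].
#'
#' @param config a [spectra_sim_config].
#' @param concentrations optional mg/kg labels; when `NULL`, drawn uniformly
#'   from `config$concentration_range`.
#' @return A list of class `labeled_spectra` with elements `spectra`
#'   (a [spectra_matrix]), `concentrations` and `config`.
#' @examples
#' set <- generate_spectra(spectra_sim_config(n_samples = 20, seed = 42))
#' dim(set$spectra)
#' @export
generate_spectra <- function(config, concentrations = NULL) {
  stopifnot(inherits(config, "spectra_sim_config"))
  n <- config$n_samples
  w <- config$wavelength_grid
  set.seed(config$seed)
  if (is.null(concentrations)) {
    concentrations <- stats::runif(n, config$concentration_range[1L],
                                   config$concentration_range[2L])
  } else {
    if (length(concentrations) != n)
      stop("`concentrations` must match `n_samples`")
    if (any(concentrations < 0)) stop("concentrations must be >= 0")
  }
  base <- leaf_baseline(w)
  band <- exp(-((w - config$planted_band)^2) / (2 * config$band_width_sigma^2))
  a <- stats::rnorm(n, 0, config$scatter_slope_sd)
  b <- stats::rnorm(n, 0, config$scatter_offset_sd)
  R <- matrix(0, n, length(w))
  for (i in seq_len(n)) {
    clean <- base - concentrations[i] * config$effect_size * band
    R[i, ] <- (1 + a[i]) * clean + b[i]
  }
  if (config$noise_sd > 0)
    R <- R + matrix(stats::rnorm(n * length(w), 0, config$noise_sd),
                    n, length(w))
  R <- pmin(pmax(R, 0), 1)
  structure(list(
    spectra = spectra_matrix(R, w),
    concentrations = as.numeric(concentrations),
    config = config), class = "labeled_spectra")
}

#' @export
print.labeled_spectra <- function(x, ...) {
  cat(sprintf("<labeled_spectra> %d samples, concentrations %.3g-%.3g mg/kg\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations)))
  print(x$spectra)
  invisible(x)
}

#' Configuration for the synthetic leaf-image generator
#'
#' Images emulate a single lit leaf photographed under the characteristic
#' band: a disk foreground on a uniform dark background, whose per-channel
#' mean intensity grows linearly with residue concentration.
#'
#' @param width,height frame size in pixels.
#' @param blob_radius leaf-disk radius in pixels; the disk must fit in the
#'   frame.
#' @param base_channel_levels length-3 RGB intensities (8-bit) of the leaf
#'   at concentration 0.
#' @param channel_slopes length-3 intensity change per mg/kg.
#' @param pixel_noise_sd iid pixel noise sd, intensity units.
#' @param background_level uniform background intensity (8-bit, dark).
#' @param seed integer seed.
#' @return A list of class `image_sim_config`.
#' @export
image_sim_config <- function(width = 64, height = 64, blob_radius = 22,
                             base_channel_levels = c(120, 90, 50),
                             channel_slopes = c(15, 8, 4),
                             pixel_noise_sd = 3,
                             background_level = 8,
                             seed = 1L) {
  if (2 * blob_radius + 1 > min(width, height))
    stop("blob does not fit inside the frame")
  if (length(base_channel_levels) != 3L || length(channel_slopes) != 3L)
    stop("channel levels and slopes must have length 3")
  if (any(base_channel_levels < 0 | base_channel_levels > 255))
    stop("`base_channel_levels` must be 8-bit values")
  if (background_level < 0 || background_level > 255)
    stop("`background_level` must be an 8-bit value")
  if (pixel_noise_sd < 0) stop("`pixel_noise_sd` must be non-negative")
  structure(list(
    width = as.integer(width), height = as.integer(height),
    blob_radius = blob_radius,
    base_channel_levels = as.numeric(base_channel_levels),
    channel_slopes = as.numeric(channel_slopes),
    pixel_noise_sd = pixel_noise_sd,
    background_level = as.numeric(background_level),
    seed = as.integer(seed)), class = "image_sim_config")
}

#' Generate one synthetic leaf image
#'
#' Rasterizes a centred disk (pixels whose centre lies within
#' `blob_radius` of the frame centre) whose channel intensities are
#' `clip(base + slope * concentration)` plus iid pixel noise, over a
#' uniform dark background. The ground-truth foreground mask is returned
#' alongside the image.
#'
#' @param concentration residue concentration in mg/kg (>= 0).
#' @param config an [image_sim_config].
#' @return A list of class `leaf_image_sim` with elements `image`
#'   (height x width x 3 array of 8-bit values), `mask` (logical
#'   height x width ground truth) and `concentration`.
#' @export
generate_leaf_image <- function(concentration, config) {
  stopifnot(inherits(config, "image_sim_config"))
  if (concentration < 0) stop("`concentration` must be >= 0")
  h <- config$height; w <- config$width
  set.seed(config$seed)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  mask <- (xs - cx)^2 + (ys - cy)^2 <= config$blob_radius^2
  img <- array(config$background_level, dim = c(h, w, 3L))
  lev <- pmin(pmax(config$base_channel_levels +
                     config$channel_slopes * concentration, 0), 255)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- lev[ch]
    if (config$pixel_noise_sd > 0)
      plane <- plane + matrix(stats::rnorm(h * w, 0, config$pixel_noise_sd),
                              h, w)
    img[, , ch] <- plane
  }
  img <- round(pmin(pmax(img, 0), 255))
  structure(list(image = img, mask = mask,
                 concentration = as.numeric(concentration)),
            class = "leaf_image_sim")
}

#' Generate a matched spectra + image dataset
#'
#' Draws per-sample concentrations either from four discrete treatment
#' groups (emulating spray dilutions 1:500, 1:800 and 1:1500 plus a clear
#' water control) or uniformly over a range, then generates spectra and
#' leaf images sharing those labels.
#'
#' @param spectra_config a [spectra_sim_config]; its `n_samples` and `seed`
#'   are overridden by `n` and the dataset seed.
#' @param image_config an [image_sim_config].
#' @param n number of samples (>= 2).
#' @param groups `"dilution"` for the four discrete treatment groups,
#'   `"uniform"` for labels drawn from `spectra_config$concentration_range`.
#' @param group_concentrations mg/kg levels of the four groups (control
#'   first); defaults inversely proportional to the dilution factors.
#' @param seed integer seed governing labels, spectra and images.
#' @return list with elements `spectra_set` (a `labeled_spectra`),
#'   `images` (list of `leaf_image_sim`), `concentrations` and `ids`.
#' @export
generate_dataset <- function(spectra_config = spectra_sim_config(),
                             image_config = image_sim_config(),
                             n = 1200,
                             groups = c("dilution", "uniform"),
                             group_concentrations = c(0, 0.83, 1.56, 2.5),
                             seed = 1L) {
  groups <- match.arg(groups)
  if (n < 2) stop("`n` must be at least 2")
  stopifnot(inherits(spectra_config, "spectra_sim_config"),
            inherits(image_config, "image_sim_config"))
  set.seed(seed)
  if (groups == "dilution") {
    if (length(group_concentrations) != 4L)
      stop("`group_concentrations` must list four levels")
    conc <- group_concentrations[rep(1:4, length.out = n)]  # balanced groups
  } else {
    conc <- stats::runif(n, spectra_config$concentration_range[1L],
                         spectra_config$concentration_range[2L])
  }
  spectra_config$n_samples <- as.integer(n)
  spectra_config$seed <- as.integer(seed)
  spectra_set <- generate_spectra(spectra_config, concentrations = conc)
  images <- vector("list", n)
  img_seeds <- sample.int(.Machine$integer.max, n)
  for (i in seq_len(n)) {
    cfg <- image_config
    cfg$seed <- img_seeds[i]
    images[[i]] <- generate_leaf_image(conc[i], cfg)
  }
  ids <- sprintf("leaf%04d", seq_len(n))
  list(spectra_set = spectra_set, images = images,
       concentrations = conc, ids = ids)
}

#' Write a synthetic image set to PNG files
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_image_set <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(dataset$ids, ".png"))
  for (i in seq_along(dataset$images))
    write_leaf_png(dataset$images[[i]]$image, paths[i])
  write_labels_csv(dataset$ids, dataset$concentrations,
                   file.path(dir, "labels.csv"))
  invisible(paths)
}
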