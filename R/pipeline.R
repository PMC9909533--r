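#' Pipeline configuration
#'
#' Paths and parameters for the two computational stages: wavelength
#' selection from spectra, and CNN training from leaf images. Every output
#' directory receives a JSON manifest echoing the configuration and seeds,
#' so a run is reproducible from the manifest alone.
#'
#' @param spectra_csv labeled spectra CSV (see [read_spectra_csv()]).
#' @param image_dir directory of leaf PNGs plus a `labels.csv`.
#' @param labels_csv labels CSV; defaults to `labels.csv` inside
#'   `image_dir`.
#' @param out_dir output directory, created if missing.
#' @param method preprocessing scheme for the wavelength stage.
#' @param sg an [sg_filter_spec()].
#' @param n_bands,min_separation band-screening parameters.
#' @param pls_ncomp PLS components for the comparison tables.
#' @param cnn a [cnn_config()].
#' @param split_seed seed of the PLS calibration/prediction split.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spectra_csv = NULL, image_dir = NULL,
                            labels_csv = NULL, out_dir = "leafspec_out",
                            method = "sg_smoothing",
                            sg = sg_filter_spec(),
                            n_bands = 7L, min_separation = 30,
                            pls_ncomp = 5L,
                            cnn = cnn_config(),
                            split_seed = 1L) {
  structure(list(
    spectra_csv = spectra_csv, image_dir = image_dir,
    labels_csv = labels_csv %||%
      (if (!is.null(image_dir)) file.path(image_dir, "labels.csv")),
    out_dir = out_dir, method = method, sg = sg,
    n_bands = as.integer(n_bands), min_separation = min_separation,
    pls_ncomp = as.integer(pls_ncomp), cnn = cnn,
    split_seed = as.integer(split_seed)), class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(cfg, stage, extra = list()) {
  manifest <- c(list(stage = stage, method = cfg$method,
                     sg_half_width = cfg$sg$half_width,
                     sg_poly_order = cfg$sg$poly_order,
                     split_seed = cfg$split_seed,
                     cnn_seed = cfg$cnn$seed,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                extra)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir,
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Wavelength-selection stage
#'
#' Reads labeled spectra, applies the configured preprocessing scheme,
#' transforms to log(1/R), computes the correlation curve and the PCA
#' scoring coefficients, screens characteristic bands, and runs the two
#' PLS comparison workflows (preprocessing ranking; full-band versus
#' characteristic-band). Writes the band report as JSON, the correlation
#' curve and both comparison tables as CSV, plus a manifest.
#'
#' @param cfg a [pipeline_config()] with `spectra_csv` set.
#' @return list with `selection` (a `band_selection`),
#'   `preprocessing_table` and `band_table` (data frames), invisibly
#'   written under `cfg$out_dir`.
#' @export
run_wavelength_stage <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$spectra_csv)) stop("`spectra_csv` not set")
  dat <- read_spectra_csv(cfg$spectra_csv)
  if (stats::sd(dat$concentrations) == 0)
    stop("labels are constant; nothing to correlate")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  M <- apply_method(dat$spectra, cfg$method, cfg$sg)
  A <- log_inverse_transform(clip_positive(M))
  curve <- correlation_curve(A, dat$concentrations)
  loads <- pca_loadings(A, q = 3L)
  sel <- screen_bands(curve, loads, cfg$n_bands, cfg$min_separation)

  pre_tab <- compare_preprocessing(dat$spectra, dat$concentrations,
                                   split_seed = cfg$split_seed,
                                   sg = cfg$sg, ncomp = cfg$pls_ncomp)
  band_tab <- compare_bands(M, dat$concentrations, sel$bands,
                            split_seed = cfg$split_seed,
                            ncomp = cfg$pls_ncomp)

  utils::write.csv(data.frame(wavelength = curve$wavelengths,
                              r = curve$r, r_squared = curve$r_squared),
                   file.path(cfg$out_dir, "correlation_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(pre_tab,
                   file.path(cfg$out_dir, "preprocessing_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(band_tab,
                   file.path(cfg$out_dir, "band_comparison.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(primary_band_nm = sel$primary, bands_nm = sel$bands,
         evidence = sel$evidence),
    file.path(cfg$out_dir, "bands.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_manifest(cfg, "wavelength",
                 list(spectra_csv = cfg$spectra_csv,
                      primary_band_nm = sel$primary))
  invisible(list(selection = sel, preprocessing_table = pre_tab,
                 band_table = band_tab))
}

# log(1/R) needs strictly positive reflectance; derivatives and centered
# schemes can be <= 0, so shift-rescale those onto (0, 1]
clip_positive <- function(M) {
  R <- M$reflectance
  if (all(R > 0)) return(M)
  rng <- range(R)
  set_reflectance(M, (R - rng[1L]) / (rng[2L] - rng[1L]) * 0.999 + 0.001)
}

#' Training stage: images to fitted model
#'
#' Batch-segments every PNG under `image_dir`, extracts the 10 features,
#' fits the residue CNN on the 8:2 split, and writes the feature CSV, the
#' training log, the evaluation report, the model container and a
#' manifest under `out_dir`. Images failing segmentation are skipped and
#' logged.
#'
#' @param cfg a [pipeline_config()] with `image_dir` set.
#' @return the fitted [residue_cnn()], invisibly.
#' @export
run_training_stage <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$image_dir)) stop("`image_dir` not set")
  labels <- read_labels_csv(cfg$labels_csv)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  feats <- extract_features_dir(cfg$image_dir)
  keep <- match(feats$sample_id, labels$sample_id)
  if (anyNA(keep))
    stop("images without labels: ",
         paste(utils::head(feats$sample_id[is.na(keep)], 5L),
               collapse = ", "))
  y <- labels$concentration[keep]
  utils::write.csv(feats, file.path(cfg$out_dir, "features.csv"),
                   row.names = FALSE)

  fit <- residue_cnn(feats, y, cfg$cnn)
  utils::write.csv(fit$log, file.path(cfg$out_dir, "training_log.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$metrics),
                   file.path(cfg$out_dir, "eval_report.csv"),
                   row.names = FALSE)
  save_model(fit, file.path(cfg$out_dir, "model.rds"))
  write_manifest(cfg, "training",
                 list(image_dir = cfg$image_dir,
                      n_images = nrow(feats),
                      n_skipped = length(attr(feats, "skipped")),
                      test_rmse = fit$metrics$rmse[2L],
                      test_r2 = fit$metrics$r2[2L]))
  invisible(fit)
}

#' Predict residue concentration for leaf images
#'
#' Loads a saved model container, runs each image through segmentation,
#' feature extraction and the network, and returns one concentration per
#' image.
#'
#' @param model_path path to a [save_model()] container.
#' @param image_paths one or more PNG paths.
#' @return named numeric vector of concentrations (mg/kg).
#' @export
run_predict <- function(model_path, image_paths) {
  model <- load_model(model_path)
  out <- vapply(image_paths, function(p) {
    img <- read_leaf_png(p)
    mask <- segment_leaf(img)
    feats <- compute_features(img, mask)
    predict(model, matrix(feats, nrow = 1L))
  }, numeric(1L))
  names(out) <- tools::file_path_sans_ext(basename(image_paths))
  out
}
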