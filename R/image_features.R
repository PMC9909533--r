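#' Read and write leaf images as PNG
#'
#' Images are handled throughout as height x width x 3 arrays of 8-bit
#' values (channel order R, G, B). Grayscale PNGs are expanded to three
#' identical channels; an alpha channel, if present, is dropped.
#'
#' @param path PNG file path.
#' @return `read_leaf_png()` returns the 8-bit image array.
#' @export
read_leaf_png <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] >= 4L) a <- a[, , 1:3, drop = FALSE]
  round(a[, , 1:3, drop = FALSE] * 255)
}

#' @rdname read_leaf_png
#' @param img height x width x 3 array of 8-bit values.
#' @export
write_leaf_png <- function(img, path) {
  check_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

check_image <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("image must be a height x width x 3 array")
  if (any(img < 0 | img > 255)) stop("image values must lie in [0, 255]")
  invisible(img)
}

#' Grayscale conversion
#'
#' ITU-R BT.601 luminance `0.299 R + 0.587 G + 0.114 B`, rounded to 8-bit.
#' The weights are configurable.
#'
#' @param img height x width x 3 image array, 8-bit values.
#' @param weights RGB luminance weights (summing to 1).
#' @return height x width matrix of 8-bit gray values.
#' @examples
#' to_gray(array(c(100, 150, 200), dim = c(1, 1, 3)))
#' @export
to_gray <- function(img, weights = c(0.299, 0.587, 0.114)) {
  check_image(img)
  g <- round(weights[1L] * img[, , 1L] + weights[2L] * img[, , 2L] +
               weights[3L] * img[, , 3L])
  matrix(g, dim(img)[1L], dim(img)[2L])
}

#' Segment the leaf from the dark background
#'
#' Otsu thresholding of the gray image (foreground = brighter side, since
#' the leaf is lit against a dark background), morphological closing then
#' opening with a 3 x 3 square structuring element, then the largest
#' connected component.
#'
#' @param img height x width x 3 image array.
#' @param channel `"gray"` to threshold the luminance image (default), or
#'   `"R"`, `"G"`, `"B"` to threshold a single channel.
#' @return logical height x width foreground mask.
#' @export
segment_leaf <- function(img, channel = c("gray", "R", "G", "B")) {
  check_image(img)
  channel <- match.arg(channel)
  g <- switch(channel, gray = to_gray(img), R = img[, , 1L],
              G = img[, , 2L], B = img[, , 3L])
  if (max(g) == min(g))
    stop("uniform image: no contrast to segment")
  th <- EBImage::otsu(g / 255, range = c(0, 1))
  mask <- g / 255 > th
  brush <- EBImage::makeBrush(3L, shape = "box")
  cleaned <- EBImage::opening(EBImage::closing(mask, brush), brush) > 0.5
  if (!any(cleaned))
    stop("empty foreground after morphological cleanup")
  labels <- EBImage::bwlabel(cleaned)
  tab <- tabulate(labels[labels > 0])
  cleaned & (labels == which.max(tab))
}

#' Zero out background pixels
#'
#' Sets every background pixel to 0 in all three channels; foreground
#' pixels are untouched.
#'
#' @param img height x width x 3 image array.
#' @param mask logical foreground mask of matching spatial shape.
#' @return de-backgrounded image array.
#' @export
remove_background <- function(img, mask) {
  check_image(img)
  if (!identical(dim(mask), dim(img)[1:2]))
    stop("mask shape must match the image")
  if (!any(mask)) stop("empty foreground mask")
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[!mask] <- 0
    img[, , ch] <- plane
  }
  img
}

#' The 10 leaf-image features
#'
#' Computes, over foreground pixels only: the average gray value of the
#' de-backgrounded image, and the per-channel mean, standard deviation
#' (population form, denominator N) and coefficient of variation (sd/mean)
#' of R, G and B. A channel with zero mean gets cv = 0 with a warning.
#'
#' @param img height x width x 3 image array.
#' @param mask logical foreground mask; must contain at least one pixel.
#' @return named numeric vector of length 10:
#'   `avg_gray, mean_R, mean_G, mean_B, sd_R, sd_G, sd_B, cv_R, cv_G, cv_B`.
#' @export
compute_features <- function(img, mask) {
  check_image(img)
  if (!identical(dim(mask), dim(img)[1:2]))
    stop("mask shape must match the image")
  if (!any(mask)) stop("empty foreground mask")
  clean <- remove_background(img, mask)
  g <- to_gray(clean)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  means <- sds <- cvs <- numeric(3L)
  for (ch in 1:3) {
    v <- clean[, , ch][mask]
    means[ch] <- mean(v)
    sds[ch] <- pop_sd(v)
    if (means[ch] > 0) {
      cvs[ch] <- sds[ch] / means[ch]
    } else {
      warning("channel mean of 0; cv reported as 0")
      cvs[ch] <- 0
    }
  }
  c(avg_gray = mean(g[mask]),
    mean_R = means[1L], mean_G = means[2L], mean_B = means[3L],
    sd_R = sds[1L], sd_G = sds[2L], sd_B = sds[3L],
    cv_R = cvs[1L], cv_G = cvs[2L], cv_B = cvs[3L])
}

#' Batch feature extraction from an image directory
#'
#' Walks every PNG in `dir`, segments, de-backgrounds and extracts the 10
#' features. Images that fail segmentation are skipped with a message and
#' recorded in the `skipped` attribute, not fatal.
#'
#' @param dir directory of PNG images.
#' @param channel segmentation channel, see [segment_leaf()].
#' @param mask_dir optional directory to write binary mask PNGs for audit.
#' @return data frame with `sample_id` plus the 10 feature columns; the
#'   character vector of skipped files is attached as attribute
#'   `"skipped"`.
#' @export
extract_features_dir <- function(dir, channel = "gray", mask_dir = NULL) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG images found in ", dir)
  if (!is.null(mask_dir))
    dir.create(mask_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); skipped <- character(0)
  for (f in files) {
    id <- tools::file_path_sans_ext(basename(f))
    feats <- tryCatch({
      img <- read_leaf_png(f)
      mask <- segment_leaf(img, channel)
      if (!is.null(mask_dir))
        png::writePNG(mask * 1, file.path(mask_dir, paste0(id, ".png")))
      compute_features(img, mask)
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(feats)) skipped <- c(skipped, basename(f))
    else rows[[id]] <- feats
  }
  if (length(rows) == 0L) stop("every image failed segmentation")
  out <- data.frame(sample_id = names(rows),
                    do.call(rbind, rows), row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}
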