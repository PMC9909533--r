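make_uniform_image <- function(h, w, rgb) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

test_that("grayscale conversion uses BT.601 weights, rounded to 8-bit", {
  expect_equal(to_gray(make_uniform_image(2, 2, c(255, 255, 255))),
               matrix(255, 2, 2))
  expect_equal(to_gray(make_uniform_image(2, 2, c(0, 0, 0))),
               matrix(0, 2, 2))
  expect_equal(to_gray(make_uniform_image(1, 1, c(100, 150, 200)))[1, 1],
               round(0.299 * 100 + 0.587 * 150 + 0.114 * 200))  # 141
})

test_that("segmentation recovers the exact disk and rejects flat images", {
  cfg <- image_sim_config(pixel_noise_sd = 0, blob_radius = 20, seed = 1)
  im <- generate_leaf_image(1, cfg)
  mask <- segment_leaf(im$image)
  expect_identical(mask, im$mask)
  expect_identical(sum(mask), disk_area_oracle(cfg$width, cfg$height, 20))
  expect_error(segment_leaf(make_uniform_image(10, 10, c(50, 50, 50))),
               "uniform")
})

test_that("the segmented area is stable under global brightness scaling", {
  cfg <- image_sim_config(pixel_noise_sd = 0,
                          base_channel_levels = c(100, 80, 40),
                          background_level = 8)
  im <- generate_leaf_image(0, cfg)
  scaled <- im$image * 1.2                  # stays within 8-bit range
  expect_identical(segment_leaf(scaled), segment_leaf(im$image))
})

test_that("background removal zeroes exactly the masked-out pixels", {
  img <- make_uniform_image(4, 4, c(10, 20, 30))
  full <- matrix(TRUE, 4, 4)
  expect_identical(remove_background(img, full), img)
  expect_error(remove_background(img, matrix(FALSE, 4, 4)), "empty")
  checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  out <- remove_background(img, checker)
  for (ch in 1:3) {
    expect_true(all(out[, , ch][checker] == c(10, 20, 30)[ch]))
    expect_true(all(out[, , ch][!checker] == 0))
  }
  expect_error(remove_background(img, matrix(TRUE, 3, 3)), "shape")
})

test_that("the 10 features match hand arithmetic and the pixel-loop oracle", {
  img <- make_uniform_image(5, 5, c(100, 100, 100))
  mask <- matrix(TRUE, 5, 5)
  f <- compute_features(img, mask)
  expect_equal(unname(f), c(100, 100, 100, 100, 0, 0, 0, 0, 0, 0))
  # two-pixel foreground, R values {10, 20}
  img2 <- make_uniform_image(1, 2, c(0, 50, 50))
  img2[1, 1, 1] <- 10; img2[1, 2, 1] <- 20
  f2 <- compute_features(img2, matrix(TRUE, 1, 2))
  expect_equal(unname(f2["mean_R"]), 15)
  expect_equal(unname(f2["sd_R"]), 5)
  expect_equal(unname(f2["cv_R"]), 1 / 3)
  # random blob against the explicit pixel loop
  set.seed(16)
  im <- generate_leaf_image(1.2, image_sim_config(width = 24, height = 24,
                                                  blob_radius = 8,
                                                  pixel_noise_sd = 4,
                                                  seed = 16))
  expect_equal(compute_features(im$image, im$mask),
               pixel_loop_features(im$image, im$mask), tolerance = 1e-12)
})

test_that("features ignore background content entirely", {
  set.seed(17)
  im <- generate_leaf_image(1, image_sim_config(width = 24, height = 24,
                                                blob_radius = 8, seed = 17))
  f1 <- compute_features(im$image, im$mask)
  altered <- im$image
  for (ch in 1:3) {
    plane <- altered[, , ch]
    plane[!im$mask] <- sample(0:255, sum(!im$mask), replace = TRUE)
    altered[, , ch] <- plane
  }
  expect_identical(compute_features(altered, im$mask), f1)
})

test_that("adding k to one channel's foreground shifts its mean, not its sd", {
  set.seed(18)
  im <- generate_leaf_image(0.5, image_sim_config(width = 24, height = 24,
                                                  blob_radius = 8,
                                                  base_channel_levels =
                                                    c(100, 90, 50),
                                                  seed = 18))
  f1 <- compute_features(im$image, im$mask)
  shifted <- im$image
  plane <- shifted[, , 2]
  plane[im$mask] <- plane[im$mask] + 20     # no clipping at these levels
  shifted[, , 2] <- plane
  f2 <- compute_features(shifted, im$mask)
  expect_equal(unname(f2["mean_G"] - f1["mean_G"]), 20)
  expect_equal(f2["sd_G"], f1["sd_G"])
  expect_equal(f2[c("mean_R", "mean_B", "sd_R", "sd_B")],
               f1[c("mean_R", "mean_B", "sd_R", "sd_B")])
})

test_that("zero channel mean yields cv = 0 with a warning", {
  img <- make_uniform_image(3, 3, c(0, 10, 10))
  expect_warning(f <- compute_features(img, matrix(TRUE, 3, 3)), "cv")
  expect_equal(unname(f["cv_R"]), 0)
})

test_that("PNG round trip preserves 8-bit images", {
  set.seed(19)
  im <- generate_leaf_image(1, image_sim_config(width = 16, height = 16,
                                                blob_radius = 5, seed = 19))
  path <- tempfile(fileext = ".png")
  write_leaf_png(im$image, path)
  back <- read_leaf_png(path)
  expect_equal(back, im$image, ignore_attr = TRUE)
})
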