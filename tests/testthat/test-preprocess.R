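test_that("anterior-view selection keeps AP studies in order", {
  mk <- function(view) structure(list(pixels = matrix(1, 2, 2), view = view),
                                 class = "scintigraphy_study")
  out <- select_anterior(list(mk("AP"), mk("PA"), mk("AP")))
  expect_length(out, 2)
  expect_length(select_anterior(list()), 0)
  expect_length(select_anterior(replicate(5, mk("PA"), simplify = FALSE)), 0)
})

test_that("patient extent is the first and last row with positive line profile", {
  img <- matrix(0, 10, 10)
  img[3:8, 4] <- 1          # rows 2..7 in 0-based terms
  expect_identical(unname(locate_patient_extent(img)), c(3L, 8L))
  one <- matrix(0, 10, 10); one[6, 2] <- 5
  expect_identical(unname(locate_patient_extent(one)), c(6L, 6L))
  expect_error(locate_patient_extent(matrix(0, 4, 4)), "no patient")
})

test_that("whole-body crop follows the 0.85-height and centered-column rule", {
  # patient occupying 0-based rows 24..983 of a 1024 x 256 frame:
  # H = 960, top = round(983 - 0.85*960) = 167 (0-based), columns 64..191
  img <- matrix(0, 1024, 256)
  img[25:984, 100:150] <- 7
  win <- crop_window_whole_body(img)
  expect_identical(win$top, 168L)   # 1-based
  expect_identical(win$left, 65L)
  cropped <- crop_whole_body(img)
  expect_identical(dim(cropped), c(128L, 128L))
  expect_identical(cropped, img[168:295, 65:192], ignore_attr = TRUE)
})

test_that("crop window clamps at the image boundary", {
  # patient filling the full height of a 128-row image: raw top
  # round(127 - 0.85*128) = 18 clamps to 0 so the window fits
  img <- matrix(1, 128, 200)
  win <- crop_window_whole_body(img)
  expect_identical(win$top, 1L)
  expect_identical(dim(crop_whole_body(img)), c(128L, 128L))
})

test_that("narrow images are zero-padded with a warning", {
  img <- matrix(0, 300, 100)
  img[10:290, ] <- 2
  expect_warning(out <- crop_whole_body(img), "zero-padding")
  expect_identical(dim(out), c(128L, 128L))
  expect_true(all(out[, c(1:14, 115:128)] == 0))
})

test_that("crop windows match the brute-force oracle on seeded phantoms", {
  for (seed in 1:5) {
    cfg <- quiet_config(seed = seed,
                        patient_height_fraction = runif(1, 0.82, 0.96))
    st <- generate_whole_body(cfg, seed %% 4)
    expect_identical(crop_window_whole_body(st$pixels),
                     oracle_crop_window(st$pixels),
                     info = paste("seed", seed))
  }
})

test_that("planar crop takes the central window after area downsampling", {
  img <- matrix(0, 256, 256)
  img[65:192, 65:192] <- seq_len(128 * 128)
  out <- crop_planar(img)
  expect_identical(out, img[65:192, 65:192], ignore_attr = TRUE)
  # oversized input is area-averaged to 256 first; constants stay constant
  big <- matrix(3.5, 512, 512)
  out2 <- crop_planar(big)
  expect_identical(dim(out2), c(128L, 128L))
  expect_true(all(abs(out2 - 3.5) < 1e-12))
  expect_warning(small <- crop_planar(matrix(1, 100, 100)), "zero-padding")
  expect_identical(dim(small), c(128L, 128L))
})

test_that("area resampling preserves constants and block means", {
  x <- matrix(runif(64), 8, 8)
  down <- resample_area(x, 4, 4)
  manual <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    manual[i, j] <- mean(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(down, manual)
  expect_equal(resample_area(matrix(2, 10, 6), 3, 3),
               matrix(2, 3, 3))
  # non-integer factor still averages exactly (total mass preserved)
  y <- matrix(runif(35), 7, 5)
  expect_equal(mean(resample_area(y, 3, 2)), mean(y), tolerance = 1e-12)
})

test_that("log transform is zero-preserving, monotone, and compresses hot spots", {
  expect_identical(log_transform(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(log_transform(matrix(exp(1) - 1, 1, 1)), matrix(1, 1, 1))
  expect_error(log_transform(matrix(c(1, -2), 1, 2)), "negative")
  set.seed(4)
  v <- sort(runif(50, 0, 500))
  expect_true(all(diff(log_transform(matrix(v, 1))) > 0))
  # a hot spot 100x brighter than bone at 10 counts shrinks to ~2.88x
  ratio <- log_transform(matrix(1000, 1, 1)) / log_transform(matrix(10, 1, 1))
  expect_equal(as.numeric(ratio), log(1001) / log(11), tolerance = 1e-12)
  expect_lt(ratio, 3)
})

test_that("normalization statistics use the training images only, population SD", {
  a <- matrix(0, 4, 4); b <- matrix(2, 4, 4)
  st <- compute_norm_stats(list(a, b))
  expect_equal(st$mean, matrix(1, 4, 4))
  expect_equal(st$std, matrix(1, 4, 4))
  same <- compute_norm_stats(list(b, b))
  expect_equal(same$std, matrix(0, 4, 4))
  expect_equal(same$mean, b)
  expect_error(compute_norm_stats(list(a)), "at least 2")
})

test_that("z-scored training sets have pixel-wise zero mean and unit variance", {
  set.seed(8)
  imgs <- replicate(12, matrix(runif(64, 0, 6), 8, 8), simplify = FALSE)
  st <- compute_norm_stats(imgs)
  normed <- lapply(imgs, zscore_apply, stats = st)
  arr <- simplify2array(normed)
  expect_lt(max(abs(apply(arr, c(1, 2), mean))), 1e-10)
  sds <- sqrt(apply(arr, c(1, 2), function(v) mean(v^2) - mean(v)^2))
  expect_lt(max(abs(sds[st$std > st$epsilon] - 1)), 1e-10)
  # an image equal to the mean maps to zero
  expect_lt(max(abs(zscore_apply(st$mean, st))), 1e-12)
  # epsilon guard keeps constant pixels finite
  cst <- compute_norm_stats(list(matrix(3, 2, 2), matrix(3, 2, 2)))
  out <- zscore_apply(matrix(4, 2, 2), cst)
  expect_true(all(is.finite(out)))
  expect_equal(out, matrix(1 / cst$epsilon, 2, 2))
  expect_error(zscore_apply(matrix(0, 3, 3), cst), "shape")
})

test_that("preprocessing chain is deterministic and produces 128 x 128 log images", {
  studies <- generate_dataset(6, rep(0.25, 4), planar_fraction = 0.34,
                              seed = 3, base_config = phantom_config())
  pp <- preprocess_studies(studies)
  expect_length(pp$images, 6)
  for (im in pp$images) {
    expect_identical(dim(im), c(128L, 128L))
    expect_true(all(im >= 0))
  }
  pp2 <- preprocess_studies(studies)
  expect_identical(pp$images, pp2$images)
  # cardiac mask lands inside the crop for whole-body studies
  wb <- which(pp$meta$protocol == "whole_body")[1]
  mask <- crop_mask(region_mask(studies[[wb]], "cardiac"), pp$windows[[wb]])
  expect_identical(sum(mask), length(studies[[wb]]$regions$cardiac))
})
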