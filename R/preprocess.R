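# Preprocessing: anterior-view selection, thoracic cropping to 128 x 128,
# log-transform and pixel-wise z-score normalization.
#
# Geometry conventions: row 1 is cranial (top of image); all windows are
# 1-based and inclusive. The whole-body crop rule is stated in 0-based pixel
# coordinates in the literature; the arithmetic here is carried out 0-based
# and converted at the boundary, so the derived examples transfer directly.

CROP_SIZE <- 128L

#' Keep anterior-view studies
#'
#' @param studies List of `scintigraphy_study` objects.
#' @return The sub-list with `view == "AP"`, order preserved (possibly
#'   empty).
#' @export
select_anterior <- function(studies) {
  studies[vapply(studies, function(s) identical(s$view, "AP"), logical(1))]
}

#' Locate the patient's vertical extent
#'
#' Measures the line profile in the y-direction (per-row count sum) and
#' returns the first and last rows with a positive sum.
#'
#' @param image A 2-D count matrix.
#' @return `c(top = ..., bottom = ...)`, 1-based row indices.
#' @export
locate_patient_extent <- function(image) {
  rs <- rowSums(image)
  nz <- which(rs > 0)
  if (length(nz) == 0L) stop("no patient detected: image is all zero")
  c(top = nz[1], bottom = nz[length(nz)])
}

# round half away from zero (commercial rounding), used for fractional crop
# coordinates
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Whole-body thoracic crop window
#'
#' With patient height H (from [locate_patient_extent()]) and bottom row B
#' (0-based), the window top is `round(B - 0.85 * H)`; the window spans 128
#' rows downward and 128 columns centered on the image's vertical midline
#' (64 left, 64 right). The window is clamped inside the image.
#'
#' @param image A 2-D count matrix taller than 128 rows.
#' @param center `"image"` (default) centers columns on the geometric image
#'   center; `"patient"` centers on the midpoint of the nonzero columns.
#' @return `list(top, left)`: 1-based window origin of the 128 x 128 window.
#' @export
crop_window_whole_body <- function(image, center = c("image", "patient")) {
  center <- match.arg(center)
  ext <- locate_patient_extent(image)
  H <- nrow(image); W <- ncol(image)
  hp <- ext["bottom"] - ext["top"] + 1            # patient height, pixels
  b0 <- ext["bottom"] - 1                         # 0-based bottom row
  top0 <- round_half_away(b0 - 0.85 * hp)
  top0 <- min(max(top0, 0), max(H - CROP_SIZE, 0))
  mid0 <- if (center == "image") W / 2 else {
    cs <- colSums(image); nzc <- which(cs > 0)
    (nzc[1] - 1 + nzc[length(nzc)] - 1) / 2 + 0.5
  }
  left0 <- round_half_away(mid0 - CROP_SIZE / 2)
  left0 <- min(max(left0, 0), max(W - CROP_SIZE, 0))
  list(top = as.integer(top0) + 1L, left = as.integer(left0) + 1L)
}

# Extract a 128 x 128 window at a 1-based origin, zero-padding where the
# image is smaller than the window.
extract_window <- function(image, top, left, size = CROP_SIZE) {
  out <- matrix(0, size, size)
  rr <- top:(top + size - 1L); cc <- left:(left + size - 1L)
  rok <- rr >= 1L & rr <= nrow(image)
  cok <- cc >= 1L & cc <= ncol(image)
  out[which(rok), which(cok)] <- image[rr[rok], cc[cok]]
  out
}

#' Crop a whole-body image to the 128 x 128 thoracic matrix
#'
#' Applies the window from [crop_window_whole_body()]. Images narrower than
#' 128 columns are zero-padded symmetrically (with a warning).
#'
#' @inheritParams crop_window_whole_body
#' @return A 128 x 128 matrix with the window origin attached as
#'   `attr(, "window")`.
#' @export
crop_whole_body <- function(image, center = c("image", "patient")) {
  if (nrow(image) < CROP_SIZE)
    warning("image shorter than 128 rows; zero-padding")
  if (ncol(image) < CROP_SIZE)
    warning("image narrower than 128 columns; zero-padding symmetrically")
  win <- crop_window_whole_body(image, center)
  if (ncol(image) < CROP_SIZE)
    win$left <- as.integer(round_half_away(ncol(image) / 2 - CROP_SIZE / 2)) + 1L
  out <- extract_window(image, win$top, win$left)
  attr(out, "window") <- win
  out
}

#' Crop a planar thoracic image to 128 x 128
#'
#' If either dimension exceeds 256, the image is first resampled to
#' 256 x 256 by area (block) averaging; the central 128 x 128 window is then
#' returned (rows and columns 64-191 in 0-based coordinates for a 256 x 256
#' matrix). Images smaller than 128 x 128 are zero-padded centrally with a
#' warning.
#'
#' @param image A 2-D count matrix.
#' @return A 128 x 128 matrix with `attr(, "window")` (origin within the
#'   possibly resampled image) and `attr(, "resampled")`.
#' @export
crop_planar <- function(image) {
  resampled <- FALSE
  if (nrow(image) > 256L || ncol(image) > 256L) {
    image <- resample_area(image, 256L, 256L)
    resampled <- TRUE
  }
  if (nrow(image) < CROP_SIZE || ncol(image) < CROP_SIZE)
    warning("planar image smaller than 128 x 128; zero-padding")
  top <- floor((nrow(image) - CROP_SIZE) / 2) + 1L
  left <- floor((ncol(image) - CROP_SIZE) / 2) + 1L
  out <- extract_window(image, top, left)
  attr(out, "window") <- list(top = top, left = left)
  attr(out, "resampled") <- resampled
  out
}

#' Area-average (block) resampling
#'
#' Exact area-weighted averaging to an arbitrary target grid: each target
#' cell averages the source cells it covers, with fractional edge weights.
#' Preserves constants and (up to the area scale) total counts; reduces to
#' plain block averaging for integer factors.
#'
#' @param x Numeric matrix.
#' @param out_h,out_w Target size.
#' @return An `out_h` x `out_w` matrix.
#' @export
resample_area <- function(x, out_h, out_w) {
  area_weights <- function(n_in, n_out) {
    w <- matrix(0, n_out, n_in)
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      a <- (i - 1) * scale; b <- i * scale
      j1 <- floor(a) + 1; j2 <- ceiling(b)
      for (j in j1:min(j2, n_in)) {
        lo <- max(a, j - 1); hi <- min(b, j)
        if (hi > lo) w[i, j] <- (hi - lo) / scale
      }
    }
    w
  }
  A <- area_weights(nrow(x), out_h)
  B <- area_weights(ncol(x), out_w)
  A %*% x %*% t(B)
}

#' Log-transform count images
#'
#' Applies `log(1 + x)` elementwise: zeros stay zero, the map is strictly
#' monotone on non-negative counts, and hot spots (injection site, focal
#' lesions) are compressed relative to bone so they cannot dominate the
#' normalized intensity scale.
#'
#' @param image Non-negative numeric matrix (or array).
#' @return Transformed matrix of the same shape.
#' @export
log_transform <- function(image) {
  if (any(image < 0)) stop("invalid counts: negative pixel values")
  log1p(image)
}

#' Pixel-wise normalization statistics from a training set
#'
#' Per-pixel mean and (population) standard deviation over the training
#' images only; test images must never contribute.
#'
#' @param train_images List of 128 x 128 matrices (or a 3-D array with the
#'   image index last).
#' @param epsilon Floor applied to the standard deviation at division time.
#' @return An object of class `norm_stats` with `$mean`, `$std`,
#'   `$epsilon`, `$n`.
#' @export
compute_norm_stats <- function(train_images, epsilon = 1e-7) {
  if (is.list(train_images))
    train_images <- simplify2array(train_images)
  if (length(dim(train_images)) != 3L || dim(train_images)[3] < 2L)
    stop("need at least 2 training images")
  n <- dim(train_images)[3]
  mu <- apply(train_images, c(1, 2), mean)
  sq <- apply(train_images^2, c(1, 2), mean)
  structure(list(mean = mu, std = sqrt(pmax(sq - mu^2, 0)),
                 epsilon = epsilon, n = n),
            class = "norm_stats")
}

#' Apply z-score normalization
#'
#' Returns `(image - mean) / max(std, epsilon)` elementwise with the
#' training-set statistics.
#'
#' @param image Matrix matching the statistics' shape.
#' @param stats A [compute_norm_stats()] result.
#' @return Normalized matrix.
#' @export
zscore_apply <- function(image, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (!all(dim(image) == dim(stats$mean)))
    stop("image shape does not match normalization statistics")
  (image - stats$mean) / pmax(stats$std, stats$epsilon)
}

#' Preprocess a list of studies
#'
#' Full deterministic chain: keep anterior views, crop whole-body or planar
#' studies to the 128 x 128 thoracic matrix, log-transform. Normalization is
#' deliberately left to the cross-validation loop, where the statistics must
#' come from each training fold alone.
#'
#' @param studies List of `scintigraphy_study` objects.
#' @return `list(images, meta, windows)`: cropped log-count matrices, a
#'   metadata data frame (id, grade, has_metastases, protocol), and the crop
#'   windows for mapping region masks into crop coordinates.
#' @export
preprocess_studies <- function(studies) {
  studies <- select_anterior(studies)
  images <- vector("list", length(studies))
  windows <- vector("list", length(studies))
  meta <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    cropped <- if (st$protocol == "whole_body") crop_whole_body(st$pixels)
               else crop_planar(st$pixels)
    images[[i]] <- log_transform(cropped)
    windows[[i]] <- attr(cropped, "window")
    meta[[i]] <- data.frame(id = st$id %||% sprintf("S%04d", i),
                            grade = st$grade,
                            has_metastases = st$has_metastases %||% FALSE,
                            protocol = st$protocol)
  }
  list(images = images, meta = do.call(rbind, meta), windows = windows)
}

#' Map a full-frame region mask into crop coordinates
#'
#' Applies a crop window (as attached by [crop_whole_body()] or
#' [crop_planar()]) to a logical mask, e.g. the phantom cardiac region, so
#' that masks line up with preprocessed images.
#'
#' @param mask Logical matrix in full-image coordinates.
#' @param window `list(top, left)` window origin.
#' @return A 128 x 128 logical matrix.
#' @export
crop_mask <- function(mask, window) {
  extract_window(mask * 1, window$top, window$left) > 0
}
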