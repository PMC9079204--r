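# Synthetic bone-scintigraphy phantoms.
#
# The skeleton is a deterministic parametric template (ellipses, bars, bands)
# in body-relative coordinates — plausible count topology rather than anatomy.
# Grades are encoded through the mean cardiac count level relative to bone;
# the cardiac ellipse adds its uptake on top of the soft-tissue background,
# and skeletal template pixels are carved out of the ellipse so that its mean
# is exactly background + ratio x bone on noiseless phantoms.

#' Default grade-to-ratio intervals
#'
#' Cardiac-to-bone mean count ratio intervals per Perugini grade. Grade 0
#' (no uptake) sits near zero, grade 1 below bone level, grade 2 around bone
#' level and grade 3 above it. The default intervals are disjoint so phantom
#' classes are unambiguous; pass overlapping intervals to probe the difficult
#' grade 1/2 boundary.
#'
#' @return A 4 x 2 matrix, one row per grade 0-3, columns `lo` and `hi`.
#' @export
default_grade_intervals <- function() {
  m <- rbind(c(0, 0.15), c(0.3, 0.8), c(0.9, 1.1), c(1.3, 2.5))
  dimnames(m) <- list(paste0("grade", 0:3), c("lo", "hi"))
  m
}

#' Phantom configuration
#'
#' @param protocol `"whole_body"` (default 1024 x 256 frame) or `"planar"`
#'   (thoracic field of view, default 256 x 256).
#' @param image_height,image_width Frame size in pixels; defaults depend on
#'   `protocol`.
#' @param patient_height_fraction Fraction of the frame height occupied by
#'   the body (whole-body protocol), in (0, 1].
#' @param bone_intensity Mean counts per skeletal pixel.
#' @param cardiac_ratio Ratio of mean cardiac counts to `bone_intensity`;
#'   `NULL` (default) draws it from the grade interval at generation time.
#' @param background_intensity Mean counts per soft-tissue pixel; must be
#'   strictly below `bone_intensity`.
#' @param hotspot_rate Expected number of focal hot spots (injection site);
#'   the realized number is Poisson-distributed.
#' @param metastasis_count Number of focal bone lesions (integer >= 0).
#' @param noise_model `"poisson"` for Poisson counting noise, `"none"` for
#'   the noiseless template.
#' @param grade_intervals Grade-to-ratio interval matrix, see
#'   [default_grade_intervals()].
#' @param vertical_offset,horizontal_offset Body displacement in pixels from
#'   the centered position, for patient-position variability.
#' @param seed Integer seed; generation is deterministic given the
#'   configuration.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(protocol = c("whole_body", "planar"),
                           image_height = NULL, image_width = 256L,
                           patient_height_fraction = 0.9,
                           bone_intensity = 100,
                           cardiac_ratio = NULL,
                           background_intensity = 5,
                           hotspot_rate = 1,
                           metastasis_count = 0L,
                           noise_model = c("poisson", "none"),
                           grade_intervals = default_grade_intervals(),
                           vertical_offset = 0L, horizontal_offset = 0L,
                           seed = 1L) {
  protocol <- match.arg(protocol)
  noise_model <- match.arg(noise_model)
  if (is.null(image_height))
    image_height <- if (protocol == "whole_body") 1024L else 256L
  if (image_height <= 0 || image_width <= 0)
    stop("image dimensions must be positive")
  if (!(bone_intensity > background_intensity && background_intensity >= 0))
    stop("must have bone_intensity > background_intensity >= 0")
  if (!is.null(cardiac_ratio) && cardiac_ratio < 0)
    stop("cardiac_ratio must be >= 0")
  if (patient_height_fraction <= 0 || patient_height_fraction > 1)
    stop("patient_height_fraction must be in (0, 1]")
  if (hotspot_rate < 0) stop("hotspot_rate must be >= 0")
  if (metastasis_count < 0) stop("metastasis_count must be >= 0")
  structure(list(protocol = protocol,
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 patient_height_fraction = patient_height_fraction,
                 bone_intensity = bone_intensity,
                 cardiac_ratio = cardiac_ratio,
                 background_intensity = background_intensity,
                 hotspot_rate = hotspot_rate,
                 metastasis_count = as.integer(metastasis_count),
                 noise_model = noise_model,
                 grade_intervals = grade_intervals,
                 vertical_offset = as.integer(vertical_offset),
                 horizontal_offset = as.integer(horizontal_offset),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Draw a cardiac-to-bone ratio for a Perugini grade
#'
#' Samples uniformly from the grade's configured interval using the current
#' RNG state. A degenerate interval (lo == hi) returns that value exactly.
#'
#' @param grade Integer grade 0-3.
#' @param intervals 4 x 2 interval matrix, see [default_grade_intervals()].
#' @return A single non-negative ratio.
#' @export
grade_to_ratio <- function(grade, intervals = default_grade_intervals()) {
  if (length(grade) != 1L || is.na(grade) || !grade %in% 0:3)
    stop("grade must be a single integer in 0..3")
  lo <- intervals[grade + 1L, 1L]; hi <- intervals[grade + 1L, 2L]
  if (hi < lo) stop("interval upper bound below lower bound")
  if (hi == lo) lo else runif(1L, lo, hi)
}

# Elliptical mask on a pixel grid (1-based coordinates).
ellipse_mask <- function(H, W, center_r, center_c, semi_r, semi_c) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((r - center_r) / semi_r)^2 + ((c - center_c) / semi_c)^2 <= 1
}

band_mask <- function(H, W, r1, r2, c1, c2) {
  m <- matrix(FALSE, H, W)
  rr <- max(1L, round(r1)):min(H, round(r2))
  cc <- max(1L, round(c1)):min(W, round(c2))
  if (length(rr) > 0 && length(cc) > 0) m[rr, cc] <- TRUE
  m
}

# Deterministic noiseless template for a whole-body AP acquisition.
# Returns list(img, regions).
whole_body_template <- function(cfg, ratio) {
  H <- cfg$image_height; W <- cfg$image_width
  Hb <- round(cfg$patient_height_fraction * H)
  t0 <- max(1L, floor((H - Hb) / 2) + 1L + cfg$vertical_offset)
  if (t0 + Hb - 1L > H) t0 <- H - Hb + 1L
  b0 <- t0 + Hb - 1L
  m <- W / 2 + cfg$horizontal_offset
  ur <- function(u) t0 + u * (Hb - 1)      # body-relative row coordinate
  soft <- matrix(FALSE, H, W); bone <- matrix(FALSE, H, W)
  add <- function(acc, msk) acc | msk
  # soft tissue silhouette: head, neck, torso, arms, legs
  soft <- add(soft, ellipse_mask(H, W, ur(0.05), m, 0.05 * (Hb - 1), 0.045 * W))
  # crown cap: guarantees the first body row is occupied after discretization
  soft <- add(soft, band_mask(H, W, t0, ur(0.05), m - 0.01 * W, m + 0.01 * W))
  soft <- add(soft, band_mask(H, W, ur(0.09), ur(0.135), m - 0.02 * W, m + 0.02 * W))
  soft <- add(soft, band_mask(H, W, ur(0.13), ur(0.50), m - 0.16 * W, m + 0.16 * W))
  for (s in c(-1, 1))
    soft <- add(soft, band_mask(H, W, ur(0.135), ur(0.55),
                                m + s * 0.19 * W - 0.02 * W,
                                m + s * 0.19 * W + 0.02 * W))
  for (s in c(-1, 1))
    soft <- add(soft, band_mask(H, W, ur(0.48), ur(1.0),
                                m + s * 0.065 * W - 0.035 * W,
                                m + s * 0.065 * W + 0.035 * W))
  # skeleton
  skull <- ellipse_mask(H, W, ur(0.05), m, 0.05 * (Hb - 1), 0.045 * W) &
    !ellipse_mask(H, W, ur(0.05), m, 0.038 * (Hb - 1), 0.034 * W)
  bone <- add(bone, skull)
  bone <- add(bone, band_mask(H, W, ur(0.13), ur(0.16), m - 0.012 * W, m + 0.012 * W))
  bone <- add(bone, band_mask(H, W, ur(0.30), ur(0.48), m - 0.012 * W, m + 0.012 * W))
  sternum <- band_mask(H, W, ur(0.16), ur(0.30), m - 0.008 * W, m + 0.008 * W)
  bone <- add(bone, sternum)
  shoulders <- band_mask(H, W, ur(0.130), ur(0.142), m - 0.17 * W, m + 0.17 * W)
  bone <- add(bone, shoulders)
  ribs <- matrix(FALSE, H, W)
  for (k in 1:6) for (s in c(-1, 1))
    ribs <- add(ribs, band_mask(H, W, ur(0.16 + 0.025 * k) - 0.004 * Hb,
                                ur(0.16 + 0.025 * k) + 0.004 * Hb,
                                m + s * 0.03 * W - (s < 0) * 0.12 * W,
                                m + s * 0.03 * W + (s > 0) * 0.12 * W))
  bone <- add(bone, ribs)
  for (s in c(-1, 1))  # humeri
    bone <- add(bone, band_mask(H, W, ur(0.145), ur(0.38),
                                m + s * 0.19 * W - 0.005 * W,
                                m + s * 0.19 * W + 0.005 * W))
  pelvis <- ellipse_mask(H, W, ur(0.52), m, 0.045 * (Hb - 1), 0.11 * W) &
    !ellipse_mask(H, W, ur(0.52), m, 0.030 * (Hb - 1), 0.075 * W)
  bone <- add(bone, pelvis)
  for (s in c(-1, 1))  # femurs
    bone <- add(bone, band_mask(H, W, ur(0.55), ur(0.97),
                                m + s * 0.065 * W - 0.006 * W,
                                m + s * 0.065 * W + 0.006 * W))
  # cardiac ellipse, left of midline in the thorax; bones carved out
  cardiac <- ellipse_mask(H, W, ur(0.22), m - 0.055 * W,
                          0.045 * (Hb - 1), 0.055 * W)
  bone <- bone & !cardiac
  sternum <- sternum & !cardiac
  ribs <- ribs & !cardiac
  soft <- add(soft, cardiac)
  img <- matrix(0, H, W)
  img[soft] <- cfg$background_intensity
  img[bone] <- cfg$bone_intensity
  img[cardiac] <- cfg$background_intensity + ratio * cfg$bone_intensity
  # reference soft-tissue patch (abdomen, below the sternum, bone-free)
  reference <- band_mask(H, W, ur(0.40), ur(0.46), m + 0.04 * W, m + 0.13 * W)
  reference <- reference & !bone
  arm <- matrix(FALSE, H, W)
  for (s in c(-1, 1))
    arm <- add(arm, band_mask(H, W, ur(0.40), ur(0.54),
                              m + s * 0.19 * W - 0.015 * W,
                              m + s * 0.19 * W + 0.015 * W))
  list(img = img, regions = list(cardiac = cardiac, sternum = sternum,
                                 ribs = ribs, bone = bone, soft = soft,
                                 reference = reference, arm = arm),
       extent = c(top = t0, bottom = b0))
}

# Thoracic planar template: same organ logic, field of view limited to the
# chest.
planar_template <- function(cfg, ratio) {
  H <- cfg$image_height; W <- cfg$image_width
  m <- W / 2 + cfg$horizontal_offset
  soft <- band_mask(H, W, 0.06 * H, 0.98 * H, 0.12 * W, 0.88 * W)
  bone <- matrix(FALSE, H, W)
  add <- function(acc, msk) acc | msk
  shoulders <- band_mask(H, W, 0.10 * H, 0.13 * H, m - 0.34 * W, m + 0.34 * W)
  bone <- add(bone, shoulders)
  bone <- add(bone, band_mask(H, W, 0.10 * H, 0.20 * H, m - 0.02 * W, m + 0.02 * W))
  bone <- add(bone, band_mask(H, W, 0.60 * H, 0.95 * H, m - 0.02 * W, m + 0.02 * W))
  sternum <- band_mask(H, W, 0.20 * H, 0.58 * H, m - 0.015 * W, m + 0.015 * W)
  bone <- add(bone, sternum)
  ribs <- matrix(FALSE, H, W)
  for (k in 1:6) for (s in c(-1, 1))
    ribs <- add(ribs, band_mask(H, W, (0.17 + 0.065 * k) * H - 0.008 * H,
                                (0.17 + 0.065 * k) * H + 0.008 * H,
                                m + s * 0.06 * W - (s < 0) * 0.26 * W,
                                m + s * 0.06 * W + (s > 0) * 0.26 * W))
  bone <- add(bone, ribs)
  cardiac <- ellipse_mask(H, W, 0.42 * H, m - 0.12 * W, 0.10 * H, 0.12 * W)
  bone <- bone & !cardiac
  sternum <- sternum & !cardiac
  ribs <- ribs & !cardiac
  soft <- add(soft, cardiac)
  img <- matrix(0, H, W)
  img[soft] <- cfg$background_intensity
  img[bone] <- cfg$bone_intensity
  img[cardiac] <- cfg$background_intensity + ratio * cfg$bone_intensity
  reference <- band_mask(H, W, 0.70 * H, 0.85 * H, m + 0.10 * W, m + 0.25 * W) & !bone
  arm <- band_mask(H, W, 0.30 * H, 0.70 * H, 0.13 * W, 0.18 * W)
  list(img = img, regions = list(cardiac = cardiac, sternum = sternum,
                                 ribs = ribs, bone = bone, soft = soft,
                                 reference = reference, arm = arm),
       extent = c(top = round(0.06 * H), bottom = round(0.98 * H)))
}

disc_into <- function(img, r, c, radius, value) {
  msk <- ellipse_mask(nrow(img), ncol(img), r, c, radius, radius)
  img[msk] <- pmax(img[msk], value)
  img
}

phantom_study <- function(cfg, grade, template_fun) {
  if (!grade %in% 0:3) stop("grade must be in 0..3")
  with_seed(cfg$seed, {
    ratio <- cfg$cardiac_ratio %||% grade_to_ratio(grade, cfg$grade_intervals)
    tpl <- template_fun(cfg, ratio)
    img <- tpl$img
    # injection-site hot spots in the arm region, 5-20 x bone intensity
    n_hot <- if (cfg$hotspot_rate > 0) rpois(1L, cfg$hotspot_rate) else 0L
    arm_px <- which(tpl$regions$arm)
    if (n_hot > 0 && length(arm_px) > 0) {
      for (i in seq_len(n_hot)) {
        px <- arm_px[sample.int(length(arm_px), 1L)]
        img <- disc_into(img, (px - 1L) %% nrow(img) + 1L,
                         (px - 1L) %/% nrow(img) + 1L,
                         0.01 * ncol(img) + 1.5,
                         runif(1L, 5, 20) * cfg$bone_intensity)
      }
    }
    # focal bone lesions
    bone_px <- which(tpl$regions$bone)
    if (cfg$metastasis_count > 0 && length(bone_px) > 0) {
      for (i in seq_len(cfg$metastasis_count)) {
        px <- bone_px[sample.int(length(bone_px), 1L)]
        img <- disc_into(img, (px - 1L) %% nrow(img) + 1L,
                         (px - 1L) %/% nrow(img) + 1L,
                         0.012 * ncol(img) + 1.5,
                         runif(1L, 2, 4) * cfg$bone_intensity)
      }
    }
    if (cfg$noise_model == "poisson") {
      img <- matrix(rpois(length(img), img), nrow(img), ncol(img))
    }
    # regions kept as pixel-index vectors (which(mask)): a full-frame logical
    # mask per organ per study would dominate dataset memory
    structure(list(pixels = img, view = "AP",
                   protocol = cfg$protocol, grade = as.integer(grade),
                   has_metastases = cfg$metastasis_count > 0L,
                   age = round(runif(1L, 40, 90)),
                   cardiac_ratio = ratio,
                   regions = lapply(tpl$regions, which),
                   region_dim = dim(img), extent = tpl$extent,
                   config = cfg),
              class = "scintigraphy_study")
  })
}

#' Reconstruct a phantom region mask
#'
#' Phantom studies carry their generating region (cardiac ellipse, sternum,
#' ribs, skeleton, soft tissue, a bone-free reference patch, arm) as pixel
#' indices; this expands one to a full-frame logical mask.
#'
#' @param study A `scintigraphy_study` from the phantom generator.
#' @param name Region name, e.g. `"cardiac"` or `"sternum"`.
#' @return Logical matrix of the study's frame size.
#' @export
region_mask <- function(study, name) {
  idx <- study$regions[[name]]
  if (is.null(idx)) stop("unknown region: ", name)
  m <- matrix(FALSE, study$region_dim[1], study$region_dim[2])
  m[idx] <- TRUE
  m
}

#' Generate a whole-body phantom study
#'
#' Produces an anterior (AP) whole-body study whose nonzero rows span exactly
#' `round(patient_height_fraction * image_height)` rows, with a parametric
#' skeletal template, a cardiac ellipse left of the midline whose mean counts
#' are `background + cardiac_ratio * bone_intensity`, optional Poisson noise,
#' injection-site hot spots and focal bone lesions. Deterministic given the
#' configuration seed. Row 1 is cranial; row index grows toward the feet.
#'
#' @param config A [phantom_config()] with `protocol = "whole_body"`.
#' @param grade Perugini grade 0-3.
#' @return A `scintigraphy_study`: pixel matrix plus view/protocol/grade
#'   metadata and the generating region masks under `$regions`.
#' @export
generate_whole_body <- function(config, grade) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$protocol != "whole_body")
    config$protocol <- "whole_body"
  phantom_study(config, grade, whole_body_template)
}

#' Generate a planar thoracic phantom study
#'
#' As [generate_whole_body()] but the field of view covers only the thorax
#' (`protocol = "planar"`).
#'
#' @inheritParams generate_whole_body
#' @return A `scintigraphy_study`.
#' @export
generate_planar_thoracic <- function(config, grade) {
  stopifnot(inherits(config, "phantom_config"))
  config$protocol <- "planar"
  if (is.null(config$image_height) || config$image_height > 512L)
    config$image_height <- 256L
  phantom_study(config, grade, planar_template)
}

#' @export
print.scintigraphy_study <- function(x, ...) {
  cat(sprintf("<scintigraphy_study> %s %s, grade %d, %dx%d px, metastases: %s\n",
              x$view, x$protocol, x$grade, nrow(x$pixels), ncol(x$pixels),
              x$has_metastases))
  invisible(x)
}

#' Generate a phantom dataset with controlled class prevalence
#'
#' Per-grade counts follow largest-remainder rounding of
#' `n * class_proportions`, so e.g. 1334 studies at proportions
#' (0.743, 0.222, 0.017, 0.018) yield exactly 991/296/23/24 studies of
#' grades 0-3. Patient height, position, age, hot spots and metastasis flags
#' vary per study; everything is reproducible from `seed`.
#'
#' @param n Number of studies (>= 4).
#' @param class_proportions Length-4 vector of grade proportions summing to 1.
#' @param planar_fraction Fraction of studies acquired with the thoracic
#'   planar protocol instead of whole-body.
#' @param seed Master seed; per-study seeds are derived from it.
#' @param metastasis_rate Probability that a study carries bone metastases
#'   (then 1-3 focal lesions), independent of grade.
#' @param base_config Template [phantom_config()] supplying intensities,
#'   noise model and grade intervals.
#' @return A list of `scintigraphy_study` objects with `$id` set.
#' @export
generate_dataset <- function(n, class_proportions = c(0.743, 0.222, 0.017, 0.018),
                             planar_fraction = 0, seed = 1L,
                             metastasis_rate = 0.15,
                             base_config = phantom_config()) {
  if (n < 4) stop("n must be >= 4")
  if (length(class_proportions) != 4L)
    stop("class_proportions must have length 4")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  counts <- largest_remainder(n, class_proportions)
  grades <- rep(0:3, times = counts)
  with_seed(seed, {
    grades <- sample(grades)
    planar <- rep(FALSE, n)
    np <- round(n * planar_fraction)
    if (np > 0) planar[sample.int(n, np)] <- TRUE
    mets <- runif(n) < metastasis_rate
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    phf <- runif(n, 0.85, 0.95)
    voff <- round(runif(n, -12, 12))
    hoff <- round(runif(n, -8, 8))
    n_met <- ifelse(mets, sample(1:3, n, replace = TRUE), 0L)
  })
  studies <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- base_config
    cfg$seed <- seeds[i]
    cfg$patient_height_fraction <- phf[i]
    cfg$vertical_offset <- voff[i]
    cfg$horizontal_offset <- hoff[i]
    cfg$metastasis_count <- n_met[i]
    st <- if (planar[i]) generate_planar_thoracic(cfg, grades[i])
          else {
            cfg$protocol <- "whole_body"
            generate_whole_body(cfg, grades[i])
          }
    st$id <- sprintf("S%04d", i)
    studies[[i]] <- st
  }
  studies
}

# Integer apportionment by largest remainder (Hamilton's method); ties break
# toward the lower grade.
largest_remainder <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(-(raw - counts), seq_along(p))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1L
  }
  as.integer(counts)
}
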