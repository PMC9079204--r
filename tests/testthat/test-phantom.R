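test_that("grade-to-ratio sampling respects the configured intervals", {
  expect_error(grade_to_ratio(4), "0..3")
  expect_error(grade_to_ratio(-1), "0..3")
  # degenerate interval returns the point value without consuming randomness
  iv <- default_grade_intervals()
  iv[1, ] <- c(0, 0)
  expect_identical(grade_to_ratio(0, iv), 0)
  # exhaustive bound check for grade 2 under a fixed seed
  set.seed(99)
  draws <- replicate(1000, grade_to_ratio(2))
  expect_true(all(draws >= 0.9 & draws <= 1.1))
  # grade 3 ratios always exceed 1 (cardiac uptake above bone level)
  set.seed(100)
  expect_true(all(replicate(200, grade_to_ratio(3)) > 1))
  # intervals ordered by grade
  set.seed(101)
  means <- vapply(0:3, function(g) mean(replicate(200, grade_to_ratio(g))),
                  numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("whole-body phantoms have the configured extent and uptake ordering", {
  cfg <- quiet_config(seed = 7)
  st <- generate_whole_body(cfg, 3)
  expect_s3_class(st, "scintigraphy_study")
  expect_identical(st$view, "AP")
  expect_true(all(st$pixels >= 0))
  # nonzero rows span exactly round(patient_height_fraction x image_height)
  ext <- locate_patient_extent(st$pixels)
  expect_equal(unname(ext["bottom"] - ext["top"] + 1), round(0.9 * 1024))
  # grade 3: cardiac mean above sternum (bone) mean
  expect_gt(mean(st$pixels[st$regions$cardiac]),
            mean(st$pixels[st$regions$sternum]))
  # seeded determinism, bit-identical
  st2 <- generate_whole_body(cfg, 3)
  expect_identical(st$pixels, st2$pixels)
  # different seed, different noiseless layout is not required, but the
  # cardiac ratio draw must differ
  st3 <- generate_whole_body(quiet_config(seed = 8), 3)
  expect_false(isTRUE(all.equal(st$cardiac_ratio, st3$cardiac_ratio)))
})

test_that("a grade-0 phantom with a degenerate interval has background-level cardiac counts", {
  iv <- default_grade_intervals()
  iv[1, ] <- c(0, 0)
  st <- generate_whole_body(quiet_config(seed = 3, grade_intervals = iv), 0)
  cardiac <- mean(st$pixels[st$regions$cardiac])
  backgr <- mean(st$pixels[st$regions$reference])
  expect_lt(abs(cardiac - backgr) / backgr, 0.01)
})

test_that("extent tracks patient_height_fraction and position offsets", {
  for (phf in c(0.8, 0.9, 0.98)) {
    st <- generate_whole_body(quiet_config(patient_height_fraction = phf,
                                           seed = 2, vertical_offset = 5L), 1)
    ext <- locate_patient_extent(st$pixels)
    expect_equal(unname(ext["bottom"] - ext["top"] + 1), round(phf * 1024),
                 info = paste("phf =", phf))
  }
})

test_that("planar thoracic phantoms carry the planar protocol and grade ordering", {
  cfg <- quiet_config("planar", seed = 5)
  st <- generate_planar_thoracic(cfg, 3)
  expect_identical(st$protocol, "planar")
  expect_identical(dim(st$pixels), c(256L, 256L))
  expect_gt(mean(st$pixels[st$regions$cardiac]),
            mean(st$pixels[st$regions$ribs]))
  expect_identical(st$pixels, generate_planar_thoracic(cfg, 3)$pixels)
})

test_that("cardiac mean counts increase strictly with grade at interval centers", {
  iv <- default_grade_intervals()
  centers <- rowMeans(iv)
  means <- vapply(0:3, function(g) {
    cfg <- quiet_config(seed = 11, cardiac_ratio = centers[g + 1])
    st <- generate_whole_body(cfg, g)
    mean(st$pixels[st$regions$cardiac])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("Poisson noise conserves expected total counts", {
  cfg0 <- quiet_config("planar", seed = 1)
  template <- generate_planar_thoracic(cfg0, 2)
  target <- sum(template$pixels)
  totals <- vapply(1:100, function(i) {
    cfg <- phantom_config("planar", noise_model = "poisson", hotspot_rate = 0,
                          seed = 1000 + i,
                          cardiac_ratio = template$cardiac_ratio)
    sum(generate_planar_thoracic(cfg, 2)$pixels)
  }, numeric(1))
  # mean of 100 Poisson(target) totals: within 3 standard errors
  se <- sqrt(target / 100)
  expect_lt(abs(mean(totals) - target), 3 * se)
})

test_that("hot spots and metastases appear where and when configured", {
  st0 <- quiet_config(seed = 21)
  none <- generate_whole_body(st0, 1)
  cfg <- phantom_config(noise_model = "none", hotspot_rate = 3,
                        metastasis_count = 2L, seed = 21)
  spotty <- generate_whole_body(cfg, 1)
  expect_false(none$has_metastases)
  expect_true(spotty$has_metastases)
  # added focal uptake only ever increases counts
  expect_true(all(spotty$pixels >= none$pixels - 1e-9))
  expect_gt(max(spotty$pixels), 4 * cfg$bone_intensity)
})

test_that("dataset generation apportions grades by largest remainder", {
  counts <- scintigrade:::largest_remainder(1334, c(0.743, 0.222, 0.017, 0.018))
  expect_identical(counts, c(991L, 296L, 23L, 24L))
  expect_identical(scintigrade:::largest_remainder(100, c(1, 0, 0, 0)),
                   c(100L, 0L, 0L, 0L))
  studies <- generate_dataset(8, rep(0.25, 4), seed = 5,
                              base_config = quiet_config("planar"))
  grades <- vapply(studies, function(s) s$grade, integer(1))
  expect_identical(as.vector(table(factor(grades, levels = 0:3))),
                   rep(2L, 4))
  expect_error(generate_dataset(3, rep(0.25, 4)), ">= 4")
  expect_error(generate_dataset(10, c(0.5, 0.5, 0.1, 0)), "sum to 1")
})

test_that("dataset generation mixes protocols and replays deterministically", {
  mk <- function() generate_dataset(10, rep(0.25, 4), planar_fraction = 0.3,
                                    seed = 9,
                                    base_config = quiet_config("planar"))
  studies <- mk()
  protocols <- vapply(studies, function(s) s$protocol, character(1))
  expect_equal(sum(protocols == "planar"), 3)
  replay <- mk()
  for (i in seq_along(studies))
    expect_identical(studies[[i]]$pixels, replay[[i]]$pixels)
})

test_that("studies survive a disk round-trip", {
  dir <- withr::local_tempdir()
  studies <- generate_dataset(4, rep(0.25, 4), seed = 13,
                              base_config = phantom_config("planar"))
  meta <- write_studies(studies, file.path(dir, "out"))
  expect_equal(nrow(meta), 4)
  back <- read_studies(file.path(dir, "out"))
  for (i in 1:4) {
    expect_equal(back[[i]]$pixels, studies[[i]]$pixels,
                 ignore_attr = TRUE)
    expect_identical(back[[i]]$grade, studies[[i]]$grade)
  }
  # refuses to clobber without overwrite
  expect_error(write_studies(studies, file.path(dir, "out")), "not empty")
  # plain-text matrix format round-trips too
  write_studies(studies[1], file.path(dir, "txt"), format = "matrix")
  back2 <- read_studies(file.path(dir, "txt"))
  expect_equal(back2[[1]]$pixels, studies[[1]]$pixels, ignore_attr = TRUE)
})
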