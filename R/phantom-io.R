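# Disk round-trip for phantom studies: 16-bit TIFF count images plus a CSV
# metadata sidecar, optionally plain-text matrix files. Region masks are a
# generation-time provenance extra and are not persisted.

#' Write phantom studies to disk
#'
#' Writes one 16-bit grayscale TIFF per study (counts clamped at 65535) and a
#' `metadata.csv` sidecar with columns id, view, protocol, grade,
#' has_metastases, age, seed and file. With `format = "matrix"`,
#' tab-separated plain-text matrices are written instead of TIFF.
#'
#' @param studies List of `scintigraphy_study` objects (ids assigned if
#'   missing).
#' @param dir Output directory; must be empty or nonexistent unless
#'   `overwrite = TRUE`.
#' @param format `"tiff"` (default) or `"matrix"`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, the metadata data frame.
#' @export
write_studies <- function(studies, dir, format = c("tiff", "matrix"),
                          overwrite = FALSE) {
  format <- match.arg(format)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(id = character(0))
  rows <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    id <- st$id %||% sprintf("S%04d", i)
    file <- if (format == "tiff") paste0(id, ".tif") else paste0(id, ".tsv")
    px <- st$pixels
    if (format == "tiff") {
      if (any(px > 65535)) {
        warning("counts above 65535 clamped for 16-bit storage")
        px <- pmin(px, 65535)
      }
      tiff::writeTIFF(round(px) / 65535, file.path(dir, file),
                      bits.per.sample = 16L, compression = "none")
    } else {
      write.table(px, file.path(dir, file), sep = "\t",
                  row.names = FALSE, col.names = FALSE)
    }
    rows[[i]] <- data.frame(id = id, view = st$view, protocol = st$protocol,
                            grade = st$grade,
                            has_metastases = st$has_metastases,
                            age = st$age %||% NA_real_,
                            seed = st$config$seed %||% NA_integer_,
                            file = file)
  }
  meta <- do.call(rbind, rows)
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read phantom studies from disk
#'
#' Restores the studies written by [write_studies()] (pixel counts and
#' metadata; generation-time region masks are not persisted).
#'
#' @param dir Directory containing `metadata.csv` and the image files.
#' @return A list of `scintigraphy_study` objects.
#' @export
read_studies <- function(dir) {
  meta <- read.csv(file.path(dir, "metadata.csv"),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    file <- file.path(dir, meta$file[i])
    px <- if (grepl("\\.tsv$", file)) {
      as.matrix(read.table(file, sep = "\t"))
    } else {
      round(tiff::readTIFF(file) * 65535)
    }
    dimnames(px) <- NULL
    structure(list(pixels = px, view = meta$view[i],
                   protocol = meta$protocol[i],
                   grade = as.integer(meta$grade[i]),
                   has_metastases = as.logical(meta$has_metastases[i]),
                   age = meta$age[i], id = meta$id[i],
                   config = list(seed = meta$seed[i])),
              class = "scintigraphy_study")
  })
}
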