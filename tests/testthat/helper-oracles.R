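# Independent oracles used against the package implementations.

# All-pairs concordance count: the probability-of-concordance definition of
# the ROC AUC, with ties counted 1/2. Quadratic and brute force on purpose.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Brute-force re-derivation of the whole-body crop window from first
# principles: scan the line profile for nonzero rows, place the upper edge at
# 0.85 x patient height above the lowest body row, 128 rows down, 64 columns
# either side of the image center; clamp. Works in 0-based coordinates and
# converts at the end.
oracle_crop_window <- function(image) {
  nonzero <- integer(0)
  for (r in seq_len(nrow(image))) {
    if (sum(image[r, ]) > 0) nonzero <- c(nonzero, r)
  }
  stopifnot(length(nonzero) > 0)
  top1 <- nonzero[1]; bot1 <- nonzero[length(nonzero)]
  hp <- bot1 - top1 + 1
  b0 <- bot1 - 1
  raw <- b0 - 0.85 * hp
  top0 <- sign(raw) * floor(abs(raw) + 0.5)
  top0 <- min(max(top0, 0), max(nrow(image) - 128, 0))
  l_raw <- ncol(image) / 2 - 64
  left0 <- sign(l_raw) * floor(abs(l_raw) + 0.5)
  left0 <- min(max(left0, 0), max(ncol(image) - 128, 0))
  list(top = as.integer(top0 + 1), left = as.integer(left0 + 1))
}

# Noiseless phantom helper used across test files.
quiet_config <- function(...) {
  phantom_config(noise_model = "none", hotspot_rate = 0, ...)
}
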