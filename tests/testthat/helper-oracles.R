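# Independent brute-force oracles and small fixture builders.

# per-pixel loop over the mask; deliberately naive
brute_roi_stats <- function(values, mask) {
  v <- c()
  for (i in seq_len(nrow(values)))
    for (j in seq_len(ncol(values)))
      if (mask[i, j]) v <- c(v, values[i, j])
  m <- sum(v) / length(v)
  s2 <- sum((v - m)^2) / (length(v) - 1)
  list(mean = m, sd = sqrt(s2), n = length(v))
}

# Mann-Whitney via pairwise comparison counting and enumeration over value
# assignments (independent of the rank-sum route in the package)
brute_mw_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

brute_mw_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  mu <- nx * length(y) / 2
  obs <- abs(brute_mw_u(x, y) - mu)
  sets <- utils::combn(length(pool), nx)
  hits <- 0
  for (k in seq_len(ncol(sets))) {
    xs <- pool[sets[, k]]
    ys <- pool[-sets[, k]]
    if (abs(brute_mw_u(xs, ys) - mu) >= obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(sets)
}

# small (fast) phantom configuration used by most unit tests
small_config <- function(...) {
  phantom_config(matrix = 256L, ...)
}

# localization-only pipeline (noiseless slices have no defined CNR)
locate_object <- function(image, cfg = search_config()) {
  cen <- phantom_centroid(segment_phantom(image), image)
  locate_low_contrast_object(angular_profile(image, cen, cfg))
}

# lightweight cnr_result stand-in for report-layer tests
fake_result <- function(contrast, noise) {
  structure(list(contrast_hu = contrast, noise_hu = noise,
                 cnr = contrast / noise,
                 object_stats = NULL, background_stats = NULL),
            class = "cnr_result")
}
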