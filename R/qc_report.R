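#' Summarize per-slice CNR results as a measurement series
#'
#' Means and sample standard deviations (n-1) of contrast, noise and CNR
#' across slices. CNR is averaged per slice, never computed as a ratio of
#' averaged contrast to averaged noise. A single-slice series reports SDs of
#' 0 and is flagged (`n1 = TRUE`).
#'
#' @param results List of `cnr_result` objects (e.g. from [auto_cnr()] over a
#'   stack), or a data frame with columns `contrast_hu`, `noise_hu`, `cnr`.
#' @param label Series label, e.g. `"120 kV"`.
#' @return Object of class `cnr_series`.
#' @export
summarize_cnr <- function(results, label = "") {
  if (is.data.frame(results)) {
    per_slice <- results[, c("contrast_hu", "noise_hu", "cnr")]
  } else {
    if (length(results) == 0L) stop("empty result list")
    if (!all(vapply(results, inherits, logical(1), "cnr_result")))
      stop("`results` must be a list of cnr_result objects")
    per_slice <- data.frame(
      contrast_hu = vapply(results, `[[`, numeric(1), "contrast_hu"),
      noise_hu = vapply(results, `[[`, numeric(1), "noise_hu"),
      cnr = vapply(results, `[[`, numeric(1), "cnr"))
  }
  n <- nrow(per_slice)
  if (n == 0L) stop("empty result list")
  sd0 <- function(v) if (n > 1L) stats::sd(v) else 0
  structure(list(
    label = label, per_slice = per_slice, n = n, n1 = n == 1L,
    mean_contrast = mean(per_slice$contrast_hu), sd_contrast = sd0(per_slice$contrast_hu),
    mean_noise = mean(per_slice$noise_hu), sd_noise = sd0(per_slice$noise_hu),
    mean_cnr = mean(per_slice$cnr), sd_cnr = sd0(per_slice$cnr)),
    class = "cnr_series")
}

#' @export
print.cnr_series <- function(x, ...) {
  cat(sprintf("<cnr_series> %s (n = %d%s)\n",
              if (nzchar(x$label)) x$label else "unlabelled", x$n,
              if (x$n1) ", single slice" else ""))
  cat(sprintf("  contrast %.1f ± %.1f HU, noise %.1f ± %.1f HU, CNR %.1f ± %.1f\n",
              x$mean_contrast, x$sd_contrast, x$mean_noise, x$sd_noise,
              x$mean_cnr, x$sd_cnr))
  invisible(x)
}

#' @export
summary.cnr_series <- function(object, ...) {
  print(object)
  cat(sprintf("  per-slice CNR range: [%.2f, %.2f]\n",
              min(object$per_slice$cnr), max(object$per_slice$cnr)))
  invisible(object)
}

#' Percent difference between two measurement series
#'
#' `|mean_a - mean_b| / mean_b * 100`, with `b` the reference (conventionally
#' the manual measurement).
#'
#' @param a,b `cnr_series` objects; `b` is the reference.
#' @param field One of `"cnr"`, `"contrast"`, `"noise"`.
#' @return Percent difference (numeric scalar).
#' @export
percent_difference <- function(a, b, field = c("cnr", "contrast", "noise")) {
  field <- match.arg(field)
  stopifnot(inherits(a, "cnr_series"), inherits(b, "cnr_series"))
  ma <- a[[paste0("mean_", field)]]
  mb <- b[[paste0("mean_", field)]]
  if (mb == 0) stop("undefined percent difference: reference mean is zero")
  abs(ma - mb) / mb * 100
}

#' Mann-Whitney U test (rank sum, exact or tie-corrected normal)
#'
#' U is computed from rank sums with midranks assigned to ties. For combined
#' sample sizes of at most 12 the two-sided p-value is exact, by full
#' enumeration of the `choose(n_x + n_y, n_x)` label assignments of the
#' observed (mid)ranks; for larger samples a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @param exact_limit Combined size at or below which the exact enumeration
#'   path is used.
#' @return List with `u_statistic` (U for sample `x`), `p_value` (two-sided),
#'   and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (n <= exact_limit) {
    sets <- utils::combn(n, nx)
    rsums <- colSums(matrix(r[sets], nrow = nx))
    u_perm <- rsums - nx * (nx + 1) / 2
    p <- mean(abs(u_perm - mu) >= abs(u - mu) - 1e-9)
    method <- "exact (full enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- mu / 6 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(u_statistic = u, p_value = p, method = method)
}

#' ACR tolerance check on a measurement series
#'
#' The accreditation criterion for the low-contrast module: mean CNR must be
#' at least 1.0 (boundary inclusive).
#'
#' @param series A `cnr_series`.
#' @return Object of class `acr_check` with elements `pass`, `mean_cnr`,
#'   `tolerance`.
#' @export
acr_tolerance_check <- function(series) {
  stopifnot(inherits(series, "cnr_series"))
  structure(list(pass = series$mean_cnr >= 1.0, mean_cnr = series$mean_cnr,
                 tolerance = 1.0),
            class = "acr_check")
}

#' @export
print.acr_check <- function(x, ...) {
  cat(sprintf("ACR low-contrast CNR check: mean CNR %.2f vs tolerance %.1f -> %s\n",
              x$mean_cnr, x$tolerance, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Compare two measurement series (e.g. automatic vs manual)
#'
#' Percent difference of the series means (second series as reference) and a
#' Mann-Whitney U test on the per-slice values, at a significance level of
#' 0.05. The percent-difference definition is printed in every report.
#'
#' @param a,b `cnr_series`; `b` is the reference (manual) series.
#' @param field One of `"cnr"`, `"contrast"`, `"noise"`.
#' @param alpha Significance level.
#' @return Object of class `cnr_comparison`.
#' @export
compare_series <- function(a, b, field = c("cnr", "contrast", "noise"),
                           alpha = 0.05) {
  field <- match.arg(field)
  col <- if (field == "cnr") "cnr" else paste0(field, "_hu")
  mw <- mann_whitney_u(a$per_slice[[col]], b$per_slice[[col]])
  structure(list(
    series_a = a, series_b = b, field = field,
    percent_difference = percent_difference(a, b, field),
    u_statistic = mw$u_statistic, p_value = mw$p_value, method = mw$method,
    alpha = alpha, significant = mw$p_value < alpha),
    class = "cnr_comparison")
}

#' @export
print.cnr_comparison <- function(x, ...) {
  cat(sprintf("<cnr_comparison> %s: '%s' vs reference '%s'\n", x$field,
              x$series_a$label, x$series_b$label))
  cat("  percent difference = |mean(a) - mean(ref)| / mean(ref) x 100\n")
  cat(sprintf("  means %.3f vs %.3f -> %.1f%%\n",
              x$series_a[[paste0("mean_", x$field)]],
              x$series_b[[paste0("mean_", x$field)]], x$percent_difference))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.4g (%s): %s at alpha = %.2f\n",
              x$u_statistic, x$p_value, x$method,
              if (x$significant) "significantly different"
              else "not significantly different", x$alpha))
  invisible(x)
}

#' Write a measurement series as CSV
#'
#' Per-slice rows followed by mean and SD summary rows; values at full double
#' precision. Comment lines (prefixed `#`) carry the label and the
#' percent-difference convention used by comparison reports.
#'
#' @param series A `cnr_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnr_csv <- function(series, path) {
  stopifnot(inherits(series, "cnr_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cnr_series label=%s n=%d", series$label, series$n),
               "# percent difference convention: |auto - manual| / manual x 100",
               "row,slice,contrast_hu,noise_hu,cnr"), con)
  fm <- function(v) sprintf("%.17g", v)
  for (k in seq_len(series$n))
    writeLines(sprintf("slice,%d,%s,%s,%s", k,
                       fm(series$per_slice$contrast_hu[k]),
                       fm(series$per_slice$noise_hu[k]),
                       fm(series$per_slice$cnr[k])), con)
  writeLines(sprintf("mean,,%s,%s,%s", fm(series$mean_contrast),
                     fm(series$mean_noise), fm(series$mean_cnr)), con)
  writeLines(sprintf("sd,,%s,%s,%s", fm(series$sd_contrast),
                     fm(series$sd_noise), fm(series$sd_cnr)), con)
  invisible(path)
}

#' Read a measurement series written by [write_cnr_csv()]
#'
#' Summary statistics are recomputed from the per-slice rows.
#'
#' @param path CSV path.
#' @return A `cnr_series`.
#' @export
read_cnr_csv <- function(path) {
  lines <- readLines(path)
  label <- sub("^# cnr_series label=(.*) n=\\d+$", "\\1",
               lines[startsWith(lines, "# cnr_series")][1])
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  slices <- df[df$row == "slice", c("contrast_hu", "noise_hu", "cnr")]
  summarize_cnr(slices, label = label)
}
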