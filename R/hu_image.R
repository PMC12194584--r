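#' Calibrated Hounsfield-unit image
#'
#' Wraps a 2D grid of CT numbers (HU) together with its physical pixel
#' spacing. All geometry in the package (the 55 mm radial search, ROI
#' diameters) is computed in millimetres from this spacing, so changes of
#' reconstruction field of view are handled transparently.
#'
#' Coordinate convention: positions are `(x, y)` in mm with the origin at the
#' centre of the top-left pixel, `x` increasing with columns (rightward on the
#' displayed image) and `y` increasing with rows (downward). The physical
#' width of the image is `cols * col_spacing` mm.
#'
#' @param values Numeric matrix of CT numbers in HU (air is about -1000).
#' @param spacing_mm Numeric pair `(row_spacing, col_spacing)` in mm/pixel;
#'   a single number is recycled to both.
#'
#' @return An object of class `hu_image`: a list with elements `values`,
#'   `spacing_mm`, `rows`, `cols`.
#'
#' @examples
#' img <- hu_image(matrix(0, 256, 256), spacing_mm = 1)
#' img
#' @export
hu_image <- function(values, spacing_mm) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix of HU", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite (HU scale)", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be two positive numbers (row, col) in mm/pixel",
         call. = FALSE)
  if (nrow(values) < 64L || ncol(values) < 64L)
    stop("image must be at least 64 x 64 pixels", call. = FALSE)
  structure(
    list(values = values, spacing_mm = spacing_mm,
         rows = nrow(values), cols = ncol(values)),
    class = "hu_image")
}

#' @export
print.hu_image <- function(x, ...) {
  cat(sprintf("<hu_image> %d x %d pixels, spacing %.4g x %.4g mm (%.1f x %.1f mm)\n",
              x$rows, x$cols, x$spacing_mm[1], x$spacing_mm[2],
              x$rows * x$spacing_mm[1], x$cols * x$spacing_mm[2]))
  cat(sprintf("  HU range: [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
#' @importFrom graphics image
plot.hu_image <- function(x, window = c(-1100, 200), ...) {
  v <- pmin(pmax(t(x$values[x$rows:1, , drop = FALSE]), window[1]), window[2])
  xs <- (seq_len(x$cols) - 1) * x$spacing_mm[2]
  ys <- (seq_len(x$rows) - 1) * x$spacing_mm[1]
  graphics::image(xs, ys, v, col = grDevices::gray.colors(256),
                  asp = 1, xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}

is_hu_image <- function(x) inherits(x, "hu_image")

# physical (x, y) of the image centre in mm
image_center_mm <- function(image) {
  c(x = (image$cols - 1) / 2 * image$spacing_mm[2],
    y = (image$rows - 1) / 2 * image$spacing_mm[1])
}
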