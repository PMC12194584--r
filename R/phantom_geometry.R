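#' Segment the phantom body from air
#'
#' Thresholds the HU image, keeps the largest connected component and fills
#' internal holes, yielding the phantom-body footprint. The default threshold
#' of -300 HU sits midway between air (about -1000 HU) and the water-equivalent
#' body, and is robust to the noise levels produced by any reconstruction
#' kernel. Largest-component selection discards table/couch fragments at the
#' image edges; hole filling makes the mask insensitive to hypodense inserts.
#'
#' @param image An [hu_image].
#' @param threshold_hu Foreground threshold in HU (default -300).
#' @return An object of class `phantom_mask`: list with `mask` (logical matrix
#'   congruent with the image) and `pixel_count`.
#' @export
segment_phantom <- function(image, threshold_hu = -300) {
  stopifnot(is_hu_image(image))
  fg <- image$values > threshold_hu
  if (!any(fg))
    stop("no phantom found: no pixels above ", threshold_hu, " HU")
  lab <- EBImage::bwlabel(matrix(as.numeric(fg), nrow = image$rows))
  counts <- tabulate(as.integer(lab[lab > 0]))
  biggest <- which.max(counts)
  mask <- matrix(FALSE, image$rows, image$cols)
  mask[lab == biggest] <- TRUE
  filled <- EBImage::fillHull(matrix(as.numeric(mask), nrow = image$rows)) > 0
  structure(list(mask = filled, pixel_count = sum(filled)),
            class = "phantom_mask")
}

#' @export
print.phantom_mask <- function(x, ...) {
  cat(sprintf("<phantom_mask> %d x %d, %d foreground pixels\n",
              nrow(x$mask), ncol(x$mask), x$pixel_count))
  invisible(x)
}

#' Centroid and equivalent diameter of the phantom body
#'
#' The unweighted (binary) centroid of the mask in physical coordinates: the
#' anchor from which the 55 mm radial search for the low-contrast object is
#' measured. A binary rather than intensity-weighted centroid is used so the
#' low-contrast insert (a few HU) cannot bias the estimate. The equivalent
#' diameter is that of a circle with the mask's area; for a valid ACR phantom
#' body slice it should be close to the nominal 200 mm, and a value outside
#' [150, 250] mm raises a warning flag (wrong module or object) while the
#' measurement proceeds.
#'
#' @param mask A `phantom_mask` from [segment_phantom()].
#' @param image The [hu_image] the mask was computed from (for spacing).
#' @return Object of class `centroid_estimate`: list with `center_mm`
#'   (named `(x, y)` in mm), `equivalent_diameter_mm`, `suspect` (logical flag).
#' @export
phantom_centroid <- function(mask, image) {
  stopifnot(inherits(mask, "phantom_mask"), is_hu_image(image))
  if (mask$pixel_count == 0L) stop("empty phantom mask")
  idx <- which(mask$mask, arr.ind = TRUE)
  center <- c(x = (mean(idx[, "col"]) - 1) * image$spacing_mm[2],
              y = (mean(idx[, "row"]) - 1) * image$spacing_mm[1])
  area_mm2 <- mask$pixel_count * prod(image$spacing_mm)
  eqd <- 2 * sqrt(area_mm2 / pi)
  suspect <- eqd < 150 || eqd > 250
  if (suspect)
    warning(sprintf(paste0("equivalent diameter %.1f mm outside [150, 250] mm:",
                           " possibly not an ACR phantom body slice"), eqd))
  structure(list(center_mm = center, equivalent_diameter_mm = eqd,
                 suspect = suspect),
            class = "centroid_estimate")
}

#' @export
print.centroid_estimate <- function(x, ...) {
  cat(sprintf("<centroid_estimate> center (%.2f, %.2f) mm, equivalent diameter %.1f mm%s\n",
              x$center_mm[1], x$center_mm[2], x$equivalent_diameter_mm,
              if (x$suspect) " [SUSPECT]" else ""))
  invisible(x)
}
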