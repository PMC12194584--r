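#' Search configuration for the rotating-ROI CNR measurement
#'
#' Geometry of the statistical localization: a circular ROI of
#' `roi_diameter_mm` is centred `radius_mm` from the phantom centroid and
#' stepped through a full rotation in `step_deg` increments; the background
#' ROI of `background_roi_diameter_mm` sits at the centroid itself. Defaults
#' match the ACR low-contrast module: the 25 mm reference cylinder lies at a
#' radial distance of 55 mm, and 2-degree clockwise steps give a 180-point
#' angular profile.
#'
#' Angle convention: 0 degrees points to 12 o'clock of the displayed image and
#' angles increase clockwise, so an ROI centre is
#' `centroid + radius * (sin(theta), -cos(theta))` in `(x, y)` display
#' coordinates with y downward.
#'
#' @param radius_mm Radial distance of the rotating ROI centres (mm).
#' @param roi_diameter_mm Diameter of the rotating/object ROI (mm).
#' @param step_deg Angular step (degrees); must divide 360.
#' @param background_roi_diameter_mm Diameter of the central background ROI (mm).
#' @return Object of class `search_config`.
#' @export
search_config <- function(radius_mm = 55, roi_diameter_mm = 25, step_deg = 2,
                          background_roi_diameter_mm = 25) {
  if (radius_mm <= 0 || roi_diameter_mm <= 0 || background_roi_diameter_mm <= 0)
    stop("all lengths must be positive")
  if (step_deg <= 0 || 360 %% step_deg != 0)
    stop("`step_deg` must be a positive divisor of 360")
  structure(list(radius_mm = radius_mm, roi_diameter_mm = roi_diameter_mm,
                 step_deg = step_deg,
                 background_roi_diameter_mm = background_roi_diameter_mm),
            class = "search_config")
}

# ROI centre for clockwise angle theta (degrees) from 12 o'clock, y downward
.roi_center_at <- function(center, radius_mm, angle_deg) {
  th <- angle_deg * pi / 180
  c(x = unname(center[1]) + radius_mm * sin(th),
    y = unname(center[2]) - radius_mm * cos(th))
}

.check_circle_inside <- function(image, center_mm, diameter_mm, what = "ROI") {
  r <- diameter_mm / 2
  xmax <- (image$cols - 1) * image$spacing_mm[2]
  ymax <- (image$rows - 1) * image$spacing_mm[1]
  if (center_mm[1] - r < 0 || center_mm[1] + r > xmax ||
      center_mm[2] - r < 0 || center_mm[2] + r > ymax)
    stop(sprintf("geometry error: %s circle (center %.1f, %.1f mm, diameter %.1f mm) exceeds image bounds",
                 what, center_mm[1], center_mm[2], diameter_mm))
  invisible(TRUE)
}

#' Binary mask of a circular ROI
#'
#' A pixel belongs to the ROI iff its centre lies within `diameter_mm / 2` of
#' `center_mm` (Euclidean distance in mm). Purely geometric: the image supplies
#' only dimensions and spacing.
#'
#' @param image An [hu_image].
#' @param center_mm Circle centre `(x, y)` in mm.
#' @param diameter_mm Circle diameter in mm; must lie fully inside the image.
#' @return Logical matrix congruent with the image.
#' @export
circular_roi_mask <- function(image, center_mm, diameter_mm) {
  stopifnot(is_hu_image(image))
  .check_circle_inside(image, center_mm, diameter_mm)
  r <- diameter_mm / 2
  xs <- (seq_len(image$cols) - 1) * image$spacing_mm[2]
  ys <- (seq_len(image$rows) - 1) * image$spacing_mm[1]
  outer((ys - center_mm[2])^2, (xs - center_mm[1])^2, "+") <= r^2
}

# HU values inside a circular ROI, via the circle's bounding box (fast path
# for the 180-position rotating search)
.roi_values <- function(image, center_mm, diameter_mm, what = "ROI") {
  .check_circle_inside(image, center_mm, diameter_mm, what)
  r <- diameter_mm / 2
  sy <- image$spacing_mm[1]; sx <- image$spacing_mm[2]
  i0 <- max(1L, ceiling((center_mm[2] - r) / sy) + 1L)
  i1 <- min(image$rows, floor((center_mm[2] + r) / sy) + 1L)
  j0 <- max(1L, ceiling((center_mm[1] - r) / sx) + 1L)
  j1 <- min(image$cols, floor((center_mm[1] + r) / sx) + 1L)
  ys <- (seq(i0, i1) - 1) * sy
  xs <- (seq(j0, j1) - 1) * sx
  inside <- outer((ys - center_mm[2])^2, (xs - center_mm[1])^2, "+") <= r^2
  image$values[i0:i1, j0:j1][inside]
}

#' Mean and standard deviation of CT numbers in an ROI
#'
#' @param image An [hu_image].
#' @param mask Logical matrix congruent with the image (e.g. from
#'   [circular_roi_mask()]).
#' @return Object of class `roi_stats`: `mean_hu`, `sd_hu` (sample SD, n-1
#'   denominator), `n_pixels`.
#' @export
roi_stats <- function(image, mask) {
  stopifnot(is_hu_image(image))
  if (!is.logical(mask) || !identical(dim(mask), dim(image$values)))
    stop("`mask` must be a logical matrix congruent with the image")
  v <- image$values[mask]
  .stats_from_values(v)
}

.stats_from_values <- function(v) {
  if (length(v) < 2L)
    stop("statistics error: ROI selects fewer than 2 pixels")
  structure(list(mean_hu = mean(v), sd_hu = stats::sd(v),
                 n_pixels = length(v)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> mean %.2f HU, SD %.2f HU, n = %d px\n",
              x$mean_hu, x$sd_hu, x$n_pixels))
  invisible(x)
}

#' Angular CT-number profile of the rotating ROI
#'
#' Steps a circular ROI clockwise around the phantom centroid at
#' `cfg$radius_mm` and records the mean CT number at each angle over one full
#' rotation. The resulting profile peaks where the ROI covers the largest
#' low-contrast object.
#'
#' @param image An [hu_image].
#' @param phantom_center Centroid `(x, y)` in mm (see [phantom_centroid()]).
#' @param cfg A [search_config()].
#' @return Object of class `angular_profile`: `angles_deg`, `mean_hu`,
#'   `argmax_deg`, plus the generating geometry.
#' @export
angular_profile <- function(image, phantom_center, cfg = search_config()) {
  stopifnot(is_hu_image(image), inherits(cfg, "search_config"))
  if (inherits(phantom_center, "centroid_estimate"))
    phantom_center <- phantom_center$center_mm
  angles <- seq(0, 360 - cfg$step_deg, by = cfg$step_deg)
  means <- vapply(angles, function(a) {
    ctr <- .roi_center_at(phantom_center, cfg$radius_mm, a)
    v <- tryCatch(.roi_values(image, ctr, cfg$roi_diameter_mm),
                  error = function(e)
                    stop(sprintf("at angle %g deg: %s", a, conditionMessage(e)),
                         call. = FALSE))
    mean(v)
  }, numeric(1))
  structure(list(angles_deg = angles, mean_hu = means,
                 argmax_deg = angles[which.max(means)],
                 phantom_center = phantom_center, cfg = cfg),
            class = "angular_profile")
}

#' @export
print.angular_profile <- function(x, ...) {
  cat(sprintf("<angular_profile> %d angles (step %g deg), max %.2f HU at %g deg\n",
              length(x$angles_deg), x$cfg$step_deg, max(x$mean_hu), x$argmax_deg))
  invisible(x)
}

#' @export
#' @importFrom graphics plot abline
plot.angular_profile <- function(x, ...) {
  graphics::plot(x$angles_deg, x$mean_hu, type = "l",
                 xlab = "ROI angle (deg, clockwise from 12 o'clock)",
                 ylab = "mean CT number (HU)", ...)
  graphics::abline(v = x$argmax_deg, lty = 2)
  invisible(x)
}

#' Locate the largest low-contrast object from an angular profile
#'
#' The object is taken at the angle of maximum mean CT number (first
#' occurrence on exact ties); its centre is the rotating-ROI centre at that
#' angle, i.e. exactly `cfg$radius_mm` from the phantom centroid.
#'
#' @param profile An [angular_profile()].
#' @param phantom_center Centroid `(x, y)` in mm; defaults to the centre the
#'   profile was built around.
#' @param cfg A [search_config()]; defaults to the profile's.
#' @return Object of class `object_location`: `center_mm`, `angle_deg`.
#' @export
locate_low_contrast_object <- function(profile, phantom_center = NULL,
                                       cfg = NULL) {
  stopifnot(inherits(profile, "angular_profile"))
  if (is.null(phantom_center)) phantom_center <- profile$phantom_center
  if (inherits(phantom_center, "centroid_estimate"))
    phantom_center <- phantom_center$center_mm
  if (is.null(cfg)) cfg <- profile$cfg
  if (length(profile$mean_hu) == 0L) stop("empty angular profile")
  k <- which.max(profile$mean_hu)
  angle <- profile$angles_deg[k]
  structure(list(center_mm = .roi_center_at(phantom_center, cfg$radius_mm, angle),
                 angle_deg = angle),
            class = "object_location")
}

#' @export
print.object_location <- function(x, ...) {
  cat(sprintf("<object_location> angle %g deg, center (%.2f, %.2f) mm\n",
              x$angle_deg, x$center_mm[1], x$center_mm[2]))
  invisible(x)
}

#' Contrast-to-noise ratio from an object and a background ROI
#'
#' CNR = (mean object CT number - mean background CT number) / background SD.
#' Contrast is signed (the ACR module-2 reference object is hyperdense, so
#' values are positive in practice); noise is the sample standard deviation of
#' the background ROI.
#'
#' @param image An [hu_image].
#' @param object_center ROI centre on the low-contrast object, `(x, y)` mm
#'   (or an `object_location`).
#' @param background_center Background ROI centre `(x, y)` mm, normally the
#'   phantom centroid.
#' @param cfg A [search_config()] supplying both ROI diameters.
#' @return Object of class `cnr_result`: `contrast_hu`, `noise_hu`, `cnr`,
#'   `object_stats`, `background_stats`.
#' @export
measure_cnr <- function(image, object_center, background_center,
                        cfg = search_config()) {
  stopifnot(is_hu_image(image), inherits(cfg, "search_config"))
  if (inherits(object_center, "object_location"))
    object_center <- object_center$center_mm
  if (inherits(background_center, "centroid_estimate"))
    background_center <- background_center$center_mm
  obj <- .stats_from_values(
    .roi_values(image, object_center, cfg$roi_diameter_mm, "object ROI"))
  bg <- .stats_from_values(
    .roi_values(image, background_center, cfg$background_roi_diameter_mm,
                "background ROI"))
  if (bg$sd_hu == 0)
    stop("degenerate input: background SD is zero (noiseless image; CNR undefined)")
  contrast <- obj$mean_hu - bg$mean_hu
  structure(list(contrast_hu = contrast, noise_hu = bg$sd_hu,
                 cnr = contrast / bg$sd_hu,
                 object_stats = obj, background_stats = bg, cfg = cfg),
            class = "cnr_result")
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("<cnr_result> contrast %.1f HU, noise %.1f HU, CNR %.1f\n",
              x$contrast_hu, x$noise_hu, x$cnr))
  if (!is.null(x$location))
    cat(sprintf("  object at %g deg, (%.2f, %.2f) mm; phantom centroid (%.2f, %.2f) mm\n",
                x$location$angle_deg, x$location$center_mm[1],
                x$location$center_mm[2],
                x$centroid$center_mm[1], x$centroid$center_mm[2]))
  invisible(x)
}

#' @export
#' @importFrom graphics symbols points
plot.cnr_result <- function(x, image = NULL, ...) {
  if (!is.null(x$profile)) {
    plot(x$profile, main = sprintf("CNR %.2f", x$cnr), ...)
  } else {
    stop("nothing to plot: result carries no angular profile")
  }
  invisible(x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Fully automatic CNR measurement on one phantom slice
#'
#' End-to-end statistical measurement: segment the phantom body, take its
#' binary centroid, build the rotating-ROI angular profile at
#' `cfg$radius_mm`, place the object ROI at the profile maximum and the
#' background ROI at the centroid, and evaluate the CNR. Robust to phantom
#' misalignment because the search is anchored on the measured centroid, not
#' the image centre.
#'
#' Errors from individual stages are tagged with the stage name, e.g.
#' `[segment_phantom] no phantom found ...`.
#'
#' @param image An [hu_image].
#' @param cfg A [search_config()].
#' @param threshold_hu Body segmentation threshold in HU.
#' @return A `cnr_result` additionally carrying `location`
#'   (`object_location`), `centroid` (`centroid_estimate`) and `profile`
#'   (`angular_profile`).
#'
#' @examples
#' slc <- generate_slice(phantom_config(noise_sd_hu = 3, matrix = 256L), 1L)
#' auto_cnr(slc$image)
#' @export
auto_cnr <- function(image, cfg = search_config(), threshold_hu = -300) {
  stopifnot(is_hu_image(image))
  mask <- .stage("segment_phantom", segment_phantom(image, threshold_hu))
  centroid <- .stage("phantom_centroid", phantom_centroid(mask, image))
  profile <- .stage("angular_profile",
                    angular_profile(image, centroid$center_mm, cfg))
  loc <- .stage("locate_low_contrast_object",
                locate_low_contrast_object(profile, centroid$center_mm, cfg))
  res <- .stage("measure_cnr",
                measure_cnr(image, loc$center_mm, centroid$center_mm, cfg))
  res$location <- loc
  res$centroid <- centroid
  res$profile <- profile
  res
}
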