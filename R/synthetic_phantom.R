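#' Configuration for a synthetic ACR low-contrast-module slice
#'
#' Parameterizes a simulated slice of the ACR CT phantom's low-contrast
#' module: a circular water-equivalent body in air, one hyperdense
#' low-contrast disc (the 25 mm reference cylinder) at a known radial
#' distance and angle, additive Gaussian noise on the body, and an optional
#' phantom misalignment. Defaults reflect the nominal module geometry: a
#' 200 mm body at about 90 HU, the 25 mm object at 55 mm radius with ~6 HU
#' contrast, reconstructed at a 235 mm field of view on a 512 matrix.
#'
#' The generator emulates what a mean/SD-based measurement sees; it does not
#' model reconstruction physics (noise is white, not kernel-correlated, and
#' there is no beam hardening). Sharp-kernel acquisitions are emulated purely
#' by raising `noise_sd_hu`.
#'
#' @param fov_mm Reconstruction field of view (mm); with `matrix` this fixes
#'   the pixel spacing `fov_mm / matrix`.
#' @param matrix Pixels per image side.
#' @param body_diameter_mm Phantom body diameter (mm).
#' @param background_hu CT number of the body.
#' @param air_hu CT number outside the body.
#' @param contrast_hu Object CT number minus background.
#' @param object_angle_deg Ground-truth object angle (degrees clockwise from
#'   12 o'clock).
#' @param object_radius_mm Radial distance of the object centre from the
#'   phantom centre (mm).
#' @param object_diameter_mm Object diameter (mm).
#' @param noise_sd_hu SD of additive Gaussian noise on body pixels (HU).
#' @param offset_mm Phantom centre offset `(dx, dy)` from the image centre (mm).
#' @param n_slices Number of slices in a stack.
#' @param seed Stack-level random seed.
#' @param small_cylinders Draw the smaller (2-6 mm) cylinder series for visual
#'   realism; they are never measurement targets.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(fov_mm = 235, matrix = 512L, body_diameter_mm = 200,
                           background_hu = 90, air_hu = -1000, contrast_hu = 6,
                           object_angle_deg = 30, object_radius_mm = 55,
                           object_diameter_mm = 25, noise_sd_hu = 3,
                           offset_mm = c(0, 0), n_slices = 1L, seed = 1L,
                           small_cylinders = FALSE) {
  if (object_radius_mm + object_diameter_mm / 2 >= body_diameter_mm / 2)
    stop("config error: object not fully inside the phantom body")
  if (fov_mm < body_diameter_mm + 2 * max(abs(offset_mm)))
    stop("config error: field of view too small for body plus offset")
  if (noise_sd_hu < 0) stop("config error: noise_sd_hu must be >= 0")
  if (matrix < 64L) stop("config error: matrix must be >= 64")
  if (n_slices < 1L) stop("config error: n_slices must be >= 1")
  structure(list(fov_mm = fov_mm, matrix = as.integer(matrix),
                 body_diameter_mm = body_diameter_mm,
                 background_hu = background_hu, air_hu = air_hu,
                 contrast_hu = contrast_hu,
                 object_angle_deg = object_angle_deg %% 360,
                 object_radius_mm = object_radius_mm,
                 object_diameter_mm = object_diameter_mm,
                 noise_sd_hu = noise_sd_hu, offset_mm = offset_mm,
                 n_slices = as.integer(n_slices), seed = as.integer(seed),
                 small_cylinders = small_cylinders),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(paste0("<phantom_config> %d px, FOV %g mm, body %g mm @ %g HU, ",
                     "object %g mm @ %g deg (+%g HU), noise SD %g HU, ",
                     "offset (%g, %g) mm, %d slice(s), seed %d\n"),
              x$matrix, x$fov_mm, x$body_diameter_mm, x$background_hu,
              x$object_diameter_mm, x$object_angle_deg, x$contrast_hu,
              x$noise_sd_hu, x$offset_mm[1], x$offset_mm[2], x$n_slices,
              x$seed))
  invisible(x)
}

# area-fraction coverage of a disc on the pixel grid; pixels within half a
# pixel diagonal of the rim are supersampled 4 x 4 to avoid rasterization bias
.disc_coverage <- function(xs, ys, center, radius, s) {
  d <- sqrt(outer((ys - center[2])^2, (xs - center[1])^2, "+"))
  h <- sqrt(2) / 2 * s
  cov <- matrix(0, length(ys), length(xs))
  cov[d <= radius - h] <- 1
  band <- which(d > radius - h & d < radius + h)
  if (length(band) > 0L) {
    bi <- ((band - 1L) %% length(ys)) + 1L
    bj <- ((band - 1L) %/% length(ys)) + 1L
    px <- xs[bj]; py <- ys[bi]
    off <- (seq_len(4L) - 2.5) / 4 * s
    acc <- numeric(length(band))
    for (ox in off) for (oy in off)
      acc <- acc + ((px + ox - center[1])^2 + (py + oy - center[2])^2 <= radius^2)
    cov[band] <- acc / 16
  }
  cov
}

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483647)
}

#' Generate one synthetic phantom slice with ground truth
#'
#' Deterministic given `(cfg, slice_seed)`: pixels are `air_hu` outside the
#' body disc, `background_hu` inside, `background_hu + contrast_hu` inside the
#' object disc, with disc edges antialiased by area fraction; independent
#' Gaussian noise of SD `noise_sd_hu` is then added to body pixels. The
#' caller's RNG state is left untouched.
#'
#' @param cfg A [phantom_config()].
#' @param slice_seed Integer seed for this slice's noise field.
#' @return List with `image` (an [hu_image]) and `truth` (list:
#'   `object_center_mm`, `phantom_center_mm`, `object_angle_deg`,
#'   `true_contrast_hu`, `true_noise_sd_hu`).
#' @export
generate_slice <- function(cfg, slice_seed = cfg$seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(slice_seed))

  s <- cfg$fov_mm / cfg$matrix
  xs <- (seq_len(cfg$matrix) - 1) * s
  ys <- xs
  img_center <- c((cfg$matrix - 1) / 2 * s, (cfg$matrix - 1) / 2 * s)
  ph_center <- img_center + cfg$offset_mm
  obj_center <- .roi_center_at(ph_center, cfg$object_radius_mm,
                               cfg$object_angle_deg)

  cov_body <- .disc_coverage(xs, ys, ph_center, cfg$body_diameter_mm / 2, s)
  cov_obj <- .disc_coverage(xs, ys, obj_center, cfg$object_diameter_mm / 2, s)
  values <- cfg$air_hu + cov_body * (cfg$background_hu - cfg$air_hu) +
    cov_obj * cfg$contrast_hu

  if (isTRUE(cfg$small_cylinders)) {
    # decorative 2-6 mm series, spaced away from the reference object
    dia <- c(6, 5, 4, 3, 2)
    ang <- cfg$object_angle_deg + c(60, 85, 105, 120, 132)
    for (m in seq_along(dia)) {
      ctr <- .roi_center_at(ph_center, cfg$object_radius_mm, ang[m])
      values <- values + .disc_coverage(xs, ys, ctr, dia[m] / 2, s) *
        cfg$contrast_hu
    }
  }

  if (cfg$noise_sd_hu > 0) {
    body_idx <- which(cov_body > 0)
    values[body_idx] <- values[body_idx] +
      stats::rnorm(length(body_idx), 0, cfg$noise_sd_hu)
  }

  list(image = hu_image(values, spacing_mm = c(s, s)),
       truth = list(object_center_mm = obj_center,
                    phantom_center_mm = ph_center,
                    object_angle_deg = cfg$object_angle_deg,
                    true_contrast_hu = cfg$contrast_hu,
                    true_noise_sd_hu = cfg$noise_sd_hu))
}

#' Generate a stack of independent synthetic slices
#'
#' Slice `k` uses a seed derived deterministically from `(cfg$seed, k - 1)`;
#' all slices share the same noiseless structure and differ only in their
#' noise fields.
#'
#' @param cfg A [phantom_config()].
#' @return List of `n_slices` elements, each as returned by [generate_slice()].
#' @export
generate_stack <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  lapply(seq_len(cfg$n_slices) - 1L,
         function(k) generate_slice(cfg, .derive_seed(cfg$seed, k)))
}

#' Write a synthetic stack as a DICOM series
#'
#' One minimal CT DICOM file per slice (`slice_001.dcm`, ...), HU encoded via
#' rescale slope/intercept, pixel spacing `fov/matrix`, instance numbers
#' 1..n in stack order. Round-trips through [read_dicom_slice()] to within
#' +/- 0.5 HU.
#'
#' @param stack A list from [generate_stack()] (or of bare [hu_image]s).
#' @param dir Output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
write_synthetic_dicom <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  series_uid <- .new_uid(); study_uid <- .new_uid()
  paths <- character(length(stack))
  for (k in seq_along(stack)) {
    img <- if (is_hu_image(stack[[k]])) stack[[k]] else stack[[k]]$image
    paths[k] <- file.path(dir, sprintf("slice_%03d.dcm", k))
    write_dicom_slice(img, paths[k], instance_number = k,
                      series_uid = series_uid, study_uid = study_uid)
  }
  invisible(paths)
}
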