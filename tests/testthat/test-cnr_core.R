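flat <- function(hu = 90, n = 256L, spacing = 1) {
  hu_image(matrix(hu, n, n), spacing)
}

test_that("circular ROI masks are geometric and match analytic areas", {
  img <- hu_image(matrix(0, 512, 512), 0.459)
  ctr <- c(255.5, 255.5) * 0.459
  m <- circular_roi_mask(img, ctr, 25)
  expect_lt(abs(sum(m) - pi * 12.5^2 / 0.459^2) / (pi * 12.5^2 / 0.459^2), 0.02)

  # degenerate circle of one pixel pitch centred on a pixel centre
  img1 <- flat(0, 128L, 1)
  m1 <- circular_roi_mask(img1, c(64, 64), 1)
  expect_identical(sum(m1), 1L)

  # masks depend only on geometry, not on image values
  imgA <- flat(0, 128L, 1); imgB <- flat(500, 128L, 1)
  expect_identical(circular_roi_mask(imgA, c(60, 60), 20),
                   circular_roi_mask(imgB, c(60, 60), 20))

  expect_error(circular_roi_mask(img1, c(5, 5), 25), "geometry error")
})

test_that("roi_stats equals hand values and the brute-force oracle", {
  img <- flat(90, 128L)
  m <- circular_roi_mask(img, c(64, 64), 10)
  s <- roi_stats(img, m)
  expect_equal(s$mean_hu, 90)
  expect_equal(s$sd_hu, 0)

  v <- matrix(90, 128, 128); v[64, 63:65] <- c(88, 90, 92)
  img2 <- hu_image(v, 1)
  m3 <- matrix(FALSE, 128, 128); m3[64, 63:65] <- TRUE
  s3 <- roi_stats(img2, m3)
  expect_equal(s3$mean_hu, 90)
  expect_equal(s3$sd_hu, 2)

  set.seed(77)
  noisy <- hu_image(matrix(rnorm(128^2, 90, 4), 128, 128), 0.918)
  for (dia in c(25, 11.3)) {
    mm <- circular_roi_mask(noisy, c(58.7, 60.1), dia)
    got <- roi_stats(noisy, mm)
    want <- brute_roi_stats(noisy$values, mm)
    expect_identical(got$n_pixels, want$n)
    expect_equal(got$mean_hu, want$mean)
    expect_equal(got$sd_hu, want$sd)
  }

  expect_error(roi_stats(img, matrix(FALSE, 128, 128)), "statistics error")
})

test_that("angular profile is flat on a homogeneous phantom and has 360/step points", {
  slc <- generate_slice(small_config(noise_sd_hu = 0, contrast_hu = 0), 1L)
  cen <- phantom_centroid(segment_phantom(slc$image), slc$image)
  prof <- angular_profile(slc$image, cen)
  expect_length(prof$mean_hu, 180L)
  expect_lt(max(prof$mean_hu) - min(prof$mean_hu), 1e-9)

  prof5 <- angular_profile(slc$image, cen, search_config(step_deg = 5))
  expect_length(prof5$mean_hu, 72L)
  expect_error(angular_profile(slc$image, c(2, 2)), "at angle")
})

test_that("noiseless localization hits the ground-truth angle at any start", {
  for (ang in c(0, 134, 220.7, 359)) {
    slc <- generate_slice(small_config(noise_sd_hu = 0, object_angle_deg = ang), 1L)
    cen <- phantom_centroid(segment_phantom(slc$image), slc$image)
    prof <- angular_profile(slc$image, cen)
    diff <- abs((prof$argmax_deg - ang + 180) %% 360 - 180)
    expect_lte(diff, 2)
    loc <- locate_low_contrast_object(prof)
    expect_equal(sqrt(sum((loc$center_mm - cen$center_mm)^2)), 55)
  }
})

test_that("profile argmax tie-breaks to the first angle in scan order", {
  prof <- structure(list(angles_deg = seq(0, 358, by = 2),
                         mean_hu = rep(90, 180), argmax_deg = 0,
                         phantom_center = c(100, 100),
                         cfg = search_config()),
                    class = "angular_profile")
  prof$mean_hu[c(11, 91)] <- 96  # equal maxima at 20 and 180 degrees
  loc <- locate_low_contrast_object(prof)
  expect_equal(loc$angle_deg, 20)
})

test_that("measure_cnr implements contrast/noise with the arithmetic identity", {
  set.seed(12)
  v <- matrix(rnorm(256^2, 90, 3), 256, 256)
  xs <- seq_len(256) - 1; ctr <- (256 - 1) / 2
  d <- sqrt(outer((xs - ctr)^2, (xs - ctr)^2, "+"))
  v[d > 100] <- -1000
  obj_ctr <- c(ctr + 55, ctr)
  dobj <- sqrt(outer((xs - obj_ctr[2])^2, (xs - obj_ctr[1])^2, "+"))
  v[dobj <= 12.5] <- v[dobj <= 12.5] + 6
  img <- hu_image(v, 1)

  res <- measure_cnr(img, obj_ctr, c(ctr, ctr))
  expect_equal(res$cnr * res$noise_hu, res$contrast_hu)
  expect_equal(res$contrast_hu,
               res$object_stats$mean_hu - res$background_stats$mean_hu)
  expect_equal(res$cnr, 2, tolerance = 0.15)

  # zero contrast
  res0 <- measure_cnr(img, c(ctr, ctr - 55), c(ctr, ctr))
  expect_lt(abs(res0$cnr), 0.2)

  # noiseless background is a degenerate input
  expect_error(measure_cnr(flat(90), c(64, 64), c(100, 100)), "CNR undefined")
})

test_that("localization tolerates phantom misalignment", {
  slc <- generate_slice(small_config(noise_sd_hu = 0, object_angle_deg = 270,
                                     offset_mm = c(4, -3)), 1L)
  loc <- locate_object(slc$image)
  err <- sqrt(sum((loc$center_mm - slc$truth$object_center_mm)^2))
  expect_lt(err, 2)
})

test_that("auto_cnr on a stack recovers the configured contrast-to-noise ratio", {
  cfg <- small_config(noise_sd_hu = 3, contrast_hu = 6, n_slices = 10L, seed = 5L)
  cnrs <- vapply(generate_stack(cfg), function(s) auto_cnr(s$image)$cnr,
                 numeric(1))
  expect_equal(mean(cnrs), 2, tolerance = 0.1)
})

test_that("doubling the noise halves the mean CNR", {
  mean_cnr <- function(sd, seed) {
    cfg <- small_config(noise_sd_hu = sd, n_slices = 8L, seed = seed)
    mean(vapply(generate_stack(cfg), function(s) auto_cnr(s$image)$cnr,
                numeric(1)))
  }
  c3 <- mean_cnr(3, 21L)
  c6 <- mean_cnr(6, 22L)
  expect_equal(c3 / c6, 2, tolerance = 0.15)
})

test_that("auto_cnr tags stage failures and handles a null object", {
  air <- hu_image(matrix(-1000, 128, 128), 1)
  expect_error(auto_cnr(air), "\\[segment_phantom\\].*no phantom found")

  slc <- generate_slice(small_config(noise_sd_hu = 3, contrast_hu = 0), 9L)
  res <- auto_cnr(slc$image)
  expect_lt(abs(res$cnr), 3 / sqrt(res$object_stats$n_pixels) * 5)
})
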