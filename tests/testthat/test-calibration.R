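test_that("chip measurement recovers known uniform fills exactly", {
  fill <- colorchecker_srgb()
  cc <- checker_image(fill)
  m <- measure_chips(cc$image, cc$layout)
  expect_equal(nrow(m), 24)
  expect_equal(as.matrix(m[, c("mR", "mG", "mB")]), unname(fill),
               ignore_attr = TRUE)
})

test_that("the chip margin excludes border pixels", {
  img <- uniform_image(20, 20, c(10, 20, 30))
  # 1-px bright border around a 10 x 10 chip at (2, 2)
  img[3, 3:12, ] <- 255
  img[12, 3:12, ] <- 255
  img[3:12, 3, ] <- 255
  img[3:12, 12, ] <- 255
  layout <- list(list(chip_id = 1, x = 2, y = 2, w = 10, h = 10))
  m <- measure_chips(img, layout, reference = matrix(0, 1, 3),
                     margin_fraction = 0.2)
  expect_equal(unlist(m[, c("mR", "mG", "mB")]), c(mR = 10, mG = 20, mB = 30))
  # margin 0 includes the bright border
  m0 <- measure_chips(img, layout, reference = matrix(0, 1, 3),
                      margin_fraction = 0)
  expect_gt(m0$mR, 10)
  expect_error(measure_chips(img, layout, reference = matrix(0, 1, 3),
                             margin_fraction = 0.5), "margin_fraction")
})

test_that("already-calibrated chips give an identity-acting model", {
  ref <- colorchecker_srgb()
  meas <- data.frame(chip_id = 1:24, mR = ref[, 1], mG = ref[, 2],
                     mB = ref[, 3], rR = ref[, 1], rG = ref[, 2],
                     rB = ref[, 3])
  for (method in c("quadratic_cross_band", "linear")) {
    fit <- fit_calibration(meas, method)
    expect_lt(fit$mean_delta, 1e-6)
    px <- c(120.5, 30.2, 200.1)
    expect_equal(unname(apply_calibration(fit, px)), px, tolerance = 1e-6)
  }
})

test_that("a quadratic cross-band relation is recovered to < 1e-6 delta E", {
  meas_rgb <- colorchecker_srgb()
  coef <- random_quad_coef(seed = 21)
  ref_rgb <- pmin(pmax(quad_map(meas_rgb, coef), 0), 255)
  meas <- data.frame(chip_id = 1:24, mR = meas_rgb[, 1], mG = meas_rgb[, 2],
                     mB = meas_rgb[, 3], rR = ref_rgb[, 1],
                     rG = ref_rgb[, 2], rB = ref_rgb[, 3])
  fit <- fit_calibration(meas, "quadratic_cross_band")
  expect_lt(fit$mean_delta, 1e-6)
  cal <- apply_calibration(fit, meas_rgb)
  expect_lt(max(delta_e76(srgb_to_lab(cal), srgb_to_lab(ref_rgb))), 1e-6)
})

test_that("quadratic calibration is never worse than linear", {
  ref <- colorchecker_srgb()
  for (s in 1:10) {
    set.seed(100 + s)
    # smooth monotone distortion: gain + offset + tone curve
    g <- runif(3, 0.85, 1.15); o <- rnorm(3, 0, 5); gam <- runif(1, 0.9, 1.1)
    meas_rgb <- sweep(255 * (ref / 255)^gam, 2, g, "*")
    meas_rgb <- pmin(pmax(sweep(meas_rgb, 2, o, "+"), 0), 255)
    meas <- data.frame(chip_id = 1:24, mR = meas_rgb[, 1],
                       mG = meas_rgb[, 2], mB = meas_rgb[, 3],
                       rR = ref[, 1], rG = ref[, 2], rB = ref[, 3])
    dq <- fit_calibration(meas, "quadratic_cross_band")$mean_delta
    dl <- fit_calibration(meas, "linear")$mean_delta
    expect_lte(dq, dl + 1e-9)
  }
})

test_that("under-determined or degenerate designs are rejected", {
  ref <- colorchecker_srgb()
  meas <- data.frame(chip_id = 1:24, mR = ref[, 1], mG = ref[, 2],
                     mB = ref[, 3], rR = ref[, 1], rG = ref[, 2],
                     rB = ref[, 3])
  expect_error(fit_calibration(meas[1:9, ], "quadratic_cross_band"),
               "at least 10 chips")
  expect_error(fit_calibration(meas[1:3, ], "linear"), "at least 4 chips")
  flat <- meas
  flat[, c("mR", "mG", "mB")] <- 100  # all chips measured identical
  expect_error(fit_calibration(flat, "linear"), "rank-deficient")
})

test_that("calibrated values are clipped to the 8-bit range", {
  ref <- colorchecker_srgb()
  meas <- data.frame(chip_id = 1:24, mR = ref[, 1], mG = ref[, 2],
                     mB = ref[, 3], rR = ref[, 1], rG = ref[, 2],
                     rB = ref[, 3])
  fit <- fit_calibration(meas, "linear")
  fit$coefficients[1, ] <- c(500, -500, 0)  # force out-of-gamut mapping
  out <- apply_calibration(fit, c(200, 200, 200))
  expect_true(all(out >= 0 & out <= 255))
  expect_equal(unname(out[1]), 255)
  expect_equal(unname(out[2]), 0)
})

test_that("calibration survives a JSON round trip", {
  ref <- colorchecker_srgb()
  coef <- random_quad_coef(seed = 31)
  meas_rgb <- pmin(pmax(quad_map(ref, coef), 0), 255)
  meas <- data.frame(chip_id = 1:24, mR = meas_rgb[, 1], mG = meas_rgb[, 2],
                     mB = meas_rgb[, 3], rR = ref[, 1], rG = ref[, 2],
                     rB = ref[, 3])
  fit <- fit_calibration(meas, light_condition = "WF0")
  path <- tempfile(fileext = ".json")
  calibration_to_json(fit, path)
  back <- calibration_from_json(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back$mean_delta, fit$mean_delta, tolerance = 1e-12)
  expect_equal(back$light_condition, "WF0")
  px <- matrix(runif(30, 0, 255), ncol = 3)
  expect_equal(apply_calibration(back, px), apply_calibration(fit, px),
               tolerance = 1e-9)
})

test_that("cross-condition application is flagged but allowed", {
  ref <- colorchecker_srgb()
  meas <- data.frame(chip_id = 1:24, mR = ref[, 1], mG = ref[, 2],
                     mB = ref[, 3], rR = ref[, 1], rG = ref[, 2],
                     rB = ref[, 3])
  fit <- fit_calibration(meas, light_condition = "WF0")
  img <- structure(list(pixels = uniform_image(4, 4, c(10, 10, 10)),
                        light_condition = "PF0"),
                   class = "synthetic_image")
  expect_message(apply_calibration(fit, img), "WF0")
})

test_that("per-condition calibration aligns disk colours across conditions", {
  # distorted conditions, no pixel noise: after per-condition calibration
  # the same disk should measure nearly the same colour everywhere
  design <- study_design(seed = 42, cultivars = default_cultivars()[c(1, 5, 13, 14)],
                         link = default_links(), pixel_noise_sd = 0)
  study <- generate_study(design)
  labs <- list()
  for (key in names(study$images)) {
    img <- study$images[[key]]
    chips <- measure_chips(img, img$checker_layout, img$checker_reference)
    cal <- fit_calibration(chips, light_condition = img$light_condition)
    ci <- apply_calibration(cal, img$pixels)
    for (rn in names(img$roi_polygons)) {
      mask <- rasterise_polygon(img$roi_polygons[[rn]], dim(ci)[1:2])
      labs[[paste(key, rn)]] <- data.frame(
        disk = rn, t(srgb_to_lab(roi_colour(ci, mask)$mean_rgb)))
    }
  }
  labs <- do.call(rbind, labs)
  spread <- sapply(split(labs, labs$disk), function(d) {
    lab <- as.matrix(d[, c("L", "a", "b")])
    mean(delta_e76(lab, matrix(colMeans(lab), 1)))
  })
  expect_lt(median(spread), 2)
})
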