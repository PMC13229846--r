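test_that("a fixed seed reproduces the study bit for bit", {
  d <- study_design(seed = 1, cultivars = default_cultivars()[c(1, 5, 14)],
                    link = default_links())
  s1 <- generate_study(d)
  s2 <- generate_study(d)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$wetlab, s2$wetlab)
  expect_identical(s1$images[[3]]$pixels, s2$images[[3]]$pixels)
  # truth does not depend on whether images are rendered
  s3 <- generate_study(d, render_images = FALSE)
  expect_identical(s1$truth, s3$truth)
  expect_null(s3$images)
})

test_that("the default design yields 96 roots per light condition", {
  st <- generate_study(study_design(seed = 2), render_images = FALSE)
  counts <- table(st$truth$light_condition)
  expect_equal(length(counts), 6)
  expect_true(all(counts == 96))
  expect_equal(nrow(st$wetlab), 96)
  # anthocyanin assay availability mirrors the study: 6 + 3 + 6 + 1
  tac_n <- tapply(!is.na(st$wetlab$A520_pH1), st$wetlab$cultivar, sum)
  expect_equal(as.vector(tac_n[c("P1", "P2", "PY1", "R1")]), c(6, 3, 6, 1))
  expect_equal(sum(tac_n), 16)
})

test_that("light conditions satisfy their structural invariants", {
  conds <- light_conditions()
  names <- vapply(conds, `[[`, "", "name")
  key <- vapply(conds, function(cc)
    paste(cc$environment, cc$exposure_step), "")
  expect_equal(anyDuplicated(names), 0)
  expect_equal(anyDuplicated(key), 0)  # name <-> (environment, step)
  times <- vapply(conds, `[[`, 0, "exposure_time_s")
  expect_true(all(times %in% c(1 / 25, 1 / 50, 1 / 100, 1 / 60, 1 / 30)))
  glare <- vapply(conds, `[[`, 0, "glare")
  env <- vapply(conds, `[[`, "", "environment")
  expect_true(all(glare[env == "PF"] == 0))   # polarisation kills glare
  expect_true(all(glare[env == "WF"] > 0))
})

test_that("a noiseless identity study round-trips disk colour to < 0.5 dE", {
  d <- study_design(seed = 3, cultivars = default_cultivars(lab_sd = c(0, 0, 0)),
                    link = default_links(),
                    light_conditions = identity_conditions(),
                    pixel_noise_sd = 0)
  st <- generate_study(d)
  for (key in c("W1_WF0", "O2_PF0", "P1_WF+1")) {
    img <- st$images[[key]]
    chips <- measure_chips(img, img$checker_layout, img$checker_reference)
    cal <- fit_calibration(chips)
    ci <- apply_calibration(cal, img$pixels)
    tr <- st$truth[st$truth$light_condition == img$light_condition &
                     st$truth$cultivar == img$cultivar, ]
    for (rn in names(img$roi_polygons)) {
      mask <- rasterise_polygon(img$roi_polygons[[rn]], dim(ci)[1:2])
      lab <- srgb_to_lab(roi_colour(ci, mask)$mean_rgb)
      rep <- as.integer(sub(".*_r", "", rn))
      truth_lab <- unlist(tr[tr$replicate == rep,
                             c("L_star", "a_star", "b_star")])
      expect_lt(delta_e76(lab, truth_lab), 0.5)
    }
  }
})

test_that("glare strictly raises the mean disk lightness", {
  meanL <- sapply(c(0, 5, 10, 20), function(amp) {
    d <- study_design(seed = 5, cultivars = default_cultivars()[4],
                      link = default_links(),
                      light_conditions = identity_conditions(glare = amp)[2],
                      pixel_noise_sd = 0)
    st <- generate_study(d)
    img <- st$images[[1]]
    Ls <- sapply(names(img$roi_polygons), function(rn) {
      mask <- rasterise_polygon(img$roi_polygons[[rn]],
                                dim(img$pixels)[1:2])
      srgb_to_lab(roi_colour(img$pixels, mask)$mean_rgb)[1]
    })
    mean(Ls)
  })
  expect_true(all(diff(meanL) > 0))
})

test_that("pigment-equation inversion is the exact algebraic inverse", {
  assay <- study_design(seed = 1)$assay
  # chlorophyll-free micro-case: A470 = 227 * Cxc / 1000
  one <- invert_pigment_equations(
    data.frame(tcc = 2.5, tac = NA, moisture_fraction = 0.9), assay)
  cxc <- 2.5 * 10 * assay$tcc_mass_g / (assay$tcc_volume_mL * (1 - 0.9))
  expect_equal(one$A470, 227 * cxc / 1000, tolerance = 1e-12)
  expect_equal(one$A662, 0)
  expect_true(attr(one, "chlorophyll_free"))
  # zero anthocyanins: both buffers read the same difference
  z <- invert_pigment_equations(
    data.frame(tcc = 1, tac = 0, moisture_fraction = 0.9), assay)
  expect_equal(z$A520_pH1 - z$A700_pH1, z$A520_pH45 - z$A700_pH45)
  # forward-inverse round trip over random panels
  set.seed(6)
  panel <- data.frame(tcc = runif(100, 0, 20), tac = runif(100, 0, 80),
                      moisture_fraction = runif(100, 0.82, 0.93))
  ab <- invert_pigment_equations(panel, assay)
  fw_tcc <- lichtenthaler_tcc(ab$A662, ab$A645, ab$A470,
                              extract_volume_mL = assay$tcc_volume_mL,
                              sample_mass_g = assay$tcc_mass_g,
                              moisture_fraction = panel$moisture_fraction)
  fw_tac <- ph_differential_tac(ab$A520_pH1, ab$A700_pH1, ab$A520_pH45,
                                ab$A700_pH45, DF = assay$DF, MW = assay$MW,
                                EF = assay$EF,
                                extract_volume_mL = assay$tac_volume_mL,
                                sample_mass_g = assay$tac_mass_g,
                                moisture_fraction = panel$moisture_fraction)
  expect_lt(max(abs(fw_tcc$tcc_mg_per_100g_fw - panel$tcc)), 1e-9)
  expect_lt(max(abs(fw_tac$tac_mg_per_100g_fw - panel$tac)), 1e-9)
  expect_error(invert_pigment_equations(
    data.frame(tcc = -1, tac = NA, moisture_fraction = 0.9), assay),
    "non-negative")
})

test_that("cultivar colour clusters keep their qualitative ordering", {
  cultivars <- default_cultivars()
  labs <- t(vapply(cultivars, `[[`, numeric(3), "mean_lab"))
  groups <- vapply(cultivars, `[[`, "", "colour_group")
  expect_equal(unname(labs[groups == "white", 1]),
               max(labs[, 1]))                       # white: highest L*
  expect_true(all(labs[groups == "purple", 1] <
                    labs[groups != "purple", 1]))    # purple: lowest L*
  expect_true(all(labs[groups == "yellow", 3] >
                    labs[groups == "yellow", 2]))    # yellow: b* >> a*
  expect_true(all(labs[groups %in% c("orange", "red"), 2] > 20))
})

test_that("the noiseless forward pipeline recovers the generative link", {
  # colour varies (biology), but pigment noise, pixel noise and distortion
  # are off: a PLS fit on pipeline-recovered colours should reproduce the
  # generative coefficients nearly exactly
  d <- study_design(seed = 8, light_conditions = identity_conditions()[2],
                    pigment_noise_sd = c(tcc = 0, tac = 0, lutein = 0,
                                         lycopene = 0, alpha_carotene = 0,
                                         beta_carotene = 0),
                    pixel_noise_sd = 0)
  st <- generate_study(d)
  rows <- list()
  for (key in names(st$images)) {
    img <- st$images[[key]]
    cal <- fit_calibration(measure_chips(img, img$checker_layout,
                                         img$checker_reference))
    ci <- apply_calibration(cal, img$pixels)
    for (rn in names(img$roi_polygons)) {
      mask <- rasterise_polygon(img$roi_polygons[[rn]], dim(ci)[1:2])
      lab <- srgb_to_lab(roi_colour(ci, mask)$mean_rgb)
      lch <- lab_to_lch(lab)
      rep <- as.integer(sub(".*_r", "", rn))
      rows[[paste(key, rn)]] <- data.frame(
        cultivar = img$cultivar, replicate = rep,
        L_star = lab[1], a_star = lab[2], b_star = lab[3],
        C_star = lch[2], h_deg = lch[3])
    }
  }
  rec <- do.call(rbind, rows)
  truth <- st$truth[st$truth$light_condition == "WF0", ]
  m <- merge(rec, truth[, c("cultivar", "replicate", "tcc")],
             by = c("cultivar", "replicate"))
  fit <- fit_pls(as.matrix(m[, predictor_cols]), m$tcc)
  expect_gt(fit$r2_ss, 0.99)
  gen <- d$link$tcc[predictor_cols]
  est <- coef(fit)[predictor_cols]
  cosine <- sum(gen * est) / sqrt(sum(gen^2) * sum(est^2))
  expect_gt(cosine, 0.99)
})

test_that("overfull disk layouts are rejected as layout errors", {
  expect_error(study_design(seed = 1, n_replicates = 60), "layout error")
})

test_that("a study can be persisted and read back from plain files", {
  d <- study_design(seed = 9, cultivars = default_cultivars()[c(4, 14)],
                    link = default_links())
  st <- generate_study(d)
  dir <- file.path(tempdir(), "study_out")
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "images", "O1_WF0.png")))
  px <- png::readPNG(file.path(dir, "images", "O1_WF0.png")) * 255
  expect_equal(round(px), st$images[["O1_WF0"]]$pixels, ignore_attr = TRUE)
  rois <- read_rois(file.path(dir, "rois", "O1.json"))
  expect_equal(length(rois), d$n_replicates)
  unlink(dir, recursive = TRUE)
})
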