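test_that("carotenoid equations reproduce hand-computed micro-cases", {
  # chlorophyll-free: A470 = 1 forces Cxc = 1000/227
  r <- lichtenthaler_tcc(0, 0, 1, extract_volume_mL = 3,
                         sample_mass_g = 0.5, moisture_fraction = 0.88)
  expect_equal(r$Ca, 0)
  expect_equal(r$Cb, 0)
  expect_equal(r$Cxc, 1000 / 227, tolerance = 1e-12)
  expect_equal(round(r$Cxc, 4), 4.4053)
  # general case, evaluated by hand from the three equations
  r2 <- lichtenthaler_tcc(0.5, 0.2, 0.8, extract_volume_mL = 3,
                          sample_mass_g = 0.5, moisture_fraction = 0.88)
  Ca <- 11.75 * 0.5 - 2.35 * 0.2
  Cb <- 18.61 * 0.2 - 3.96 * 0.5
  expect_equal(r2$Ca, Ca)            # 5.4050
  expect_equal(r2$Cb, Cb)            # 1.7420
  expect_equal(r2$Cxc, (1000 * 0.8 - 2.27 * Ca - 81.4 * Cb) / 227,
               tolerance = 1e-12)    # 2.8455
  expect_equal(round(r2$Cxc, 4), 2.8455)
  # all-zero absorbances give zero contents
  r0 <- lichtenthaler_tcc(0, 0, 0, extract_volume_mL = 3,
                          sample_mass_g = 0.5, moisture_fraction = 0.88)
  expect_equal(unlist(r0), c(Ca = 0, Cb = 0, Cxc = 0,
                             tcc_mg_per_100g_fw = 0))
})

test_that("anthocyanin pH-differential maths matches hand evaluation", {
  r <- ph_differential_tac(1.0, 0, 0.2, 0, DF = 40,
                           extract_volume_mL = 10, sample_mass_g = 1,
                           moisture_fraction = 0.88)
  expect_equal(r$A, 0.8)
  expect_equal(r$tac_mg_per_L, 0.8 * 449.2 * 40 * 1000 / 26900,
               tolerance = 1e-12)   # 534.3643...
  expect_equal(round(r$tac_mg_per_L, 4), 534.3643)
  # identical buffer readings: zero anthocyanin
  r0 <- ph_differential_tac(0.5, 0.1, 0.5, 0.1, DF = 40,
                            extract_volume_mL = 10, sample_mass_g = 1,
                            moisture_fraction = 0.88)
  expect_equal(r0$tac_mg_per_L, 0)
  # linearity in the dilution factor
  r80 <- ph_differential_tac(1.0, 0, 0.2, 0, DF = 80,
                             extract_volume_mL = 10, sample_mass_g = 1,
                             moisture_fraction = 0.88)
  expect_equal(r80$tac_mg_per_L, 2 * r$tac_mg_per_L)
})

test_that("path length, mass and moisture conversions behave linearly", {
  base <- lichtenthaler_tcc(0, 0, 0.8, extract_volume_mL = 3,
                            sample_mass_g = 0.5, moisture_fraction = 0.9)
  # doubling the path halves the effective absorbance
  half <- lichtenthaler_tcc(0, 0, 0.8, path_length_cm = 2,
                            extract_volume_mL = 3, sample_mass_g = 0.5,
                            moisture_fraction = 0.9)
  expect_equal(half$Cxc, base$Cxc / 2)
  # doubling the sample mass halves mg/100 g
  dm <- lichtenthaler_tcc(0, 0, 0.8, extract_volume_mL = 3,
                          sample_mass_g = 1, moisture_fraction = 0.9)
  expect_equal(dm$tcc_mg_per_100g_fw, base$tcc_mg_per_100g_fw / 2)
  # fresh-weight content is linear in (1 - moisture)
  m2 <- lichtenthaler_tcc(0, 0, 0.8, extract_volume_mL = 3,
                          sample_mass_g = 0.5, moisture_fraction = 0.8)
  expect_equal(m2$tcc_mg_per_100g_fw / base$tcc_mg_per_100g_fw,
               (1 - 0.8) / (1 - 0.9))
})

test_that("duplicate anthocyanin extractions are averaged before Eq-level maths", {
  a1 <- cbind(c(1.0), c(1.2))  # two extractions of the same sample
  r <- ph_differential_tac(a1, cbind(0, 0), cbind(0.2, 0.2), cbind(0, 0),
                           DF = 40, extract_volume_mL = 10,
                           sample_mass_g = 1, moisture_fraction = 0.88)
  expect_equal(r$A, (1.1 - 0.2))
})

test_that("inconsistent or invalid readings are rejected", {
  expect_error(lichtenthaler_tcc(-0.1, 0, 1, extract_volume_mL = 3,
                                 sample_mass_g = 0.5,
                                 moisture_fraction = 0.88),
               "non-negative")
  expect_error(lichtenthaler_tcc(1, 1, 0, extract_volume_mL = 3,
                                 sample_mass_g = 0.5,
                                 moisture_fraction = 0.88),
               "negative total-carotenoid")
  expect_error(ph_differential_tac(0.2, 0, 1.0, 0, DF = 40,
                                   extract_volume_mL = 10,
                                   sample_mass_g = 1,
                                   moisture_fraction = 0.88),
               "negative pH-differential")
  expect_error(ph_differential_tac(1, 0, 0.2, 0, DF = 0.5,
                                   extract_volume_mL = 10,
                                   sample_mass_g = 1,
                                   moisture_fraction = 0.88), "DF")
  expect_error(lichtenthaler_tcc(0, 0, 1, extract_volume_mL = 3,
                                 sample_mass_g = 0.5,
                                 moisture_fraction = 1), "moisture")
})

test_that("content filters implement the omission rules with reason codes", {
  records <- data.frame(
    cultivar = c("O1", "O2", "W1", "P1", "P2", "R1", "PY1", "Y1"),
    tcc = c(8.2, 0.20, 0.30, 0.24, 2.0, 15.1, 5.0, 0.10),
    tac = c(0.1, NA, 0.0, 45.0, 30.0, 0.9, 6.0, 0.2),
    lutein = c(0.30, 0.03, 0.020, 0.50, 0.40, 0.60, 0.65, 0.10),
    lycopene = c(0, 0, 0, 0, 0, 1.7, 0, 0))
  # total carotenoids: pure 0.25 mg/100 g threshold
  f <- apply_content_filters(records, "tcc")
  expect_equal(f$kept$cultivar, c("O1", "W1", "P2", "R1", "PY1"))
  expect_equal(f$removed$reason,
               rep("below_threshold", 3))
  expect_equal(nrow(f$kept) + nrow(f$removed), nrow(records))
  # total anthocyanins: threshold plus red-cultivar exclusion
  f2 <- apply_content_filters(records, "tac")
  expect_equal(f2$kept$cultivar, c("P1", "P2", "PY1"))
  expect_true("red_cultivar_excluded" %in% f2$removed$reason)
  expect_equal(f2$removed$reason[f2$removed$cultivar == "R1"],
               "red_cultivar_excluded")
  # individual carotenoids: purple excluded, detection limit 0.025 applies
  f3 <- apply_content_filters(records, "lutein")
  expect_false(any(f3$kept$cultivar %in% c("P1", "P2")))
  expect_true("O2" %in% f3$kept$cultivar)   # 0.03 >= detection limit
  expect_equal(f3$removed$reason[f3$removed$cultivar == "W1"],
               "below_detection_limit")
  expect_equal(f3$removed$reason[f3$removed$cultivar == "P1"],
               "purple_cultivar_excluded")
  # lycopene is never modelled
  f4 <- apply_content_filters(records, "lycopene")
  expect_equal(nrow(f4$kept), 0)
  expect_true(all(f4$removed$reason == "not_modelled"))
  # degenerate inputs
  f5 <- apply_content_filters(records[0, ], "tcc")
  expect_equal(nrow(f5$kept), 0)
  expect_error(apply_content_filters(records, "chlorophyll"),
               "unknown pigment")
  expect_error(apply_content_filters(records[, -2], "tcc"), "content column")
})
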