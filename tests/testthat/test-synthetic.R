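test_that("class mean curves follow the closed form and its edge cases", {
  # all feature amplitudes zero and flat red edge -> flat base curve
  flat <- profile_config(wavelengths = tiny_grid(),
                         features = within(default_features(),
                                           amplitude <- amplitude * 0),
                         red_edge = list(amplitude = 0, center = 715,
                                         width = 16))
  pr <- make_class_profiles(flat)
  for (curve in pr$mean_curves)
    expect_equal(curve, rep(0.3, 16))

  # single trough of depth 0.30 at 660 nm on base 0.45 -> 0.15 at 660 nm
  grid <- c(600, 630, 660, 690, 720)
  cfg <- profile_config(
    wavelengths = grid, base_reflectance = 0.45,
    features = data.frame(name = "red_trough", center = 660, width = 20,
                          amplitude = 0.30, kind = "trough",
                          stress_scaled = FALSE),
    red_edge = list(amplitude = 0, center = 715, width = 16))
  pr <- make_class_profiles(cfg)
  expect_equal(pr$mean_curves[["PET_0"]][3], 0.45 - 0.30)

  # determinism: identical config -> bitwise-identical profiles
  expect_identical(make_class_profiles(profile_config()),
                   make_class_profiles(profile_config()))

  # non-finite feature parameter rejected with the field named
  bad <- default_features(); bad$width[2] <- NaN
  expect_error(profile_config(features = bad), "features_width")
})

test_that("profiles stay in [0,1] and separability grows with the stress knob", {
  pr <- make_class_profiles(profile_config())
  for (curve in pr$mean_curves) {
    expect_true(all(curve >= 0 & curve <= 1))
  }
  # a stronger perturbation knob (scaling every stress effect together)
  # never decreases the distance between class means
  sep <- function(strength) {
    cfg <- profile_config(
      depth_scales = c("0" = 1, "10" = 1 - 0.1 * strength,
                       "100" = 1 - 0.2 * strength),
      red_edge_shift_nm = c("0" = 0, "10" = -1.8 * strength,
                            "100" = -3.5 * strength),
      nir_scales = c("0" = 1, "10" = 1 - 0.03 * strength,
                     "100" = 1 - 0.06 * strength))
    p <- make_class_profiles(cfg)
    sqrt(sum((p$mean_curves[["PET_0"]] - p$mean_curves[["PET_100"]])^2))
  }
  d <- vapply(seq(0, 1.4, by = 0.2), sep, 0)
  expect_true(all(diff(d) >= 0))
})

test_that("simulate_spectra honours the noise model and sample counts", {
  pr <- noiseless_profiles()
  # noiseless: every sample equals its class mean exactly
  sp <- simulate_spectra(pr, n_per_class = 4, seed = 3, polymers = "PS")
  for (i in seq_len(nrow(sp$X))) {
    key <- paste(sp$polymer[i], sp$class_mg_l[i], sep = "_")
    expect_equal(unname(sp$X[i, ]), unname(pr$mean_curves[[key]]))
  }

  # 300 per class x 3 classes of one polymer -> 900 rows
  sp2 <- simulate_spectra(pr, n_per_class = 300, seed = 1, polymers = "PET")
  expect_equal(nrow(sp2$X), 900)
  expect_equal(as.integer(table(sp2$class_mg_l)), rep(300L, 3))

  # CLT: mean over 1e4 i.i.d.-noise draws within 4 * noise_sd / 100 of truth
  noisy <- make_class_profiles(profile_config(wavelengths = tiny_grid(),
                                              noise_sd = 0.01, gain_sd = 0,
                                              offset_sd = 0))
  draws <- simulate_spectra(noisy, n_per_class = 10000, seed = 5,
                            polymers = "PET")
  one <- draws$X[draws$class_mg_l == "0", ]
  expect_lt(max(abs(colMeans(one) - noisy$mean_curves[["PET_0"]])),
            4 * 0.01 / 100)

  # all reflectances in [0,1]; same seed reproduces bitwise
  full <- simulate_spectra(make_class_profiles(profile_config()), 10, seed = 9)
  expect_true(all(full$X >= 0 & full$X <= 1))
  expect_identical(full,
                   simulate_spectra(make_class_profiles(profile_config()),
                                    10, seed = 9))
  expect_error(simulate_spectra(pr, n_per_class = 0), "n_per_class")
})

test_that("simulate_cube plants regions faithfully", {
  pr <- noiseless_profiles(tiny_grid(8))
  # zero leaf regions -> empty mask
  empty <- cube_layout(10, 12, data.frame())
  sim0 <- simulate_cube(empty, pr, seed = 1)
  expect_true(all(sim0$mask == 0L))
  expect_true(all(sim0$cube$data == 0.9))

  # ten disjoint ellipses -> ten labelled regions, planted means exact
  sim <- simulate_cube(ten_leaf_layout(), pr, seed = 1)
  expect_equal(max(sim$mask), 10L)
  regions <- ten_leaf_layout()$leaf_regions
  for (k in seq_len(10)) {
    px <- which(sim$mask == k)
    slab <- matrix(sim$cube$data, ncol = 8)[px, , drop = FALSE]
    key <- paste(regions$polymer[k], regions$class_mg_l[k], sep = "_")
    expect_lt(max(abs(sweep(slab, 2, pr$mean_curves[[key]]))), 1e-12)
  }

  # overlapping regions are ambiguous ground truth -> error
  bad <- cube_layout(30, 30, data.frame(cy = c(15, 16), cx = c(15, 16),
                                        ry = 5, rx = 5, polymer = "PET",
                                        class_mg_l = "0"))
  expect_error(simulate_cube(bad, pr), "overlap")
  oob <- cube_layout(10, 10, data.frame(cy = 5, cx = 9, ry = 3, rx = 3,
                                        polymer = "PET", class_mg_l = "0"))
  expect_error(simulate_cube(oob, pr), "bounds")
})

test_that("simulate_ftir_series plants shapes, order, and valid intensities", {
  specs <- data.frame(center = c(3356, 2910, 1730), width = c(60, 30, 25),
                      order = c(1L, 2L, 3L))
  ft <- simulate_ftir_series(specs, n_levels = 16, seed = 2)
  expect_equal(dim(ft$spectra), c(16, length(seq(4000, 800, by = -4))))
  expect_true(all(diff(ft$wavenumbers) < 0))
  expect_equal(attr(ft, "planted_order"), c(3356, 2910, 1730))
  # transmittance equivalent lies in (0, 1]
  tr <- absorbance_to_transmission(ft)
  expect_true(all(tr$spectra > 0 & tr$spectra <= 1))

  # all bands sharing one onset (zero stagger) -> simultaneous ground truth
  same <- data.frame(center = c(1000, 1200), width = 20, order = 1:2)
  expect_equal(attr(simulate_ftir_series(same, 8, lead_deg = 0),
                    "planted_order"), "simultaneous")
  expect_error(simulate_ftir_series(
    data.frame(center = c(1000, 1200), width = 20, order = c(1L, 1L)), 8),
    "permutation")
  one <- simulate_ftir_series(data.frame(center = 1000, width = 20,
                                         order = 1L), 8)
  expect_equal(attr(one, "planted_order"), 1000)

  expect_error(simulate_ftir_series(
    data.frame(center = c(1000, 1000), width = 20, order = 1:2), 8),
    "duplicate")
  expect_identical(simulate_ftir_series(specs, 16, seed = 7),
                   simulate_ftir_series(specs, 16, seed = 7))
})

test_that("planted-informative-band generator shifts only the planted bands", {
  sp <- simulate_informative_spectra(n_per_class = 200, n_bands = 10,
                                     informative = c(2L, 7L), effect = 2,
                                     seed = 4)
  expect_equal(attr(sp, "informative"), c(2L, 7L))
  m0 <- colMeans(sp$X[sp$class_mg_l == "0", ])
  m2 <- colMeans(sp$X[sp$class_mg_l == "2", ])
  gap <- abs(m2 - m0)
  expect_true(all(gap[c(2, 7)] > 3))
  expect_true(all(gap[-c(2, 7)] < 1))
})
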