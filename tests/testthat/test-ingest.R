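test_that("ENVI round trips are bit-exact and headers are validated", {
  set.seed(1)
  cube <- spectral_cube(array(runif(4 * 4 * 5), dim = c(4, 4, 5)),
                        seq(500, 540, by = 10), meta = "roundtrip test")
  path <- file.path(tempdir(), "rt.img")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_identical(back$data, cube$data)
  expect_identical(back$wavelengths, cube$wavelengths)

  # BIL and BSQ interleaves agree bitwise
  path2 <- file.path(tempdir(), "rt_bil.img")
  write_cube(cube, path2, interleave = "bil")
  expect_identical(read_cube(path2)$data, cube$data)

  # header without wavelengths is refused, not silently indexed
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(hdr[!grepl("wavelength", hdr)], paste0(path, ".hdr"))
  expect_error(read_cube(path), "wavelengths")

  expect_error(write_cube(cube, path, format = "hdf5"), "envi")
  expect_error(spectral_cube(array(0, dim = c(2, 2, 3)), c(1, 2)),
               "3 bands but 2")
})

test_that("band_index finds nearest centres with the lower-wavelength tie rule", {
  expect_equal(band_index(c(650, 655, 660), 655), 2L)
  expect_equal(band_index(c(654, 656), 655), 1L)   # tie -> lower wavelength
  # exhaustive-scan oracle on the default grid
  grid <- default_wavelengths()
  oracle <- function(target) {
    best <- 1
    for (i in seq_along(grid))
      if (abs(grid[i] - target) < abs(grid[best] - target)) best <- i
    best
  }
  for (target in c(425, 655, 531.7, 940, 965))
    expect_equal(band_index(grid, target), oracle(target))
  expect_error(band_index(grid, 300), "outside")
})

test_that("segmentation thresholds at 655 nm and labels 8-connected regions", {
  fx <- rect_cube()
  # uniform bright image -> no leaves
  flat <- spectral_cube(array(0.9, dim = c(10, 10, 3)), c(650, 655, 660))
  expect_equal(segment_leaves(flat)$n_regions, 0L)

  # two dark rectangles recovered with their exact pixel sets
  mask <- segment_leaves(fx$cube, band_nm = 655, threshold = 0.6,
                         min_area = 5)
  expect_equal(mask$n_regions, 2L)
  m1 <- matrix(FALSE, 20, 30); m1[fx$r1$y, fx$r1$x] <- TRUE
  m2 <- matrix(FALSE, 20, 30); m2[fx$r2$y, fx$r2$x] <- TRUE
  expect_identical(mask$labels == 1L, m1)
  expect_identical(mask$labels == 2L, m2)

  # lowering the threshold never adds leaf pixels; idempotent relabelling
  for (th in c(0.5, 0.3, 0.1)) {
    lower <- segment_leaves(fx$cube, threshold = th, min_area = 1)
    expect_true(all(which(lower$labels > 0) %in% which(mask$labels > 0)))
  }
  expect_error(segment_leaves(fx$cube, threshold = 1.2), "threshold")
})

test_that("segmentation recovers the synthetic ten-leaf board", {
  pr <- noiseless_profiles(tiny_grid(8))
  sim <- simulate_cube(ten_leaf_layout(), pr, seed = 1)
  mask <- segment_leaves(sim$cube, band_nm = 655, threshold = 0.6)
  expect_equal(mask$n_regions, 10L)
  # every recovered region matches one ground-truth region exactly
  for (k in seq_len(10)) {
    truth_label <- unique(sim$mask[mask$labels == k])
    expect_length(truth_label, 1L)
    expect_setequal(which(mask$labels == k), which(sim$mask == truth_label))
  }
})

test_that("mean-spectrum extraction is exact and noise-stable", {
  fx <- rect_cube(bands = 4)
  mask <- segment_leaves(fx$cube, min_area = 5)
  sp <- extract_mean_spectra(fx$cube, mask)
  expect_equal(nrow(sp$X), 2)
  expect_true(all(sp$X == 0.2))

  # single-pixel region returns that pixel's spectrum exactly
  lab <- matrix(0L, 3, 3); lab[2, 2] <- 1L
  set.seed(2)
  cube <- spectral_cube(array(runif(3 * 3 * 6), dim = c(3, 3, 6)),
                        seq_len(6) + 500)
  expect_equal(unname(extract_mean_spectra(cube, lab)$X[1, ]),
               cube$data[2, 2, ])

  # 2-pixel region mean is (a + b) / 2 per band, bitwise
  lab2 <- matrix(0L, 3, 3); lab2[1, 1] <- 1L; lab2[3, 2] <- 1L
  got <- extract_mean_spectra(cube, lab2)$X[1, ]
  expect_identical(unname(got), (cube$data[1, 1, ] + cube$data[3, 2, ]) / 2)

  # noiseless synthetic board: planted class curves to 1e-12
  pr <- noiseless_profiles(tiny_grid(8))
  sim <- simulate_cube(ten_leaf_layout(), pr, seed = 1)
  means <- extract_mean_spectra(sim$cube, sim$mask)
  regions <- ten_leaf_layout()$leaf_regions
  for (k in seq_len(10)) {
    key <- paste(regions$polymer[k], regions$class_mg_l[k], sep = "_")
    expect_lt(max(abs(means$X[k, ] - pr$mean_curves[[key]])), 1e-12)
  }

  # noisy cube: recovery within 3 * noise_sd / sqrt(region area)
  simn <- simulate_cube(ten_leaf_layout(), pr, seed = 3, noise_sd = 0.02)
  meansn <- extract_mean_spectra(simn$cube, simn$mask)
  for (k in seq_len(10)) {
    key <- paste(regions$polymer[k], regions$class_mg_l[k], sep = "_")
    area <- sum(simn$mask == k)
    expect_lt(max(abs(meansn$X[k, ] - pr$mean_curves[[key]])),
              3 * 0.02 / sqrt(area))
  }

  expect_error(extract_mean_spectra(cube, lab,
                                    data.frame(polymer = NA,
                                               class_mg_l = "0")),
               "empty region label")
  expect_error(extract_mean_spectra(cube, matrix(0L, 2, 2)), "shape")
})

test_that("crop_bands keeps the closed interval and is idempotent", {
  pr <- make_class_profiles(profile_config())   # default 256-band grid
  sp <- simulate_spectra(pr, n_per_class = 2, seed = 1, polymers = "PET")
  cropped <- crop_bands(sp, 425, 965)
  expect_equal(ncol(cropped$X), 256)            # full retained range
  expect_identical(crop_bands(cropped, 425, 965), cropped)

  toy <- labeled_spectra(matrix(1, 2, 3), c(400, 500, 600),
                         c("PET", "PET"), c("0", "0"))
  one <- crop_bands(toy, 450, 550)
  expect_equal(one$wavelengths, 500)
  expect_error(crop_bands(toy, 601, 700), "no bands")
  expect_error(crop_bands(toy, 700, 600), "lo_nm")
})

test_that("spectra CSV round trip preserves data and labels", {
  pr <- noiseless_profiles()
  sp <- simulate_spectra(pr, n_per_class = 3, seed = 1)
  path <- file.path(tempdir(), "spectra.csv")
  write_spectra_csv(sp, path)
  back <- read_spectra_csv(path)
  expect_equal(back$X, sp$X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.character(back$class_mg_l), as.character(sp$class_mg_l))
  expect_equal(back$wavelengths, sp$wavelengths, tolerance = 1e-9)
})
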