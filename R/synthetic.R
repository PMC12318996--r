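#' Default VNIR wavelength grid
#'
#' 256 equally spaced band centres spanning 425--965 nm, the band range
#' retained after trimming noisy spectral boundaries from a ~380--1013 nm
#' push-broom acquisition.
#'
#' @return Numeric vector of 256 strictly increasing wavelengths (nm).
#' @export
default_wavelengths <- function() seq(425, 965, length.out = 256)

#' Generator settings for class-structured leaf reflectance profiles
#'
#' Builds the configuration consumed by [make_class_profiles()].  The mean
#' curve of every (polymer, concentration) class is a flat base reflectance
#' plus Gaussian pigment/water features and a logistic red-edge rise:
#' a blue absorption trough near 480 nm (chlorophyll/carotenoid), a green
#' reflectance peak near 540 nm, the strong chlorophyll-a trough near 660 nm,
#' the red-edge transition over 660--770 nm, and a near-infrared water
#' feature near 940 nm.
#'
#' Concentration stress is encoded the way pigment degradation shows up in
#' real leaves: the absorption troughs get shallower (multiplicative
#' `depth_scales`) and the red edge shifts by a few nanometres
#' (`red_edge_shift_nm`, at most 5 nm).  Polymers differ by small multipliers
#' on the water feature so all nine classes are distinct.
#'
#' Sample-level variability has three components: a smooth multiplicative
#' gain (`gain_sd`, leaf-to-leaf brightness), an additive offset
#' (`offset_sd`, baseline level), and independent per-band Gaussian noise
#' (`noise_sd`).  The gain/offset terms are low-rank and mimic the dominant
#' correlated variation of real leaf spectra; set them to zero for a purely
#' i.i.d. noise model.
#'
#' @param wavelengths Band centres in nm, strictly increasing.
#' @param base_reflectance Flat base level of the mean curves.
#' @param features Data frame with columns `name`, `center`, `width`,
#'   `amplitude`, `kind` (`"trough"`, `"peak"`), `stress_scaled` (logical:
#'   does the concentration depth scaling apply).
#' @param red_edge List with `amplitude`, `center`, `width` of the logistic
#'   red-edge term.
#' @param depth_scales Named numeric, trough/peak depth multiplier per
#'   concentration class (mg/L).
#' @param red_edge_shift_nm Named numeric, red-edge centre shift (nm) per
#'   concentration class.
#' @param nir_scales Named numeric, red-edge/NIR plateau amplitude
#'   multiplier per concentration class (cell-structure damage lowers NIR
#'   reflectance under stress).
#' @param polymers Polymer labels.
#' @param polymer_water_scale Water-feature depth multiplier per polymer.
#' @param noise_sd,gain_sd,offset_sd Sample variability (see Details).
#' @param seed Integer seed stored with the profiles.
#' @return A list of class `"profile_config"`.
#' @export
profile_config <- function(wavelengths = default_wavelengths(),
                           base_reflectance = 0.30,
                           features = default_features(),
                           red_edge = list(amplitude = 0.45, center = 715,
                                           width = 16),
                           depth_scales = c("0" = 1.00, "10" = 0.86,
                                            "100" = 0.72),
                           red_edge_shift_nm = c("0" = 0, "10" = -2.5,
                                                 "100" = -5),
                           nir_scales = c("0" = 1.00, "10" = 0.96,
                                          "100" = 0.92),
                           polymers = c("PET", "PS", "PVC"),
                           polymer_water_scale = c(PET = 1.00, PS = 0.90,
                                                   PVC = 1.10),
                           noise_sd = 0.005,
                           gain_sd = 0.05,
                           offset_sd = 0.01,
                           seed = 1L) {
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  num_fields <- list(base_reflectance = base_reflectance,
                     noise_sd = noise_sd, gain_sd = gain_sd,
                     offset_sd = offset_sd,
                     depth_scales = depth_scales,
                     red_edge_shift_nm = red_edge_shift_nm,
                     nir_scales = nir_scales,
                     red_edge = unlist(red_edge),
                     features_center = features$center,
                     features_width = features$width,
                     features_amplitude = features$amplitude)
  for (nm in names(num_fields))
    if (!all(is.finite(num_fields[[nm]])))
      stopf("non-finite value in field '%s'", nm)
  if (noise_sd < 0 || gain_sd < 0 || offset_sd < 0)
    stopf("noise/gain/offset standard deviations must be >= 0")
  if (any(abs(red_edge_shift_nm) > 5))
    stopf("red_edge_shift_nm limited to 5 nm in magnitude")
  structure(list(wavelengths = wavelengths,
                 base_reflectance = base_reflectance,
                 features = features, red_edge = red_edge,
                 depth_scales = depth_scales,
                 red_edge_shift_nm = red_edge_shift_nm,
                 nir_scales = nir_scales,
                 polymers = polymers,
                 polymer_water_scale = polymer_water_scale,
                 noise_sd = noise_sd, gain_sd = gain_sd,
                 offset_sd = offset_sd, seed = as.integer(seed)),
            class = "profile_config")
}

#' @rdname profile_config
#' @export
default_features <- function() {
  data.frame(
    name = c("blue_trough", "green_peak", "red_trough", "water_trough"),
    center = c(480, 540, 660, 940),
    width = c(25, 30, 22, 30),
    amplitude = c(0.12, 0.08, 0.14, 0.06),
    kind = c("trough", "peak", "trough", "trough"),
    stress_scaled = c(TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

gauss <- function(x, center, width) exp(-((x - center)^2) / (2 * width^2))

# Closed-form mean reflectance curve for one (polymer, class) cell.
class_mean_curve <- function(config, polymer, class_mg_l) {
  wl <- config$wavelengths
  cls <- as.character(class_mg_l)
  ds <- config$depth_scales[[cls]]
  shift <- config$red_edge_shift_nm[[cls]]
  r <- rep(config$base_reflectance, length(wl))
  fx <- config$features
  for (i in seq_len(nrow(fx))) {
    a <- fx$amplitude[i]
    if (isTRUE(fx$stress_scaled[i])) a <- a * ds
    if (fx$name[i] == "water_trough")
      a <- a * config$polymer_water_scale[[polymer]]
    sgn <- if (fx$kind[i] == "trough") -1 else 1
    r <- r + sgn * a * gauss(wl, fx$center[i], fx$width[i])
  }
  re <- config$red_edge
  nsc <- if (is.null(config$nir_scales)) 1 else config$nir_scales[[cls]]
  r <- r + nsc * re$amplitude * plogis((wl - (re$center + shift)) / re$width)
  pmin(pmax(r, 0), 1)
}

#' Build the class-mean reflectance profiles
#'
#' Evaluates the closed-form mean curve of every (polymer, concentration
#' class) combination on the configured wavelength grid.
#'
#' @param config A [profile_config()].
#' @return A list of class `"class_profile_set"` with elements
#'   `wavelengths`, `mean_curves` (named list, `"POLY_CLASS"` keys),
#'   `classes`, `polymers`, and the generating `config`.
#' @export
make_class_profiles <- function(config = profile_config()) {
  stopifnot(inherits(config, "profile_config"))
  classes <- names(config$depth_scales)
  curves <- list()
  for (p in config$polymers)
    for (cl in classes)
      curves[[paste(p, cl, sep = "_")]] <- class_mean_curve(config, p, cl)
  structure(list(wavelengths = config$wavelengths, mean_curves = curves,
                 classes = classes, polymers = config$polymers,
                 config = config),
            class = "class_profile_set")
}

#' @export
print.class_profile_set <- function(x, ...) {
  cat(sprintf("Class profile set: %d curves (%s x %s), %d bands %.1f-%.1f nm\n",
              length(x$mean_curves), paste(x$polymers, collapse = "/"),
              paste(x$classes, collapse = "/"), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Simulate labelled leaf spectra
#'
#' Draws `n_per_class` spectra for every (polymer, concentration class)
#' cell: class mean times a per-sample gain, plus a per-sample offset and
#' i.i.d. per-band Gaussian noise, clipped to `[0, 1]`.
#'
#' @param profiles A [make_class_profiles()] result.
#' @param n_per_class Samples per (polymer, class) cell; default 300 (one to
#'   two leaves from each seedling of a treatment group).
#' @param seed Integer seed.
#' @param polymers Subset of polymers to simulate (default: all in the
#'   profile set).
#' @param noise_sd,gain_sd,offset_sd Override the profile configuration.
#' @return A `"labeled_spectra"` object: list with matrix `X`
#'   (samples x bands), `wavelengths`, factors `polymer` and `class_mg_l`,
#'   and `sample_id`.
#' @export
simulate_spectra <- function(profiles, n_per_class = 300, seed = 1L,
                             polymers = profiles$polymers,
                             noise_sd = profiles$config$noise_sd,
                             gain_sd = profiles$config$gain_sd,
                             offset_sd = profiles$config$offset_sd) {
  stopifnot(inherits(profiles, "class_profile_set"))
  if (length(profiles$mean_curves) == 0L) stopf("empty profile set")
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  wl <- profiles$wavelengths
  B <- length(wl)
  cells <- expand.grid(polymer = polymers, class_mg_l = profiles$classes,
                       stringsAsFactors = FALSE)
  n <- nrow(cells) * n_per_class
  with_seed(seed, {
    X <- matrix(0, n, B)
    polymer <- character(n); class_mg_l <- character(n)
    row <- 0L
    for (i in seq_len(nrow(cells))) {
      mu <- profiles$mean_curves[[paste(cells$polymer[i], cells$class_mg_l[i],
                                        sep = "_")]]
      for (j in seq_len(n_per_class)) {
        row <- row + 1L
        gain <- 1 + if (gain_sd > 0) rnorm(1, 0, gain_sd) else 0
        offs <- if (offset_sd > 0) rnorm(1, 0, offset_sd) else 0
        eps <- if (noise_sd > 0) rnorm(B, 0, noise_sd) else numeric(B)
        X[row, ] <- pmin(pmax(gain * mu + offs + eps, 0), 1)
        polymer[row] <- cells$polymer[i]
        class_mg_l[row] <- cells$class_mg_l[i]
      }
    }
    labeled_spectra(X, wl, polymer, class_mg_l,
                    sample_id = sprintf("%s_%s_%04d", polymer, class_mg_l,
                                        seq_len(n)))
  })
}

#' Construct a labelled-spectra object
#'
#' @param X Samples x bands reflectance matrix.
#' @param wavelengths Band centres (nm), length `ncol(X)`.
#' @param polymer,class_mg_l Per-sample labels.
#' @param sample_id Optional sample identifiers.
#' @return A list of class `"labeled_spectra"`.
#' @export
labeled_spectra <- function(X, wavelengths, polymer, class_mg_l,
                            sample_id = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != length(wavelengths))
    stopf("X has %d columns but %d wavelengths given", ncol(X),
          length(wavelengths))
  if (nrow(X) != length(polymer) || nrow(X) != length(class_mg_l))
    stopf("label length does not match row count")
  if (is.null(sample_id)) sample_id <- sprintf("s%04d", seq_len(nrow(X)))
  structure(list(X = X, wavelengths = as.numeric(wavelengths),
                 polymer = factor(polymer),
                 class_mg_l = factor(class_mg_l,
                                     levels = unique(as.character(class_mg_l))),
                 sample_id = sample_id),
            class = "labeled_spectra")
}

#' @export
print.labeled_spectra <- function(x, ...) {
  cat(sprintf("Labelled spectra: %d samples x %d bands (%.1f-%.1f nm)\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths)))
  print(table(polymer = x$polymer, class_mg_l = x$class_mg_l))
  invisible(x)
}

#' Describe a synthetic leaf board
#'
#' @param height,width Image size in pixels.
#' @param leaf_regions Data frame with one row per leaf: ellipse centre
#'   (`cy`, `cx`), semi-axes (`ry`, `rx`), `polymer`, `class_mg_l`.
#' @param background_reflectance Flat background spectrum level (bright
#'   Teflon board; must exceed the 0.6 segmentation threshold at 655 nm).
#' @return A list of class `"cube_layout"`.
#' @export
cube_layout <- function(height, width, leaf_regions,
                        background_reflectance = 0.9) {
  stopifnot(height >= 1, width >= 1)
  req <- c("cy", "cx", "ry", "rx", "polymer", "class_mg_l")
  if (nrow(leaf_regions) > 0 && !all(req %in% names(leaf_regions)))
    stopf("leaf_regions needs columns: %s", paste(req, collapse = ", "))
  structure(list(height = height, width = width, leaf_regions = leaf_regions,
                 background_reflectance = background_reflectance),
            class = "cube_layout")
}

#' Default ten-leaf board layout
#'
#' Ten narrow vertical ellipses (rice leaves are long and thin) in two rows
#' of five on a bright board, mimicking simultaneous acquisition of ten
#' leaves per scan.
#'
#' @param polymer Polymer label for all leaves.
#' @param classes Concentration classes cycled over the leaves.
#' @return A [cube_layout()].
#' @export
ten_leaf_layout <- function(polymer = "PET", classes = c("0", "10", "100")) {
  cx <- rep(seq(20, 180, length.out = 5), 2)
  cy <- rep(c(35, 105), each = 5)
  cube_layout(140, 200, data.frame(
    cy = cy, cx = cx, ry = 28, rx = 7,
    polymer = polymer,
    class_mg_l = rep_len(classes, 10),
    stringsAsFactors = FALSE))
}

ellipse_pixels <- function(height, width, cy, cx, ry, rx) {
  ys <- pmax(1L, floor(cy - ry)):pmin(height, ceiling(cy + ry))
  xs <- pmax(1L, floor(cx - rx)):pmin(width, ceiling(cx + rx))
  g <- expand.grid(y = ys, x = xs)
  inside <- ((g$y - cy) / ry)^2 + ((g$x - cx) / rx)^2 <= 1
  g[inside, , drop = FALSE]
}

#' Simulate a hyperspectral leaf board
#'
#' Renders a reflectance cube: bright flat background, each elliptical leaf
#' region filled with its class-mean spectrum plus optional i.i.d. pixel
#' noise.  Returns the cube and the ground-truth region mask.
#'
#' @param layout A [cube_layout()].
#' @param profiles A [make_class_profiles()] result.
#' @param seed Integer seed.
#' @param noise_sd Per-pixel, per-band Gaussian noise (default 0).
#' @return List with `cube` (a `"spectral_cube"`) and `mask` (integer
#'   matrix; 0 background, k for leaf k in layout order).
#' @export
simulate_cube <- function(layout, profiles, seed = 1L, noise_sd = 0) {
  stopifnot(inherits(layout, "cube_layout"),
            inherits(profiles, "class_profile_set"))
  wl <- profiles$wavelengths
  B <- length(wl)
  h <- layout$height; w <- layout$width
  regions <- layout$leaf_regions
  # reject out-of-bounds or overlapping regions up front
  mask <- matrix(0L, h, w)
  if (nrow(regions) > 0) {
    for (k in seq_len(nrow(regions))) {
      r <- regions[k, ]
      if (r$cy - r$ry < 1 || r$cy + r$ry > h ||
          r$cx - r$rx < 1 || r$cx + r$rx > w)
        stopf("leaf region %d exceeds image bounds", k)
      px <- ellipse_pixels(h, w, r$cy, r$cx, r$ry, r$rx)
      idx <- cbind(px$y, px$x)
      if (any(mask[idx] != 0L))
        stopf("leaf regions %d and %d overlap", unique(mask[idx][mask[idx] != 0])[1], k)
      mask[idx] <- k
    }
  }
  with_seed(seed, {
    data <- array(layout$background_reflectance, dim = c(h, w, B))
    if (nrow(regions) > 0) {
      for (k in seq_len(nrow(regions))) {
        r <- regions[k, ]
        mu <- profiles$mean_curves[[paste(r$polymer, r$class_mg_l, sep = "_")]]
        px <- which(mask == k, arr.ind = TRUE)
        for (b in seq_len(B)) {
          vals <- rep(mu[b], nrow(px))
          if (noise_sd > 0) vals <- vals + rnorm(nrow(px), 0, noise_sd)
          data[cbind(px, b)] <- pmin(pmax(vals, 0), 1)
        }
      }
    }
    list(cube = spectral_cube(data, wl,
                              meta = "synthetic leaf board (hyperleaf)"),
         mask = mask)
  })
}

#' Simulate an FTIR perturbation series with a planted response order
#'
#' Each spectral band is a Gaussian absorbance peak whose intensity follows
#' a monotone sigmoidal response along the perturbation axis; the onset of
#' band k is delayed according to its planted order, so bands respond
#' sequentially.  With `response = "sinusoid"` the bands instead follow one
#' sinusoidal cycle with a phase lag per rank.  The onset/phase stagger is
#' expressed as `lead_deg`, degrees of the full perturbation window.
#'
#' @param band_specs Data frame with columns `center` (cm^-1), `width`
#'   (cm^-1), `order` (response rank, a permutation of 1..n_bands), and
#'   optionally `amplitude`.
#' @param n_levels Number of perturbation levels (>= 3).
#' @param seed Integer seed.
#' @param wavenumbers Descending grid, default 4000..800 cm^-1 step 4.
#' @param response `"sigmoid"` (staggered monotone onsets, default) or
#'   `"sinusoid"` (phase-lagged single cycle).
#' @param lead_deg Separation between consecutive ranks in degrees of the
#'   perturbation window (default 40).
#' @param noise_sd Additive absorbance noise (default 0).
#' @param baseline Constant absorbance floor so transmittance stays in (0,1].
#' @return A `"ftir_series"` (see [ftir_series()]) whose
#'   `attr(, "planted_order")` lists band centres from first to last
#'   responder.
#' @export
simulate_ftir_series <- function(band_specs, n_levels = 16, seed = 1L,
                                 wavenumbers = seq(4000, 800, by = -4),
                                 response = c("sigmoid", "sinusoid"),
                                 lead_deg = 40, noise_sd = 0,
                                 baseline = 0.05) {
  response <- match.arg(response)
  if (n_levels < 3) stopf("n_levels must be >= 3")
  if (anyDuplicated(band_specs$center))
    stopf("duplicate band centers")
  nb <- nrow(band_specs)
  if (!setequal(band_specs$order, seq_len(nb)))
    stopf("band_specs$order must be a permutation of 1..%d", nb)
  if (is.null(band_specs$amplitude)) band_specs$amplitude <- 0.5
  u <- seq(0, 1, length.out = n_levels)      # normalised perturbation axis
  with_seed(seed, {
    A <- matrix(baseline, n_levels, length(wavenumbers))
    for (k in seq_len(nb)) {
      rank <- band_specs$order[k]
      frac <- (rank - 1) * lead_deg / 360     # onset/phase lag, window units
      resp <- switch(response,
        sigmoid = plogis((u - 0.25 - frac) / 0.08),
        sinusoid = 0.5 + 0.5 * sin(2 * pi * (u - frac)))
      shape <- gauss(wavenumbers, band_specs$center[k], band_specs$width[k])
      A <- A + band_specs$amplitude[k] * outer(resp, shape)
    }
    if (noise_sd > 0)
      A <- A + matrix(rnorm(length(A), 0, noise_sd), nrow(A))
    A <- pmax(A, 1e-6)
    planted <- band_specs$center[order(band_specs$order)]
    if (nb > 1L && lead_deg == 0) planted <- "simultaneous"
    out <- ftir_series(wavenumbers, A, mode = "absorbance",
                       levels = u, tissue = "synthetic")
    attr(out, "planted_order") <- planted
    out
  })
}

#' Simulate spectra with a few planted informative bands
#'
#' Benchmark generator for wavelength-selection methods: all bands are
#' Gaussian noise except `informative` band positions, whose means shift by
#' `effect` per class step.  Ground truth is carried in
#' `attr(, "informative")`.
#'
#' @param n_per_class Samples per class.
#' @param n_bands Total bands.
#' @param informative Indices of the informative bands.
#' @param effect Mean shift per class step (in noise-sd units of 1).
#' @param n_classes Number of classes.
#' @param seed Integer seed.
#' @return A `"labeled_spectra"` object (polymer label `"SYN"`).
#' @export
simulate_informative_spectra <- function(n_per_class = 50, n_bands = 40,
                                         informative = c(5L, 18L, 33L),
                                         effect = 1.5, n_classes = 3,
                                         seed = 1L) {
  stopifnot(all(informative >= 1), all(informative <= n_bands))
  n <- n_per_class * n_classes
  with_seed(seed, {
    X <- matrix(rnorm(n * n_bands), n, n_bands)
    cls <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    for (b in informative) X[, b] <- X[, b] + effect * cls
    out <- labeled_spectra(X, seq_len(n_bands), rep("SYN", n),
                           as.character(cls))
    attr(out, "informative") <- sort(informative)
    out
  })
}
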