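#' Construct an FTIR perturbation series
#'
#' @param wavenumbers Monotone wavenumber grid (cm^-1); acquisition order
#'   4000 down to 800 cm^-1 is the convention.
#' @param spectra Levels x wavenumbers intensity matrix, rows ordered by
#'   increasing perturbation (e.g. 0, 10, 100 mg/L).
#' @param mode `"transmission"` or `"absorbance"`.
#' @param levels Optional numeric perturbation values, strictly increasing.
#' @param tissue Free-text tissue tag (e.g. `"vein"`, `"mesophyll"`).
#' @return A list of class `"ftir_series"`.
#' @export
ftir_series <- function(wavenumbers, spectra,
                        mode = c("transmission", "absorbance"),
                        levels = NULL, tissue = "") {
  mode <- match.arg(mode)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavenumbers))
    stopf("spectra has %d columns but %d wavenumbers", ncol(spectra),
          length(wavenumbers))
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0)))
    stopf("wavenumbers must be monotone")
  if (is.null(levels)) levels <- seq_len(nrow(spectra)) - 1
  if (any(diff(levels) <= 0))
    stopf("perturbation levels must be strictly increasing")
  structure(list(wavenumbers = as.numeric(wavenumbers), spectra = spectra,
                 mode = mode, levels = as.numeric(levels), tissue = tissue),
            class = "ftir_series")
}

#' @export
print.ftir_series <- function(x, ...) {
  cat(sprintf("FTIR series (%s%s): %d levels x %d wavenumbers (%.0f-%.0f cm-1)\n",
              x$mode, if (nzchar(x$tissue)) paste0(", ", x$tissue) else "",
              nrow(x$spectra), length(x$wavenumbers),
              x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)]))
  invisible(x)
}

#' Convert transmission to absorbance (Beer--Lambert)
#'
#' `A = -log10(T)` per point.  Transmittance values above 1 (detector or
#' reference artefacts) are clipped to 1 and counted; non-positive values
#' are an error.
#'
#' @param series A transmission-mode `"ftir_series"`.
#' @return An absorbance-mode series; `attr(, "n_clipped")` counts clipped
#'   points.
#' @export
transmission_to_absorbance <- function(series) {
  stopifnot(inherits(series, "ftir_series"))
  if (series$mode != "transmission")
    stopf("series is already in %s mode", series$mode)
  T <- series$spectra
  bad <- which(T <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-positive transmittance at level %d, wavenumber %.0f cm-1",
          bad[1, 1], series$wavenumbers[bad[1, 2]])
  n_clipped <- sum(T > 1)
  T[T > 1] <- 1
  out <- ftir_series(series$wavenumbers, -log10(T), mode = "absorbance",
                     levels = series$levels, tissue = series$tissue)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' @rdname transmission_to_absorbance
#' @export
absorbance_to_transmission <- function(series) {
  stopifnot(inherits(series, "ftir_series"),
            series$mode == "absorbance")
  ftir_series(series$wavenumbers, 10^(-series$spectra),
              mode = "transmission", levels = series$levels,
              tissue = series$tissue)
}

# Greatest convex minorant (lower hull) of (x, y) by Andrew's monotone
# chain; x must be sorted ascending.
lower_hull <- function(x, y) {
  n <- length(x)
  idx <- integer(0)
  for (i in seq_len(n)) {
    while (length(idx) >= 2) {
      a <- idx[length(idx) - 1]; b <- idx[length(idx)]
      # drop b if it lies on/above segment a-i
      if ((y[b] - y[a]) * (x[i] - x[a]) >= (y[i] - y[a]) * (x[b] - x[a]))
        idx <- idx[-length(idx)] else break
    }
    idx <- c(idx, i)
  }
  approx(x[idx], y[idx], xout = x)$y
}

#' Baseline correction
#'
#' `"rubberband"` subtracts the greatest convex minorant of each spectrum
#' (corrected minimum is 0 to within 1e-9 at the hull contact points);
#' `"als"` subtracts an asymmetric-least-squares baseline (Eilers-style,
#' second-difference penalty `lambda`, asymmetry `p`).
#'
#' @param series An `"ftir_series"`.
#' @param method `"rubberband"` or `"als"`.
#' @param lambda,p,maxit ALS parameters.
#' @return The baseline-corrected series.
#' @export
baseline_correct <- function(series, method = c("rubberband", "als"),
                             lambda = 1e5, p = 0.01, maxit = 10) {
  stopifnot(inherits(series, "ftir_series"))
  method <- match.arg(method)
  if (length(series$wavenumbers) < 8)
    stopf("need at least 8 points per spectrum")
  asc <- order(series$wavenumbers)       # work on ascending axis
  Y <- series$spectra[, asc, drop = FALSE]
  x <- series$wavenumbers[asc]
  corr <- Y
  for (i in seq_len(nrow(Y))) {
    base <- switch(method,
      rubberband = lower_hull(x, Y[i, ]),
      als = als_baseline(Y[i, ], lambda = lambda, p = p, maxit = maxit))
    corr[i, ] <- Y[i, ] - base
  }
  out <- series
  out$spectra[, asc] <- corr
  out
}

als_baseline <- function(y, lambda = 1e5, p = 0.01, maxit = 10) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(maxit)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Split a series into functional-group and fingerprint regions
#'
#' Closed-interval views: functional group 4000--2800 cm^-1 and
#' fingerprint 1800--800 cm^-1 by default (bounds configurable).
#'
#' @param series An `"ftir_series"`.
#' @param regions Named list of `c(lo, hi)` wavenumber bounds.
#' @return Named list of `"ftir_series"` restricted to each region.
#' @export
split_regions <- function(series,
                          regions = list(functional_group = c(2800, 4000),
                                         fingerprint = c(800, 1800))) {
  stopifnot(inherits(series, "ftir_series"))
  out <- list()
  for (nm in names(regions)) {
    b <- sort(regions[[nm]])
    keep <- series$wavenumbers >= b[1] & series$wavenumbers <= b[2]
    if (!any(keep))
      stopf("region '%s' [%.0f, %.0f] contains no points", nm, b[1], b[2])
    out[[nm]] <- ftir_series(series$wavenumbers[keep],
                             series$spectra[, keep, drop = FALSE],
                             mode = series$mode, levels = series$levels,
                             tissue = series$tissue)
  }
  out
}
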