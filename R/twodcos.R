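#' Dynamic spectra for 2D correlation analysis
#'
#' Subtracts a reference spectrum from every perturbation level.  With the
#' default mean reference, column sums of the result are zero.
#'
#' @param series An `"ftir_series"` with >= 2 levels.
#' @param reference `"mean"`, `"first"`, or a numeric spectrum of matching
#'   length.
#' @return Matrix of dynamic spectra (levels x wavenumbers) with the
#'   wavenumber grid in `attr(, "wavenumbers")`.
#' @export
dynamic_spectra <- function(series, reference = "mean") {
  stopifnot(inherits(series, "ftir_series"))
  Y <- series$spectra
  if (nrow(Y) < 2) stopf("need at least 2 perturbation levels")
  ref <- if (is.numeric(reference)) {
    if (length(reference) != ncol(Y))
      stopf("custom reference has length %d, expected %d", length(reference),
            ncol(Y))
    reference
  } else switch(match.arg(reference, c("mean", "first")),
                mean = colMeans(Y), first = Y[1, ])
  out <- sweep(Y, 2, ref)
  attr(out, "wavenumbers") <- series$wavenumbers
  out
}

# Hilbert-Noda transformation matrix: N[j,k] = 0 if j == k else 1/(pi (k-j))
hilbert_noda <- function(m) {
  jk <- outer(seq_len(m), seq_len(m), function(j, k) k - j)
  N <- 1 / (pi * jk)
  N[jk == 0] <- 0
  N
}

#' Synchronous and asynchronous 2D correlation maps
#'
#' For dynamic spectra `Ytil` over `m` perturbation levels,
#' `Phi = t(Ytil) Ytil / (m - 1)` (synchronous) and
#' `Psi = t(Ytil) N Ytil / (m - 1)` (asynchronous), with `N` the
#' Hilbert--Noda matrix.  `Phi` is symmetric positive semidefinite; `Psi`
#' is antisymmetric with zero diagonal.
#'
#' @param Ytil Dynamic spectra from [dynamic_spectra()].
#' @return Wavenumber x wavenumber matrix carrying
#'   `attr(, "wavenumbers")`.
#' @export
synchronous_map <- function(Ytil) {
  m <- nrow(Ytil)
  if (is.null(m) || m < 2) stopf("need at least 2 perturbation levels")
  out <- crossprod(Ytil) / (m - 1)
  attr(out, "wavenumbers") <- attr(Ytil, "wavenumbers")
  out
}

#' @rdname synchronous_map
#' @export
asynchronous_map <- function(Ytil) {
  m <- nrow(Ytil)
  if (is.null(m) || m < 2) stopf("need at least 2 perturbation levels")
  out <- t(Ytil) %*% (hilbert_noda(m) %*% Ytil) / (m - 1)
  out <- (out - t(out)) / 2            # enforce exact antisymmetry
  attr(out, "wavenumbers") <- attr(Ytil, "wavenumbers")
  out
}

#' Run the full 2DCOS analysis
#'
#' Convenience wrapper: dynamic spectra, synchronous/asynchronous maps,
#' auto-peaks, and the cross-peak sign table.
#'
#' @param series An `"ftir_series"`.
#' @param reference Passed to [dynamic_spectra()].
#' @param prominence Passed to [find_auto_peaks()].
#' @return A list of class `"twodcos"` with `sync`, `async`,
#'   `auto_peaks`, `cross_peaks`, `wavenumbers`, `reference`, and the
#'   number of levels `m` (flagged low-rank when `m = 3`).
#' @export
twodcos <- function(series, reference = "mean", prominence = 0) {
  Ytil <- dynamic_spectra(series, reference)
  sync <- synchronous_map(Ytil)
  async <- asynchronous_map(Ytil)
  peaks <- find_auto_peaks(sync, prominence = prominence)
  cross <- NULL
  if (nrow(peaks) >= 2) {
    pr <- utils::combn(seq_len(nrow(peaks)), 2)
    idx <- match(peaks$wavenumber, series$wavenumbers)
    cross <- data.frame(
      nu1 = peaks$wavenumber[pr[1, ]], nu2 = peaks$wavenumber[pr[2, ]],
      phi = sync[cbind(idx[pr[1, ]], idx[pr[2, ]])],
      psi = async[cbind(idx[pr[1, ]], idx[pr[2, ]])])
    cross$sign_phi <- sign(cross$phi)
    cross$sign_psi <- sign(cross$psi)
  }
  structure(list(sync = sync, async = async, auto_peaks = peaks,
                 cross_peaks = cross, wavenumbers = series$wavenumbers,
                 reference = reference, m = nrow(series$spectra),
                 low_rank = nrow(series$spectra) == 3),
            class = "twodcos")
}

#' @export
print.twodcos <- function(x, ...) {
  cat(sprintf("2DCOS result: %d wavenumbers, m = %d levels%s\n",
              length(x$wavenumbers), x$m,
              if (x$low_rank) " [low-rank (m=3): interpret async with care]"
              else ""))
  cat(sprintf("  %d auto-peak(s)\n", nrow(x$auto_peaks)))
  invisible(x)
}

#' Auto-peaks of a synchronous map
#'
#' Strict local maxima of the diagonal of `Phi` whose value exceeds
#' `prominence`, ordered by decreasing intensity.
#'
#' @param Phi A synchronous map from [synchronous_map()].
#' @param prominence Minimum diagonal intensity (>= 0).
#' @return Data frame with `wavenumber`, `index`, `intensity`.
#' @export
find_auto_peaks <- function(Phi, prominence = 0) {
  stopifnot(prominence >= 0)
  d <- diag(as.matrix(Phi))
  wn <- attr(Phi, "wavenumbers")
  if (is.null(wn)) wn <- seq_along(d)
  n <- length(d)
  is_peak <- rep(FALSE, n)
  if (n >= 3)
    is_peak[2:(n - 1)] <- d[2:(n - 1)] > d[1:(n - 2)] &
                          d[2:(n - 1)] > d[3:n]
  is_peak <- is_peak & d > prominence
  out <- data.frame(wavenumber = wn[is_peak], index = which(is_peak),
                    intensity = d[is_peak])
  out[order(-out$intensity), , drop = FALSE]
}

#' Sequence band responses by Noda's rules
#'
#' For each band pair (nu1, nu2), reads the synchronous and asynchronous
#' cross-peak signs: `Phi > 0 & Psi > 0` means nu1 responds before nu2;
#' `Phi > 0 & Psi < 0` the reverse; a negative `Phi` inverts the
#' conclusion; `|Psi|` below `tol` means simultaneous.  Pairwise
#' conclusions are aggregated into a partial order; a total order is
#' reported when one exists, cyclic conclusions are flagged inconsistent
#' (never silently linearised).
#'
#' @param Phi,Psi Maps from [synchronous_map()] / [asynchronous_map()].
#' @param bands Wavenumbers of the bands to sequence (matched to the
#'   nearest grid point).
#' @param tol Absolute asynchronous intensity below which a pair counts as
#'   simultaneous (default `1e-8`).
#' @return A list of class `"noda_order"`: `pairs` (rule trace), `order`
#'   (band wavenumbers first-to-last, or NULL), `consistent`,
#'   `rendering` (arrow notation, e.g. `"3356 -> 2910"`).
#' @export
noda_ordering <- function(Phi, Psi, bands, tol = 1e-8) {
  wn <- attr(Phi, "wavenumbers")
  if (is.null(wn)) wn <- seq_len(nrow(Phi))
  idx <- vapply(bands, function(b) which.min(abs(wn - b)), 0L)
  nb <- length(bands)
  if (nb < 2) stopf("need at least 2 bands to sequence")
  pairs <- NULL
  prec <- matrix(FALSE, nb, nb)    # prec[i,j]: band i before band j
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    phi <- Phi[idx[i], idx[j]]
    psi <- Psi[idx[i], idx[j]]
    if (abs(psi) <= tol) {
      rel <- "simultaneous"
      rule <- "Psi ~ 0"
    } else if ((phi > 0) == (psi > 0)) {
      rel <- "before"; prec[i, j] <- TRUE
      rule <- sprintf("Phi %s 0, Psi %s 0", if (phi > 0) ">" else "<",
                      if (psi > 0) ">" else "<")
    } else {
      rel <- "after"; prec[j, i] <- TRUE
      rule <- sprintf("Phi %s 0, Psi %s 0", if (phi > 0) ">" else "<",
                      if (psi > 0) ">" else "<")
    }
    pairs <- rbind(pairs, data.frame(nu1 = bands[i], nu2 = bands[j],
                                     phi = phi, psi = psi, relation = rel,
                                     rule = rule))
  }
  # Kahn topological sort over the precedence relation
  remaining <- seq_len(nb)
  order_idx <- integer(0)
  consistent <- TRUE
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(j)
      !any(prec[remaining, j]), TRUE)]
    if (length(free) == 0L) { consistent <- FALSE; break }
    nxt <- free[1]
    order_idx <- c(order_idx, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  all_simultaneous <- all(pairs$relation == "simultaneous")
  ord <- if (!consistent) NULL else bands[order_idx]
  rendering <- if (!consistent) "inconsistent"
    else if (all_simultaneous) "simultaneous"
    else paste(format(ord, trim = TRUE), collapse = " → ")
  structure(list(pairs = pairs, order = ord, consistent = consistent,
                 rendering = rendering),
            class = "noda_order")
}

#' @export
print.noda_order <- function(x, ...) {
  cat("Noda sequence:", x$rendering, "\n")
  invisible(x)
}
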