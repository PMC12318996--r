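#' Principal component analysis of spectra
#'
#' Column-mean centring (optionally unit-variance scaling) followed by the
#' covariance eigendecomposition, via [stats::prcomp()].  A deterministic
#' sign convention is applied: the largest-magnitude entry of each loading
#' is made positive, for reproducible score plots.  Requesting more
#' components than the data's rank truncates to the rank and records a
#' warning.
#'
#' @param x A `"labeled_spectra"` or a samples x bands matrix.
#' @param k Number of components to keep (default 3).
#' @param scale Unit-variance scaling flag (default `FALSE`: reflectance
#'   spectra share a scale).
#' @return A list of class `"spectral_pca"`: `scores` (samples x k),
#'   `loadings` (bands x k, orthonormal columns), `explained_ratio`,
#'   `cumulative_ratio`, `center`, `scale`, `rank`, `warnings`.
#' @export
spectral_pca <- function(x, k = 3, scale = FALSE) {
  X <- if (inherits(x, "labeled_spectra")) x$X else as.matrix(x)
  if (nrow(X) < 2) stopf("need at least 2 samples")
  if (k < 1) stopf("k must be >= 1")
  total_var <- sum(apply(X, 2, var))
  if (total_var <= .Machine$double.eps)
    stopf("degenerate data: zero total variance")
  pc <- prcomp(X, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  warnings <- character(0)
  if (k > rank) {
    warnings <- sprintf("requested %d components, data rank is %d; truncated",
                        k, rank)
    k <- rank
  }
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                       # sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ratio <- ev[seq_len(k)] / sum(ev)
  structure(list(scores = scores, loadings = loadings,
                 explained_ratio = ratio,
                 cumulative_ratio = cumsum(ratio),
                 center = pc$center,
                 scale = if (scale) pc$scale else NULL,
                 rank = rank, warnings = warnings,
                 wavelengths = if (inherits(x, "labeled_spectra"))
                   x$wavelengths else NULL),
            class = "spectral_pca")
}

#' @export
print.spectral_pca <- function(x, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("Spectral PCA: %d component(s), rank %d\n", k, x$rank))
  cat("  explained:", paste(sprintf("%.1f%%", 100 * x$explained_ratio),
                            collapse = " "),
      sprintf(" (cumulative %.1f%%)\n", 100 * x$cumulative_ratio[k]))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Project new spectra onto fitted components
#'
#' @param object A `"spectral_pca"`.
#' @param newdata A `"labeled_spectra"` or matrix with matching bands.
#' @param ... Unused.
#' @return Scores matrix (samples x k).
#' @export
predict.spectral_pca <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_spectra")) newdata$X
       else as.matrix(newdata)
  if (ncol(X) != length(object$center))
    stopf("newdata has %d bands, model expects %d", ncol(X),
          length(object$center))
  X <- sweep(X, 2, object$center)
  if (!is.null(object$scale)) X <- sweep(X, 2, object$scale, "/")
  X %*% object$loadings
}

#' @export
plot.spectral_pca <- function(x, comps = c(1, 2), col = NULL, ...) {
  plot(x$scores[, comps[1]], x$scores[, comps[2]],
       xlab = sprintf("PC%d (%.1f%%)", comps[1],
                      100 * x$explained_ratio[comps[1]]),
       ylab = sprintf("PC%d (%.1f%%)", comps[2],
                      100 * x$explained_ratio[comps[2]]),
       col = if (is.null(col)) 1 else col, ...)
  invisible(x)
}
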