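#' Shapley-value attribution of band contributions
#'
#' Attributes a model's per-class scores to input bands (or contiguous
#' band groups) with interventional Shapley values: a coalition's value is
#' the model output with coalition features taken from the explained
#' sample and the rest replaced by background rows, averaged over the
#' background set.  `mode = "exact"` enumerates all `2^d` coalitions
#' (allowed for d <= 15 features/groups); `mode = "sampling"` uses seeded
#' permutation sampling.
#'
#' @param f Score function: takes a samples x bands matrix, returns a
#'   numeric vector or a samples x classes matrix (e.g.
#'   `function(X) predict(fit, X, type = "prob")`).
#' @param X Samples to explain (matrix or `"labeled_spectra"`).
#' @param background Background/reference rows (matrix); defaults to 100
#'   seeded draws from `X`.
#' @param mode `"auto"` (exact when d <= 15), `"exact"`, or `"sampling"`.
#' @param n_samples Permutations per explained sample in sampling mode.
#' @param groups Optional list of band-index vectors; attribution is then
#'   per group.  `band_groups(n_bands, k)` builds contiguous groups.
#' @param seed Integer seed (background draw and permutation sampling).
#' @return A list of class `"attribution_result"`: `shap_values`
#'   (samples x features x classes), `base_values` (per-class expected
#'   output over the background), `fx` (model output per sample),
#'   `feature_names`, `groups`, `mode`, `background_spec`, `seed`.
#' @export
shapley_attribute <- function(f, X, background = NULL,
                              mode = c("auto", "exact", "sampling"),
                              n_samples = 200, groups = NULL, seed = 1L) {
  mode <- match.arg(mode)
  X <- if (inherits(X, "labeled_spectra")) X$X else as.matrix(X)
  p <- ncol(X)
  bg_spec <- "user-supplied background matrix"
  if (is.null(background)) {
    background <- with_seed(seed, X[sample.int(nrow(X),
                                               min(100, nrow(X))), ,
                                    drop = FALSE])
    bg_spec <- sprintf("%d seeded draws from the explained set",
                       nrow(background))
  }
  background <- as.matrix(background)
  if (nrow(background) == 0L) stopf("empty background set")
  if (ncol(background) != p) stopf("background band count mismatch")
  if (is.null(groups)) groups <- as.list(seq_len(p))
  d <- length(groups)
  if (mode == "auto") mode <- if (d <= 15) "exact" else "sampling"
  if (mode == "exact" && d > 15)
    stopf("exact mode limited to 15 features/groups (got %d); use groups or sampling", d)
  fmat <- function(M) {
    out <- f(M)
    if (is.null(dim(out))) out <- matrix(out, ncol = 1)
    as.matrix(out)
  }
  base <- colMeans(fmat(background))
  K <- length(base)
  n <- nrow(X)
  fx <- fmat(X)
  phi <- array(0, dim = c(n, d, K))
  if (mode == "exact") {
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
    # Shapley kernel weight |S|! (d-|S|-1)! / d!
    coal_weight <- function(s) exp(lgamma(s + 1) + lgamma(d - s) -
                                     lgamma(d + 1))
    for (i in seq_len(n)) {
      v <- matrix(0, nrow(masks), K)
      for (mi in seq_len(nrow(masks))) {
        keep <- unlist(groups[masks[mi, ]])
        Mb <- background
        if (length(keep)) Mb[, keep] <- rep(X[i, keep], each = nrow(Mb))
        v[mi, ] <- colMeans(fmat(Mb))
      }
      key <- apply(masks, 1, function(m) paste(as.integer(m),
                                               collapse = ""))
      vlookup <- function(m) v[match(paste(as.integer(m), collapse = ""),
                                     key), ]
      for (j in seq_len(d)) {
        without_j <- masks[!masks[, j], , drop = FALSE]
        for (r in seq_len(nrow(without_j))) {
          S <- without_j[r, ]
          Sj <- S; Sj[j] <- TRUE
          wgt <- coal_weight(sum(S))
          phi[i, j, ] <- phi[i, j, ] + wgt * (vlookup(Sj) - vlookup(S))
        }
      }
    }
  } else {
    with_seed(seed, {
      for (i in seq_len(n)) {
        acc <- matrix(0, d, K)
        for (s in seq_len(n_samples)) {
          perm <- sample.int(d)
          b <- background[sample.int(nrow(background), 1), ]
          cur <- b
          vprev <- fmat(matrix(cur, 1))
          for (j in perm) {
            cur[groups[[j]]] <- X[i, groups[[j]]]
            vnew <- fmat(matrix(cur, 1))
            acc[j, ] <- acc[j, ] + (vnew - vprev)
            vprev <- vnew
          }
        }
        phi[i, , ] <- acc / n_samples
      }
    })
  }
  feature_names <- if (d == p) as.character(seq_len(p))
    else vapply(groups, function(g) sprintf("g%d-%d", min(g), max(g)), "")
  structure(list(shap_values = phi, base_values = base, fx = fx,
                 feature_names = feature_names, groups = groups,
                 mode = mode, background_spec = bg_spec, seed = seed),
            class = "attribution_result")
}

#' Contiguous band groups for grouped attribution
#'
#' @param n_bands Total band count.
#' @param k Number of contiguous groups (default 16).
#' @return List of index vectors.
#' @export
band_groups <- function(n_bands, k = 16) {
  split(seq_len(n_bands), ceiling(seq_len(n_bands) / (n_bands / k)))
}

#' @export
print.attribution_result <- function(x, ...) {
  dm <- dim(x$shap_values)
  cat(sprintf("Shapley attribution (%s mode): %d sample(s) x %d feature(s) x %d class(es)\n",
              x$mode, dm[1], dm[2], dm[3]))
  cat("  background:", x$background_spec, "\n")
  invisible(x)
}

#' Global band importance
#'
#' Mean absolute attribution per feature, taken over samples at each
#' sample's predicted class, ranked in descending order.
#'
#' @param result An `"attribution_result"`.
#' @param top_k Rows to keep (default: all).
#' @return Data frame `feature`, `importance`, ordered by importance.
#' @export
global_importance <- function(result, top_k = NULL) {
  stopifnot(inherits(result, "attribution_result"))
  dm <- dim(result$shap_values)
  pred_class <- apply(result$fx, 1, which.max)
  imp <- vapply(seq_len(dm[2]), function(j)
    mean(abs(result$shap_values[cbind(seq_len(dm[1]), j, pred_class)])), 0)
  out <- data.frame(feature = result$feature_names, importance = imp)
  out <- out[order(-out$importance), , drop = FALSE]
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}

#' Per-class beeswarm-style attribution table
#'
#' Long-format table of attributions toward one class: one row per
#' (sample, feature), with the feature's value (the colour channel of a
#' beeswarm plot) and its signed attribution (positive = promotes the
#' class score, negative = inhibits).
#'
#' @param result An `"attribution_result"`.
#' @param class Class index (1-based) or label in `class_labels`.
#' @param X The explained samples (for the feature values); required when
#'   grouped attribution was used with `feature_value = "mean"`.
#' @param class_labels Optional class labels matching the model's output
#'   columns.
#' @return Data frame `sample`, `feature`, `value`, `attribution`.
#' @export
per_class_summary <- function(result, class, X = NULL,
                              class_labels = NULL) {
  stopifnot(inherits(result, "attribution_result"))
  dm <- dim(result$shap_values)
  k <- if (is.numeric(class)) as.integer(class)
       else match(as.character(class), class_labels)
  if (is.na(k) || k < 1 || k > dm[3])
    stopf("unknown class '%s'", as.character(class))
  vals <- NA_real_
  if (!is.null(X)) {
    X <- if (inherits(X, "labeled_spectra")) X$X else as.matrix(X)
    vals <- vapply(seq_len(dm[2]), function(j)
      rowMeans(X[, result$groups[[j]], drop = FALSE]),
      numeric(dm[1]))
  }
  out <- expand.grid(sample = seq_len(dm[1]), feature = seq_len(dm[2]))
  out$feature_name <- result$feature_names[out$feature]
  out$value <- if (is.null(X)) NA_real_ else vals[cbind(out$sample,
                                                        out$feature)]
  out$attribution <- result$shap_values[cbind(out$sample, out$feature,
                                              rep(k, nrow(out)))]
  out
}
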