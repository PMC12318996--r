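#' Partial least squares discriminant analysis
#'
#' One-hot encodes the class labels and fits a PLS2 regression by NIPALS
#' latent-variable extraction; prediction is the argmax of the fitted
#' responses (ties broken toward the lowest class index).  When `ncomp` is
#' `NULL` the component count is chosen by stratified 5-fold
#' cross-validated accuracy over `1..max_ncomp`.
#'
#' @param x A `"labeled_spectra"` (the `class_mg_l` labels are used) or a
#'   samples x bands matrix.
#' @param labels Class labels (required when `x` is a matrix).
#' @param ncomp Number of latent variables, or `NULL` for CV selection.
#' @param max_ncomp Upper bound for CV selection (default 10).
#' @param cv_seed Seed for the CV fold assignment.
#' @return A list of class `"plsda"` with the latent-variable fit
#'   (`weights`, `x_loadings`, `y_loadings`, `coefficients`), class
#'   encoding, centres, and `ncomp`.
#' @export
plsda <- function(x, labels = NULL, ncomp = NULL, max_ncomp = 10,
                  cv_seed = 1L) {
  X <- if (inherits(x, "labeled_spectra")) x$X else as.matrix(x)
  if (is.null(labels)) {
    if (!inherits(x, "labeled_spectra"))
      stopf("labels required when x is a matrix")
    labels <- x$class_mg_l
  }
  y <- factor(labels)
  if (nlevels(y) < 2) stopf("need at least 2 classes")
  if (is.null(ncomp)) {
    cand <- seq_len(min(max_ncomp, nrow(X) - 2, ncol(X)))
    acc <- vapply(cand, function(a)
      cv_accuracy_plsda(X, y, ncomp = a, folds = 5, seed = cv_seed), 0)
    ncomp <- cand[which.max(acc)]
  }
  ncomp <- min(ncomp, nrow(X) - 1, ncol(X))
  fit <- nipals_pls2(X, class_indicator(y), ncomp)
  structure(c(fit, list(classes = levels(y), ncomp = ncomp)),
            class = "plsda")
}

class_indicator <- function(y) {
  Y <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# NIPALS PLS2 on column-centred X and Y.
nipals_pls2 <- function(X, Y, ncomp, tol = 1e-10, maxit = 500) {
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xr <- sweep(X, 2, xbar); Yr <- sweep(Y, 2, ybar)
  p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, q, ncomp); Tm <- matrix(0, nrow(X), ncomp)
  for (a in seq_len(ncomp)) {
    u <- Yr[, which.max(apply(Yr, 2, var))]
    t_old <- rep(Inf, nrow(X))
    for (it in seq_len(maxit)) {
      w <- crossprod(Xr, u)
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) break
      w <- w / nw
      tt <- Xr %*% w
      cc <- crossprod(Yr, tt) / sum(tt^2)
      u <- Yr %*% cc / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pp <- crossprod(Xr, tt) / sum(tt^2)
    Xr <- Xr - tt %*% t(pp)
    Yr <- Yr - tt %*% t(cc)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- tt
  }
  B <- W %*% solve(crossprod(P, W), t(C))
  list(weights = W, x_loadings = P, y_loadings = C, scores = Tm,
       coefficients = B, x_center = xbar, y_center = ybar)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d latent variable(s), classes: %s\n", x$ncomp,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict classes or scores from a PLS-DA fit
#'
#' @param object A `"plsda"` fit.
#' @param newdata A `"labeled_spectra"` or matrix.
#' @param type `"class"` (default), `"response"` (fitted indicator
#'   responses), or `"prob"` (softmax of the responses, a calibrated-ish
#'   probability surrogate used for loss reporting).
#' @param ... Unused.
#' @return Factor of classes, or a numeric matrix.
#' @export
predict.plsda <- function(object, newdata, type = c("class", "response",
                                                    "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "labeled_spectra")) newdata$X
       else as.matrix(newdata)
  if (ncol(X) != length(object$x_center))
    stopf("newdata has %d bands, model expects %d", ncol(X),
          length(object$x_center))
  Yhat <- sweep(X, 2, object$x_center) %*% object$coefficients
  Yhat <- sweep(Yhat, 2, object$y_center, "+")
  colnames(Yhat) <- object$classes
  if (type == "response") return(Yhat)
  if (type == "prob") return(softmax(Yhat))
  # argmax with ties to the lowest class index
  factor(object$classes[apply(Yhat, 1, which.max)], levels = object$classes)
}

softmax <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

# Stratified k-fold CV accuracy of a PLS-DA with fixed ncomp.
cv_accuracy_plsda <- function(X, y, ncomp, folds = 5, seed = 1L) {
  y <- factor(y)
  fold_id <- with_seed(seed, stratified_folds(y, folds))
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (nlevels(droplevels(y[tr])) < 2) next
    fit <- plsda(X[tr, , drop = FALSE], y[tr],
                 ncomp = min(ncomp, sum(tr) - 1))
    pred <- predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  correct / length(y)
}

stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (lv in levels(y)) {
    i <- which(y == lv)
    id[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  id
}
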