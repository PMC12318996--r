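#' SE-LSTM configuration
#'
#' Settings for the squeeze-and-excitation LSTM classifier.  The spectrum of
#' length C is reshaped into C channels, reweighted by the SE block, then
#' fed band-by-band (low to high wavelength, one band value per time step)
#' through stacked LSTM layers; the final hidden state feeds a fully
#' connected softmax head over the concentration classes.
#'
#' @param n_layers Stacked LSTM layers (1, 2 or 3; default 2).
#' @param units Hidden units per layer (16/32/64/128 in the tuning grid;
#'   default 32).
#' @param reduction_ratio SE bottleneck ratio r (must divide the band
#'   count; default 16).
#' @param n_classes Output classes (default 3: 0/10/100 mg/L).
#' @param optimizer `"Adam"` (default), `"SGD"` or `"RMSprop"`.
#' @param learning_rate Default 0.01.
#' @param epochs Training epochs (default 200).
#' @param batch_size Minibatch size (default 32).
#' @param use_se `FALSE` gives the plain-LSTM baseline.
#' @param clip_norm Global gradient-norm clipping threshold (default 1;
#'   `Inf` disables).  Standard stabilisation for recurrent nets trained
#'   over long sequences.
#' @param standardize Z-score each band on the calibration set before the
#'   network (default `TRUE`; stored with the model and applied at
#'   prediction time).  Reflectance differences between stress classes are
#'   small fractions of the absolute level, so standardisation puts the
#'   discriminative signal on an O(1) scale at every time step.
#' @param seed Integer seed for initialisation and minibatch shuffling.
#' @return A list of class `"selstm_config"`.
#' @export
selstm_config <- function(n_layers = 2, units = 32, reduction_ratio = 16,
                          n_classes = 3,
                          optimizer = c("Adam", "SGD", "RMSprop"),
                          learning_rate = 0.01, epochs = 200,
                          batch_size = 32, use_se = TRUE, clip_norm = 1,
                          standardize = TRUE, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(n_layers >= 1, units >= 1, learning_rate >= 0, epochs >= 0,
            batch_size >= 1)
  structure(list(n_layers = as.integer(n_layers), units = as.integer(units),
                 reduction_ratio = as.integer(reduction_ratio),
                 n_classes = as.integer(n_classes), optimizer = optimizer,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), use_se = use_se,
                 clip_norm = clip_norm,
                 standardize = standardize, seed = as.integer(seed)),
            class = "selstm_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Squeeze-and-excitation block forward pass
#'
#' For a 1-D spectrum each channel holds a single value, so global average
#' pooling returns the spectrum itself: `z = x`;
#' `s = sigmoid(relu(z W1 + b1) W2 + b2)`; output `s * x` elementwise.
#' With all weights and biases zero, `s = 0.5` everywhere.
#'
#' @param params List with `W1` (C x C/r), `b1`, `W2` (C/r x C), `b2`.
#' @param x Spectrum vector (length C) or batch matrix (n x C).
#' @return Reweighted signal, same shape as `x`.
#' @export
se_block_forward <- function(params, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1) else as.matrix(x)
  if (ncol(X) != nrow(params$W1))
    stopf("SE block expects %d channels, got %d", nrow(params$W1), ncol(X))
  U <- sweep(X %*% params$W1, 2, params$b1, "+")
  Rl <- pmax(U, 0)
  S <- sigmoid(sweep(Rl %*% params$W2, 2, params$b2, "+"))
  out <- S * X
  if (vec) drop(out) else out
}

#' Single LSTM cell step
#'
#' The gate equations: `f = sigmoid(x W_fx + h W_fh + b_f)`, likewise for
#' the input gate `i` and output gate `o`; candidate
#' `g = tanh(x W_gx + h W_gh + b_g)`; `c_t = f * c_prev + i * g`;
#' `h_t = o * tanh(c_t)`.
#'
#' @param params List with input weights `W_fx`, `W_ix`, `W_ox`, `W_gx`
#'   (input_size x H), recurrent weights `W_fh`, `W_ih`, `W_oh`, `W_gh`
#'   (H x H), and biases `b_f`, `b_i`, `b_o`, `b_g` (length H).
#' @param x_t Input at time t: vector (input_size) or batch (n x
#'   input_size).
#' @param h_prev,c_prev Previous hidden and cell state, same batch shape.
#' @return List with `h` and `c`.
#' @export
lstm_cell_step <- function(params, x_t, h_prev, c_prev) {
  vec <- is.null(dim(x_t))
  X <- if (vec) matrix(x_t, 1) else as.matrix(x_t)
  H <- if (is.null(dim(h_prev))) matrix(h_prev, 1) else as.matrix(h_prev)
  C <- if (is.null(dim(c_prev))) matrix(c_prev, 1) else as.matrix(c_prev)
  if (!all(is.finite(X)) || !all(is.finite(H)) || !all(is.finite(C)))
    stopf("non-finite inputs to lstm_cell_step")
  f <- sigmoid(sweep(X %*% params$W_fx + H %*% params$W_fh, 2, params$b_f, "+"))
  i <- sigmoid(sweep(X %*% params$W_ix + H %*% params$W_ih, 2, params$b_i, "+"))
  o <- sigmoid(sweep(X %*% params$W_ox + H %*% params$W_oh, 2, params$b_o, "+"))
  g <- tanh(sweep(X %*% params$W_gx + H %*% params$W_gh, 2, params$b_g, "+"))
  c_t <- f * C + i * g
  h_t <- o * tanh(c_t)
  if (vec) list(h = drop(h_t), c = drop(c_t)) else list(h = h_t, c = c_t)
}

# ---- packed parameter representation used by training -----------------------
# Each layer holds Wx (d x 4H), Wh (H x 4H), b (4H), gate column order
# f, i, o, g.  The head holds Wy (H x K), by (K).

init_params <- function(C, config) {
  H <- config$units; L <- config$n_layers; K <- config$n_classes
  r <- config$reduction_ratio
  pr <- list()
  if (config$use_se) {
    if (C %% r != 0)
      stopf("reduction ratio %d does not divide the band count %d", r, C)
    m <- C %/% r
    pr$se <- list(W1 = matrix(runif(C * m, -0.1, 0.1), C, m),
                  b1 = rep(0, m),
                  W2 = matrix(runif(m * C, -0.1, 0.1), m, C),
                  b2 = rep(0, C))
  }
  pr$layers <- vector("list", L)
  for (l in seq_len(L)) {
    d <- if (l == 1) 1L else H
    sc <- 1 / sqrt(H)
    b <- rep(0, 4 * H)
    b[seq_len(H)] <- 1                      # forget-gate bias 1: long memory
    pr$layers[[l]] <- list(
      Wx = matrix(runif(d * 4 * H, -sc, sc), d, 4 * H),
      Wh = matrix(runif(H * 4 * H, -sc, sc), H, 4 * H),
      b = b)
  }
  pr$head <- list(Wy = matrix(runif(H * K, -0.1, 0.1), H, K), by = rep(0, K))
  pr
}

# Forward pass over a batch; returns probabilities and (optionally) the
# caches needed for backpropagation through time.
selstm_fwd <- function(pr, X, config, keep_cache = FALSE) {
  n <- nrow(X); C <- ncol(X)
  H <- config$units; L <- config$n_layers
  cache <- list()
  if (config$use_se) {
    se <- pr$se
    U <- sweep(X %*% se$W1, 2, se$b1, "+")
    Rl <- pmax(U, 0)
    S <- sigmoid(sweep(Rl %*% se$W2, 2, se$b2, "+"))
    Xw <- S * X
    if (keep_cache) cache$se <- list(U = U, Rl = Rl, S = S, X = X)
  } else Xw <- X
  hs <- lapply(seq_len(L), function(l) matrix(0, n, H))
  cs <- lapply(seq_len(L), function(l) matrix(0, n, H))
  steps <- if (keep_cache) vector("list", C) else NULL
  for (t in seq_len(C)) {
    xin <- Xw[, t, drop = FALSE]
    st <- if (keep_cache) vector("list", L) else NULL
    for (l in seq_len(L)) {
      ly <- pr$layers[[l]]
      A <- sweep(xin %*% ly$Wx + hs[[l]] %*% ly$Wh, 2, ly$b, "+")
      f <- sigmoid(A[, 1:H, drop = FALSE])
      i <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
      o <- sigmoid(A[, (2 * H + 1):(3 * H), drop = FALSE])
      g <- tanh(A[, (3 * H + 1):(4 * H), drop = FALSE])
      c_new <- f * cs[[l]] + i * g
      tc <- tanh(c_new)
      h_new <- o * tc
      if (keep_cache)
        st[[l]] <- list(xin = xin, h_prev = hs[[l]], c_prev = cs[[l]],
                        f = f, i = i, o = o, g = g, tc = tc)
      hs[[l]] <- h_new; cs[[l]] <- c_new
      xin <- h_new
    }
    if (keep_cache) steps[[t]] <- st
  }
  logits <- sweep(hs[[L]] %*% pr$head$Wy, 2, pr$head$by, "+")
  probs <- softmax(logits)
  list(probs = probs, h_last = hs[[L]],
       cache = if (keep_cache) c(cache, list(steps = steps, Xw = Xw)) else NULL)
}

# Backward pass; returns gradients with the same structure as `pr`.
selstm_bwd <- function(pr, fwd, Y1hot, config) {
  n <- nrow(Y1hot); C <- length(fwd$cache$steps)
  H <- config$units; L <- config$n_layers
  gr <- list(layers = vector("list", L))
  for (l in seq_len(L)) {
    ly <- pr$layers[[l]]
    gr$layers[[l]] <- list(Wx = ly$Wx * 0, Wh = ly$Wh * 0, b = ly$b * 0)
  }
  dlogits <- (fwd$probs - Y1hot) / n
  gr$head <- list(Wy = crossprod(fwd$h_last, dlogits),
                  by = colSums(dlogits))
  dh_next <- lapply(seq_len(L), function(l) matrix(0, n, H))
  dc_next <- lapply(seq_len(L), function(l) matrix(0, n, H))
  dh_next[[L]] <- dlogits %*% t(pr$head$Wy)
  dXw <- matrix(0, n, C)
  for (t in rev(seq_len(C))) {
    dx_above <- NULL
    for (l in rev(seq_len(L))) {
      st <- fwd$cache$steps[[t]][[l]]
      dh <- dh_next[[l]]
      if (!is.null(dx_above)) dh <- dh + dx_above
      do_ <- dh * st$tc
      dc <- dh * st$o * (1 - st$tc^2) + dc_next[[l]]
      df <- dc * st$c_prev
      di <- dc * st$g
      dg <- dc * st$i
      dc_next[[l]] <- dc * st$f
      dA <- cbind(df * st$f * (1 - st$f),
                  di * st$i * (1 - st$i),
                  do_ * st$o * (1 - st$o),
                  dg * (1 - st$g^2))
      ly <- pr$layers[[l]]
      gr$layers[[l]]$Wx <- gr$layers[[l]]$Wx + crossprod(st$xin, dA)
      gr$layers[[l]]$Wh <- gr$layers[[l]]$Wh + crossprod(st$h_prev, dA)
      gr$layers[[l]]$b <- gr$layers[[l]]$b + colSums(dA)
      dh_next[[l]] <- dA %*% t(ly$Wh)
      dxin <- dA %*% t(ly$Wx)
      if (l > 1) dx_above <- dxin else dXw[, t] <- dxin
    }
  }
  if (config$use_se) {
    sc <- fwd$cache$se
    se <- pr$se
    dS <- dXw * sc$X
    dV <- dS * sc$S * (1 - sc$S)
    dRl <- dV %*% t(se$W2)
    dU <- dRl * (sc$U > 0)
    gr$se <- list(W1 = crossprod(sc$X, dU), b1 = colSums(dU),
                  W2 = crossprod(sc$Rl, dV), b2 = colSums(dV))
  }
  gr
}

# Apply `fun(weight, gradient, key)` to every parameter tensor, preserving
# the nested structure; `key` is a unique string for optimizer state.
walk_params <- function(pr, gr, fun) {
  out <- pr
  if (!is.null(pr$se))
    for (nm in names(pr$se))
      out$se[[nm]] <- fun(pr$se[[nm]], gr$se[[nm]], paste0("se.", nm))
  for (l in seq_along(pr$layers))
    for (nm in names(pr$layers[[l]]))
      out$layers[[l]][[nm]] <- fun(pr$layers[[l]][[nm]],
                                   gr$layers[[l]][[nm]],
                                   paste0("layers", l, ".", nm))
  for (nm in names(pr$head))
    out$head[[nm]] <- fun(pr$head[[nm]], gr$head[[nm]], paste0("head.", nm))
  out
}

clip_gradients <- function(gr, clip_norm) {
  if (!is.finite(clip_norm)) return(gr)
  ss <- 0
  acc <- function(g) ss <<- ss + sum(g^2)
  if (!is.null(gr$se)) lapply(gr$se, acc)
  lapply(gr$layers, function(l) lapply(l, acc))
  lapply(gr$head, acc)
  nrm <- sqrt(ss)
  if (nrm <= clip_norm) return(gr)
  walk_params(gr, gr, function(g, ., key) g * (clip_norm / nrm))
}

make_optimizer <- function(config) {
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  lr <- config$learning_rate
  switch(config$optimizer,
    SGD = function(pr, gr) walk_params(pr, gr, function(w, g, key) w - lr * g),
    RMSprop = function(pr, gr) {
      walk_params(pr, gr, function(w, g, key) {
        v <- if (is.null(state[[key]])) g * 0 else state[[key]]
        v <- 0.9 * v + 0.1 * g^2
        state[[key]] <- v
        w - lr * g / (sqrt(v) + 1e-8)
      })
    },
    Adam = function(pr, gr) {
      state$t <- state$t + 1L
      b1 <- 0.9; b2 <- 0.999
      walk_params(pr, gr, function(w, g, key) {
        mk <- paste0("m.", key); vk <- paste0("v.", key)
        m <- if (is.null(state[[mk]])) g * 0 else state[[mk]]
        v <- if (is.null(state[[vk]])) g * 0 else state[[vk]]
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        state[[mk]] <- m; state[[vk]] <- v
        mhat <- m / (1 - b1^state$t)
        vhat <- v / (1 - b2^state$t)
        w - lr * mhat / (sqrt(vhat) + 1e-8)
      })
    })
}

cross_entropy <- function(probs, y_int) {
  p <- probs[cbind(seq_along(y_int), y_int)]
  -mean(log(pmax(p, 1e-12)))
}

#' Stratified calibration/prediction split
#'
#' @param labels Class labels.
#' @param frac Calibration fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with integer vectors `calibration` and `prediction`.
#' @export
stratified_split <- function(labels, frac = 0.7, seed = 1L) {
  y <- factor(labels)
  with_seed(seed, {
    cal <- integer(0)
    for (lv in levels(y)) {
      i <- which(y == lv)
      cal <- c(cal, sample(i, max(1L, round(frac * length(i)))))
    }
    cal <- sort(cal)
    list(calibration = cal,
         prediction = setdiff(seq_along(y), cal))
  })
}

#' Fit the SE-LSTM concentration classifier
#'
#' Trains by minibatch backpropagation through time, minimising mean
#' cross-entropy with the configured optimizer.  All randomness
#' (initialisation, split, shuffling) is derived from `config$seed`, so
#' identical configurations reproduce identical fits.
#'
#' @param x A `"labeled_spectra"` (classes taken from `class_mg_l`) or a
#'   samples x bands matrix.
#' @param labels Class labels when `x` is a matrix.
#' @param config A [selstm_config()].
#' @param split Either a calibration fraction (default 0.7, stratified) or
#'   a list with `calibration`/`prediction` index vectors.
#' @return A list of class `"selstm"`: `params`, `config`, `classes`,
#'   `loss_curve` (per-epoch mean training loss), `report` (an
#'   `"eval_report"` on the calibration and prediction sets), `split`.
#' @export
selstm <- function(x, labels = NULL, config = selstm_config(), split = 0.7) {
  X <- if (inherits(x, "labeled_spectra")) x$X else as.matrix(x)
  if (is.null(labels)) {
    if (!inherits(x, "labeled_spectra"))
      stopf("labels required when x is a matrix")
    labels <- x$class_mg_l
  }
  y <- factor(labels)
  if (is.numeric(split))
    split <- stratified_split(y, frac = split, seed = config$seed)
  y_cal <- droplevels(y[split$calibration])
  if (nlevels(y_cal) < 2) stopf("calibration split has fewer than 2 classes")
  if (nlevels(y) > config$n_classes)
    stopf("%d classes present but n_classes = %d", nlevels(y),
          config$n_classes)
  x_center <- rep(0, ncol(X)); x_scale <- rep(1, ncol(X))
  if (isTRUE(config$standardize)) {
    Xcal <- X[split$calibration, , drop = FALSE]
    x_center <- colMeans(Xcal)
    x_scale <- pmax(apply(Xcal, 2, sd), 1e-8)
    X <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  }
  Xc <- X[split$calibration, , drop = FALSE]
  yc <- as.integer(y[split$calibration])
  n <- nrow(Xc); C <- ncol(X)
  Y1 <- matrix(0, n, config$n_classes)
  Y1[cbind(seq_len(n), yc)] <- 1
  loss_curve <- numeric(config$epochs)
  pr <- with_seed(config$seed, {
    pr <- init_params(C, config)
    step <- make_optimizer(config)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        fwd <- selstm_fwd(pr, Xc[b, , drop = FALSE], config,
                          keep_cache = TRUE)
        loss <- cross_entropy(fwd$probs, yc[b])
        if (!is.finite(loss))
          stopf("training diverged (non-finite loss) at epoch %d", ep)
        ep_loss <- ep_loss + loss * length(b)
        gr <- selstm_bwd(pr, fwd, Y1[b, , drop = FALSE], config)
        gr <- clip_gradients(gr, config$clip_norm)
        pr <- step(pr, gr)
      }
      loss_curve[ep] <- ep_loss / n
    }
    pr
  })
  model <- structure(list(params = pr, config = config, classes = levels(y),
                          n_bands = C, split = split, loss_curve = loss_curve,
                          x_center = x_center, x_scale = x_scale),
                     class = "selstm")
  # X is already standardised here; undo for the report's predict path
  raw <- function(M) sweep(sweep(M, 2, x_scale, "*"), 2, x_center, "+")
  model$report <- evaluate_model(model,
                                 list(X = raw(Xc), y = y[split$calibration]),
                                 list(X = raw(X[split$prediction, ,
                                                drop = FALSE]),
                                      y = y[split$prediction]))
  model
}

#' @export
print.selstm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s: %d layer(s) x %d units, %d bands -> %d classes\n",
              if (cfg$use_se) "SE-LSTM" else "LSTM", cfg$n_layers, cfg$units,
              x$n_bands, cfg$n_classes))
  cat(sprintf("  %s, lr %.3g, %d epochs (final training loss %.4f)\n",
              cfg$optimizer, cfg$learning_rate, cfg$epochs,
              tail(x$loss_curve, 1)))
  if (!is.null(x$report))
    cat(sprintf("  calibration %.2f%% / prediction %.2f%% (overfit %.2f pp)\n",
                x$report$accuracy_calibration, x$report$accuracy_prediction,
                x$report$overfit_coefficient))
  invisible(x)
}

#' @export
summary.selstm <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %d\n", n_params_selstm(object$config,
                                                    object$n_bands)))
  invisible(object$report)
}

#' @export
coef.selstm <- function(object, ...) object$params

#' @export
plot.selstm <- function(x, ...) {
  plot(seq_along(x$loss_curve), x$loss_curve, type = "l",
       xlab = "epoch", ylab = "mean cross-entropy", ...)
  invisible(x)
}

#' Predict from a fitted SE-LSTM
#'
#' @param object A `"selstm"` fit.
#' @param newdata A `"labeled_spectra"` or matrix with the training band
#'   count.
#' @param type `"class"` (default) or `"prob"` (softmax probabilities;
#'   rows sum to 1).
#' @param ... Unused.
#' @return Factor of classes or a probability matrix.
#' @export
predict.selstm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "labeled_spectra")) newdata$X
       else as.matrix(newdata)
  if (ncol(X) != object$n_bands)
    stopf("newdata has %d bands, model expects %d", ncol(X), object$n_bands)
  if (isTRUE(object$config$standardize))
    X <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  probs <- selstm_fwd(object$params, X, object$config)$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[apply(probs, 1, which.max)], levels = object$classes)
}

n_params_selstm <- function(config, C) {
  H <- config$units; total <- 0
  if (config$use_se) {
    m <- C %/% config$reduction_ratio
    total <- total + C * m + m + m * C + C
  }
  for (l in seq_len(config$n_layers)) {
    d <- if (l == 1) 1 else H
    total <- total + d * 4 * H + H * 4 * H + 4 * H
  }
  total + H * config$n_classes + config$n_classes
}

#' Evaluate a classifier on calibration and prediction sets
#'
#' Accuracy is percent correct argmax; loss is mean cross-entropy of the
#' predicted probabilities; the overfitting coefficient is the
#' calibration-minus-prediction accuracy gap in percentage points.
#'
#' @param model A fitted `"selstm"` or `"plsda"` (anything with a
#'   probability-producing `predict` method).
#' @param calibration,prediction Lists with `X` (matrix or
#'   `"labeled_spectra"`) and `y` labels.
#' @return A list of class `"eval_report"`.
#' @export
evaluate_model <- function(model, calibration, prediction) {
  part <- function(set) {
    X <- if (inherits(set$X, "labeled_spectra")) set$X$X else as.matrix(set$X)
    if (nrow(X) == 0L) stopf("empty evaluation set")
    y <- as.character(set$y)
    classes <- if (inherits(model, "selstm")) model$classes
               else model$classes
    if (!all(y %in% classes))
      stopf("label outside model classes: %s",
            paste(setdiff(unique(y), classes), collapse = ", "))
    probs <- if (inherits(model, "plsda"))
      predict(model, X, type = "prob") else predict(model, X, type = "prob")
    pred <- classes[apply(probs, 1, which.max)]
    list(acc = 100 * mean(pred == y),
         loss = cross_entropy(probs, match(y, classes)))
  }
  cal <- part(calibration); pred <- part(prediction)
  structure(list(accuracy_calibration = cal$acc,
                 accuracy_prediction = pred$acc,
                 loss_calibration = cal$loss,
                 loss_prediction = pred$loss,
                 overfit_coefficient = cal$acc - pred$acc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("calibration: %.2f%% (loss %.4f) | prediction: %.2f%% ",
                     "(loss %.4f) | overfit %.2f pp\n"),
              x$accuracy_calibration, x$loss_calibration,
              x$accuracy_prediction, x$loss_prediction,
              x$overfit_coefficient))
  invisible(x)
}

#' Architecture grid search
#'
#' One seeded training run per (layers, units) cell; rows ranked by
#' prediction accuracy with ties broken toward fewer parameters.  Failed
#' cells are recorded (`error` column), not fatal.
#'
#' @param x,labels Training data as in [selstm()].
#' @param layers,units Grid axes (defaults 1:3 and 16/32/64/128).
#' @param config Base configuration (optimizer, learning rate, epochs...).
#' @param split Passed to [selstm()].
#' @return Data frame, one ranked row per grid cell.
#' @export
grid_search_architecture <- function(x, labels = NULL, layers = 1:3,
                                     units = c(16, 32, 64, 128),
                                     config = selstm_config(),
                                     split = 0.7) {
  grid <- expand.grid(n_layers = layers, units = units)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$n_layers <- as.integer(grid$n_layers[i])
    cfg$units <- as.integer(grid$units[i])
    cell <- data.frame(n_layers = cfg$n_layers, units = cfg$units,
                       n_params = NA, accuracy_calibration = NA,
                       accuracy_prediction = NA, loss_calibration = NA,
                       loss_prediction = NA, overfit_coefficient = NA,
                       error = NA_character_)
    tryCatch({
      fit <- selstm(x, labels, config = cfg, split = split)
      r <- fit$report
      cell$n_params <- n_params_selstm(cfg, fit$n_bands)
      cell$accuracy_calibration <- r$accuracy_calibration
      cell$accuracy_prediction <- r$accuracy_prediction
      cell$loss_calibration <- r$loss_calibration
      cell$loss_prediction <- r$loss_prediction
      cell$overfit_coefficient <- r$overfit_coefficient
      cell
    }, error = function(e) { cell$error <- conditionMessage(e); cell })
  })
  out <- do.call(rbind, rows)
  out[order(-out$accuracy_prediction, out$n_params, na.last = TRUE), ,
      drop = FALSE]
}

#' Optimizer and learning-rate sweep
#'
#' One seeded run per (optimizer, learning rate) cell on a fixed
#' architecture; ranked like [grid_search_architecture()].
#'
#' @param x,labels Training data.
#' @param optimizers Default SGD/Adam/RMSprop.
#' @param learning_rates Default 0.001, 0.005, 0.01, 0.05, 0.1.
#' @param config Base configuration (architecture fixed here).
#' @param split Passed to [selstm()].
#' @return Data frame, one ranked row per cell.
#' @export
grid_search_training <- function(x, labels = NULL,
                                 optimizers = c("SGD", "Adam", "RMSprop"),
                                 learning_rates = c(0.001, 0.005, 0.01,
                                                    0.05, 0.1),
                                 config = selstm_config(), split = 0.7) {
  grid <- expand.grid(optimizer = optimizers, lr = learning_rates,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$optimizer <- grid$optimizer[i]
    cfg$learning_rate <- grid$lr[i]
    cell <- data.frame(optimizer = cfg$optimizer,
                       learning_rate = cfg$learning_rate,
                       accuracy_calibration = NA, accuracy_prediction = NA,
                       loss_prediction = NA, overfit_coefficient = NA,
                       error = NA_character_)
    tryCatch({
      fit <- selstm(x, labels, config = cfg, split = split)
      r <- fit$report
      cell$accuracy_calibration <- r$accuracy_calibration
      cell$accuracy_prediction <- r$accuracy_prediction
      cell$loss_prediction <- r$loss_prediction
      cell$overfit_coefficient <- r$overfit_coefficient
      cell
    }, error = function(e) { cell$error <- conditionMessage(e); cell })
  })
  out <- do.call(rbind, rows)
  out[order(-out$accuracy_prediction, na.last = TRUE), , drop = FALSE]
}
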