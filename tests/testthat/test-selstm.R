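test_that("lstm_cell_step matches closed forms at special parameter settings", {
  H <- 3
  zero <- list(W_fx = matrix(0, 1, H), W_fh = matrix(0, H, H), b_f = rep(0, H),
               W_ix = matrix(0, 1, H), W_ih = matrix(0, H, H), b_i = rep(0, H),
               W_ox = matrix(0, 1, H), W_oh = matrix(0, H, H), b_o = rep(0, H),
               W_gx = matrix(0, 1, H), W_gh = matrix(0, H, H), b_g = rep(0, H))
  # all parameters zero: gates at 0.5, candidate 0, so c = h = 0
  st <- lstm_cell_step(zero, 0.7, rep(0, H), rep(0, H))
  expect_equal(st$c, rep(0, H))
  expect_equal(st$h, rep(0, H))

  # scalar worked case: all weights 1, x = 1, zero state
  ones <- scalar_cell_params(1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0)
  st <- lstm_cell_step(ones, 1, 0, 0)
  expect_equal(st$c, 0.55677, tolerance = 1e-5)
  expect_equal(st$h, 0.36961, tolerance = 1e-5)

  # saturated-shut forget gate: c reduces to i * g
  shut <- scalar_cell_params(0, 0, -1e3, 0.4, 0, 0.2, 0, 0, 0, 0.9, 0, -0.1)
  st <- lstm_cell_step(shut, 1.3, 0.5, 2.0)
  i <- plogis(0.4 * 1.3 + 0.2)
  g <- tanh(0.9 * 1.3 - 0.1)
  expect_lt(abs(st$c - i * g), 1e-12)

  expect_error(lstm_cell_step(ones, NaN, 0, 0), "non-finite")
})

test_that("SE block matches closed forms and a hand-evaluated C=2 case", {
  C <- 4
  zero <- list(W1 = matrix(0, C, 2), b1 = rep(0, 2),
               W2 = matrix(0, 2, C), b2 = rep(0, C))
  x <- c(0.2, -1, 3, 0.5)
  expect_equal(se_block_forward(zero, x), 0.5 * x)
  expect_equal(se_block_forward(zero, rep(0, C)), rep(0, C))

  # C = 2, r = 1: hand-set weights, scalar arithmetic oracle
  pars <- list(W1 = matrix(c(0.5, -0.3), 2, 1), b1 = 0.1,
               W2 = matrix(c(0.8, -0.6), 1, 2), b2 = c(-0.2, 0.4))
  x2 <- c(1.5, -0.7)
  u <- 0.5 * 1.5 + (-0.3) * (-0.7) + 0.1
  r <- max(u, 0)
  s1 <- 1 / (1 + exp(-(0.8 * r - 0.2)))
  s2 <- 1 / (1 + exp(-(-0.6 * r + 0.4)))
  expect_equal(se_block_forward(pars, x2), c(s1 * x2[1], s2 * x2[2]),
               tolerance = 1e-9)
  expect_error(se_block_forward(pars, c(1, 2, 3)), "channels")
})

test_that("forward pass is a chained cell evaluation with softmax output", {
  # single-layer, 1-unit model with hand weights on a 3-band input
  cfg <- selstm_config(n_layers = 1, units = 1, n_classes = 3,
                       use_se = FALSE, standardize = FALSE, seed = 1)
  pr <- list(layers = list(list(Wx = matrix(c(0.5, -0.2, 0.3, 0.7), 1, 4),
                                Wh = matrix(c(-0.1, 0.4, 0.2, -0.3), 1, 4),
                                b = c(0.05, -0.02, 0.1, 0))),
             head = list(Wy = matrix(c(1, -1, 0.5), 1, 3), by = c(0, 0.1, -0.1)))
  x <- c(0.3, -0.6, 0.9)
  probs <- hyperleaf:::selstm_fwd(pr, matrix(x, 1), cfg)$probs
  # oracle: chain lstm_cell_step over the 3 bands with the same gate layout
  cell <- list(W_fx = pr$layers[[1]]$Wx[, 1, drop = FALSE],
               W_ix = pr$layers[[1]]$Wx[, 2, drop = FALSE],
               W_ox = pr$layers[[1]]$Wx[, 3, drop = FALSE],
               W_gx = pr$layers[[1]]$Wx[, 4, drop = FALSE],
               W_fh = pr$layers[[1]]$Wh[, 1, drop = FALSE],
               W_ih = pr$layers[[1]]$Wh[, 2, drop = FALSE],
               W_oh = pr$layers[[1]]$Wh[, 3, drop = FALSE],
               W_gh = pr$layers[[1]]$Wh[, 4, drop = FALSE],
               b_f = pr$layers[[1]]$b[1], b_i = pr$layers[[1]]$b[2],
               b_o = pr$layers[[1]]$b[3], b_g = pr$layers[[1]]$b[4])
  h <- 0; cc <- 0
  for (t in 1:3) {
    st <- lstm_cell_step(cell, x[t], h, cc)
    h <- st$h; cc <- st$c
  }
  logits <- h * c(1, -1, 0.5) + c(0, 0.1, -0.1)
  expect_equal(drop(probs), exp(logits) / sum(exp(logits)), tolerance = 1e-12)
  expect_equal(sum(probs), 1, tolerance = 1e-6)
})

test_that("analytic gradients match finite differences on a tiny model", {
  ns <- asNamespace("hyperleaf")
  set.seed(42)
  C <- 6; n <- 4
  cfg <- selstm_config(n_layers = 2, units = 3, reduction_ratio = 2,
                       n_classes = 3, seed = 1)
  pr <- hyperleaf:::with_seed(7, ns$init_params(C, cfg))
  X <- matrix(runif(n * C), n, C)
  y <- c(1L, 2L, 3L, 1L)
  Y1 <- matrix(0, n, 3); Y1[cbind(1:n, y)] <- 1
  loss_fn <- function(p) ns$cross_entropy(ns$selstm_fwd(p, X, cfg)$probs, y)
  fwd <- ns$selstm_fwd(pr, X, cfg, keep_cache = TRUE)
  gr <- ns$selstm_bwd(pr, fwd, Y1, cfg)
  eps <- 1e-6
  check <- function(w, g, set) {
    for (i in sample(length(w), min(5, length(w)))) {
      up <- w; up[i] <- up[i] + eps
      dn <- w; dn[i] <- dn[i] - eps
      num <- (loss_fn(set(up)) - loss_fn(set(dn))) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  }
  check(pr$se$W1, gr$se$W1, function(w) { p <- pr; p$se$W1[] <- w; p })
  check(pr$layers[[1]]$Wh, gr$layers[[1]]$Wh,
        function(w) { p <- pr; p$layers[[1]]$Wh[] <- w; p })
  check(pr$layers[[2]]$Wx, gr$layers[[2]]$Wx,
        function(w) { p <- pr; p$layers[[2]]$Wx[] <- w; p })
  check(pr$head$Wy, gr$head$Wy, function(w) { p <- pr; p$head$Wy[] <- w; p })
})

test_that("training is seed-deterministic and inert at zero learning rate", {
  sp <- simulate_informative_spectra(n_per_class = 15, n_bands = 8,
                                     informative = c(2L, 5L), seed = 3)
  cfg <- selstm_config(n_layers = 1, units = 4, reduction_ratio = 2,
                       epochs = 3, seed = 5)
  f1 <- selstm(sp, config = cfg)
  f2 <- selstm(sp, config = cfg)
  expect_identical(tail(f1$loss_curve, 1), tail(f2$loss_curve, 1))
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1, sp$X, type = "prob"),
                   predict(f2, sp$X, type = "prob"))

  # zero learning rate leaves the seeded initialisation untouched
  cfg0 <- cfg; cfg0$learning_rate <- 0
  f0 <- selstm(sp, config = cfg0)
  init <- hyperleaf:::with_seed(cfg0$seed,
                                hyperleaf:::init_params(8, cfg0))
  expect_identical(f0$params, init)
})

test_that("class permutation in the head permutes the output probabilities", {
  sp <- simulate_informative_spectra(n_per_class = 10, n_bands = 8,
                                     informative = c(2L, 5L), seed = 2)
  cfg <- selstm_config(n_layers = 1, units = 4, reduction_ratio = 2,
                       epochs = 2, seed = 9)
  fit <- selstm(sp, config = cfg)
  perm <- c(3L, 1L, 2L)
  fit2 <- fit
  fit2$params$head$Wy <- fit$params$head$Wy[, perm]
  fit2$params$head$by <- fit$params$head$by[perm]
  p1 <- predict(fit, sp$X, type = "prob")
  p2 <- predict(fit2, sp$X, type = "prob")
  expect_equal(unname(p2), unname(p1[, perm]), tolerance = 1e-12)
})

test_that("evaluation reports accuracy, loss, and the overfit gap", {
  # classifier stub whose accuracy is exact by construction
  fake <- structure(list(classes = c("0", "10", "100")), class = "probtab")
  registerS3method("predict", "probtab",
                   function(object, newdata, type = "prob", ...) {
                     n <- nrow(newdata)
                     # predicts class "0" when the first feature is 1
                     p <- matrix(c(0.98, 0.01, 0.01), n, 3, byrow = TRUE)
                     swap <- which(newdata[, 1] == 0)
                     if (length(swap))
                       p[swap, ] <- matrix(c(0.01, 0.98, 0.01),
                                           length(swap), 3, byrow = TRUE)
                     p
                   })
  mkset <- function(n_right, n_wrong) {
    X <- matrix(1, n_right + n_wrong, 2)
    y <- rep("0", n_right + n_wrong)
    if (n_wrong > 0) y[seq_len(n_wrong)] <- "10"  # predicted "0", truth "10"
    list(X = X, y = y)
  }
  # 9601/10000 vs 9388/10000 correct: overfit gap = 96.01 - 93.88 = 2.13
  rep <- evaluate_model(fake, mkset(9601, 399), mkset(9388, 612))
  expect_equal(rep$accuracy_calibration, 96.01)
  expect_equal(rep$accuracy_prediction, 93.88)
  expect_equal(rep$overfit_coefficient, 2.13)

  # identical sets: no gap; a perfect classifier has ~zero loss
  same <- mkset(100, 0)
  rep2 <- evaluate_model(fake, same, same)
  expect_equal(rep2$overfit_coefficient, 0)
  expect_equal(rep2$accuracy_calibration, 100)
  expect_lt(rep2$loss_calibration, 0.05)
  expect_error(evaluate_model(fake, list(X = same$X, y = rep("bad", 100)),
                              same),
               "outside model classes")
})

test_that("grid searches return one ranked row per cell with the tie rule", {
  sp <- simulate_informative_spectra(n_per_class = 10, n_bands = 8,
                                     informative = c(2L, 5L), seed = 6)
  cfg <- selstm_config(reduction_ratio = 2, epochs = 1, seed = 4)
  one <- grid_search_architecture(sp, layers = 2, units = 8, config = cfg)
  expect_equal(nrow(one), 1)
  tab <- grid_search_architecture(sp, layers = 1:2, units = c(4, 8),
                                  config = cfg)
  expect_equal(nrow(tab), 4)
  expect_true(all(diff(tab$accuracy_prediction) <= 1e-12))
  # among equal accuracies, smaller models first
  for (acc in unique(tab$accuracy_prediction)) {
    sub <- tab[tab$accuracy_prediction == acc, ]
    expect_true(all(diff(sub$n_params) >= 0))
  }
})
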