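#' Characteristic-wavelength subset
#'
#' @param method One of `"SPA"`, `"GA"`, `"PSO"`, `"BOSS"`.
#' @param indices Selected band positions (made unique and sorted).
#' @param wavelengths_nm Band centres of the selection.
#' @param fitness_trace Per-iteration best fitness (selector-dependent).
#' @param seed Seed the selection was run under.
#' @param details Selector-specific extras.
#' @return A list of class `"wavelength_subset"`.
#' @export
wavelength_subset <- function(method, indices, wavelengths_nm,
                              fitness_trace = numeric(0), seed = NA_integer_,
                              details = list()) {
  indices <- sort(unique(as.integer(indices)))
  structure(list(method = method, indices = indices,
                 wavelengths_nm = wavelengths_nm[seq_along(wavelengths_nm)],
                 fitness_trace = fitness_trace, seed = seed,
                 details = details),
            class = "wavelength_subset")
}

#' @export
print.wavelength_subset <- function(x, ...) {
  cat(sprintf("%s selection: %d band(s)\n", x$method, length(x$indices)))
  cat("  ", paste(format(x$wavelengths_nm, trim = TRUE, digits = 5),
                  collapse = ", "), "nm\n")
  invisible(x)
}

get_xy <- function(x, labels) {
  X <- if (inherits(x, "labeled_spectra")) x$X else as.matrix(x)
  if (is.null(labels)) {
    if (!inherits(x, "labeled_spectra"))
      stopf("labels required when x is a matrix")
    labels <- x$class_mg_l
  }
  list(X = X, y = factor(labels),
       wl = if (inherits(x, "labeled_spectra")) x$wavelengths
            else seq_len(ncol(X)))
}

# Wrapper criterion shared by GA/PSO/BOSS: cross-validated PLS-DA accuracy
# minus a size penalty.
subset_fitness <- function(X, y, idx, lambda = 0.2, ncomp = 5, folds = 3,
                           cv_seed = 1L) {
  if (length(idx) == 0L) return(-Inf)
  acc <- cv_accuracy_plsda(X[, idx, drop = FALSE], y,
                           ncomp = min(ncomp, length(idx)),
                           folds = folds, seed = cv_seed)
  acc - lambda * length(idx) / ncol(X)
}

#' Successive projections algorithm
#'
#' Forward selection minimising collinearity: from each candidate start
#' column, the chain grows by repeatedly adding the column with the largest
#' norm after projection onto the orthogonal complement of the chosen
#' columns.  The final chain (start column and length between `k_min` and
#' `k_max`) is the one with the highest cross-validated PLS-DA accuracy;
#' ties go to fewer bands.
#'
#' @param x A `"labeled_spectra"` or matrix.
#' @param labels Class labels (when `x` is a matrix).
#' @param k_min,k_max Candidate subset sizes.
#' @param starts Candidate start columns (default: all).
#' @param folds,ncomp,cv_seed Cross-validation settings for the size choice.
#' @return A `"wavelength_subset"` (method `"SPA"`).
#' @export
spa_select <- function(x, labels = NULL, k_min = 3, k_max = 15,
                       starts = NULL, folds = 5, ncomp = 5, cv_seed = 1L) {
  d <- get_xy(x, labels)
  X <- d$X; y <- d$y
  B <- ncol(X)
  if (k_max > B) stopf("k_max (%d) exceeds band count (%d)", k_max, B)
  if (k_min > k_max) stopf("k_min must be <= k_max")
  if (qr(scale(X, center = TRUE, scale = FALSE))$rank < k_min)
    stopf("data rank below k_min")
  if (is.null(starts)) starts <- seq_len(B)
  chains <- lapply(starts, function(j0) spa_chain(X, j0, k_max))
  best <- NULL
  for (ch in chains) {
    for (k in k_min:min(k_max, length(ch))) {
      idx <- ch[seq_len(k)]
      acc <- cv_accuracy_plsda(X[, idx, drop = FALSE], y,
                               ncomp = min(ncomp, k), folds = folds,
                               seed = cv_seed)
      if (is.null(best) || acc > best$acc ||
          (acc == best$acc && k < length(best$idx)))
        best <- list(idx = idx, acc = acc)
    }
  }
  wavelength_subset("SPA", best$idx, d$wl[sort(unique(best$idx))],
                    fitness_trace = best$acc, seed = cv_seed,
                    details = list(k_min = k_min, k_max = k_max,
                                   cv_accuracy = best$acc))
}

# One SPA chain: successive orthogonal-projection residual maximisation.
spa_chain <- function(X, start, k) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  R <- Xc
  chain <- integer(0)
  j <- start
  for (step in seq_len(k)) {
    chain <- c(chain, j)
    q <- R[, j]
    nq <- sqrt(sum(q^2))
    if (nq < 1e-12) break
    q <- q / nq
    R <- R - q %*% crossprod(q, R)     # project all columns off q
    R[, chain] <- 0
    norms <- sqrt(colSums(R^2))
    if (max(norms) < 1e-10) break
    j <- which.max(norms)
  }
  chain
}

#' Genetic-algorithm wavelength selection
#'
#' Binary-mask chromosomes; fitness is cross-validated PLS-DA accuracy
#' minus `lambda * |subset| / B`.  Tournament selection (size 2), uniform
#' crossover, bit-flip mutation, one elite carried each generation (so the
#' best-fitness trace is non-decreasing).  All-zero masks are repaired to a
#' single random band.
#'
#' @param x,labels Data as in [spa_select()].
#' @param population,generations GA size (defaults 50 x 100).
#' @param p_crossover,p_mutation Crossover and per-bit mutation rates.
#' @param lambda Size-penalty weight (default 0.2).
#' @param init_p Initial per-bit inclusion probability.
#' @param ncomp,folds Wrapper PLS-DA settings.
#' @param seed Integer seed.
#' @return A `"wavelength_subset"` (method `"GA"`).
#' @export
ga_select <- function(x, labels = NULL, population = 50, generations = 100,
                      p_crossover = 0.8, p_mutation = 0.02, lambda = 0.2,
                      init_p = 0.3, ncomp = 5, folds = 3, seed = 1L) {
  if (population < 2) stopf("population must be >= 2")
  d <- get_xy(x, labels)
  X <- d$X; y <- d$y; B <- ncol(X)
  fit_cache <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(fit_cache[[key]])) return(fit_cache[[key]])
    v <- subset_fitness(X, y, which(mask), lambda, ncomp, folds,
                        cv_seed = seed)
    fit_cache[[key]] <- v
    v
  }
  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(B, 1)] <- TRUE
    mask
  }
  with_seed(seed, {
    pop <- lapply(seq_len(population),
                  function(i) repair(runif(B) < init_p))
    fits <- vapply(pop, fitness, 0)
    trace <- numeric(generations)
    for (g in seq_len(generations)) {
      elite_i <- which.max(fits)
      newpop <- list(pop[[elite_i]])
      while (length(newpop) < population) {
        pick <- function() {
          cand <- sample.int(population, 2)
          pop[[cand[which.max(fits[cand])]]]
        }
        a <- pick(); b <- pick()
        if (runif(1) < p_crossover) {
          sw <- runif(B) < 0.5
          tmp <- a; a[sw] <- b[sw]; b[sw] <- tmp[sw]
        }
        for (child in list(a, b)) {
          flip <- runif(B) < p_mutation
          child[flip] <- !child[flip]
          newpop <- c(newpop, list(repair(child)))
        }
      }
      pop <- newpop[seq_len(population)]
      fits <- vapply(pop, fitness, 0)
      trace[g] <- max(fits)
    }
    best <- pop[[which.max(fits)]]
    idx <- which(best)
    wavelength_subset("GA", idx, d$wl[idx], fitness_trace = cummax(trace),
                      seed = seed,
                      details = list(lambda = lambda,
                                     population = population,
                                     generations = generations))
  })
}

#' Binary particle-swarm wavelength selection
#'
#' Binary PSO with a sigmoid-shaped velocity transfer of the V type: the
#' probability that a bit flips is `|2 * sigmoid(v) - 1|`, so zero velocity
#' leaves a particle frozen.  Inertia decays linearly (0.9 to 0.4 by
#' default); fitness as in [ga_select()]; the global-best trace is
#' non-decreasing by construction.
#'
#' @param x,labels Data.
#' @param swarm,iterations Swarm size and iteration count (30 x 100).
#' @param inertia Length-2 vector: start and end inertia weights.
#' @param c1,c2 Cognitive and social acceleration (default 2).
#' @param lambda,init_p,ncomp,folds As in [ga_select()].
#' @param seed Integer seed.
#' @return A `"wavelength_subset"` (method `"PSO"`).
#' @export
pso_select <- function(x, labels = NULL, swarm = 30, iterations = 100,
                       inertia = c(0.9, 0.4), c1 = 2, c2 = 2, lambda = 0.2,
                       init_p = 0.3, ncomp = 5, folds = 3, seed = 1L) {
  if (swarm < 2) stopf("swarm must be >= 2")
  d <- get_xy(x, labels)
  X <- d$X; y <- d$y; B <- ncol(X)
  fit_cache <- new.env(parent = emptyenv())
  fitness <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(fit_cache[[key]])) return(fit_cache[[key]])
    v <- subset_fitness(X, y, which(mask), lambda, ncomp, folds,
                        cv_seed = seed)
    fit_cache[[key]] <- v
    v
  }
  with_seed(seed, {
    pos <- lapply(seq_len(swarm), function(i) {
      m <- runif(B) < init_p
      if (!any(m)) m[sample.int(B, 1)] <- TRUE
      m
    })
    vel <- lapply(seq_len(swarm), function(i) rep(0, B))
    pbest <- pos
    pfit <- vapply(pos, fitness, 0)
    gbest <- pbest[[which.max(pfit)]]
    gfit <- max(pfit)
    trace <- numeric(iterations)
    for (it in seq_len(iterations)) {
      w <- inertia[1] + (inertia[2] - inertia[1]) *
        (it - 1) / max(1, iterations - 1)
      for (s in seq_len(swarm)) {
        r1 <- runif(B); r2 <- runif(B)
        vel[[s]] <- w * vel[[s]] +
          c1 * r1 * (pbest[[s]] - pos[[s]]) +
          c2 * r2 * (gbest - pos[[s]])
        vel[[s]] <- pmin(pmax(vel[[s]], -6), 6)
        p_flip <- abs(2 * sigmoid(vel[[s]]) - 1)
        flip <- runif(B) < p_flip
        m <- pos[[s]]
        m[flip] <- vel[[s]][flip] > 0      # move toward velocity sign
        if (!any(m)) m[sample.int(B, 1)] <- TRUE
        pos[[s]] <- m
        f <- fitness(m)
        if (f > pfit[s]) { pfit[s] <- f; pbest[[s]] <- m }
        if (f > gfit) { gfit <- f; gbest <- m }
      }
      trace[it] <- gfit
    }
    idx <- which(gbest)
    wavelength_subset("PSO", idx, d$wl[idx], fitness_trace = cummax(trace),
                      seed = seed,
                      details = list(lambda = lambda, swarm = swarm,
                                     iterations = iterations))
  })
}

#' Bootstrapping soft shrinkage wavelength selection
#'
#' Maintains inclusion weights over bands (normalised to sum 1 each
#' round).  Each shrinkage round draws bootstrap sub-models — band subsets
#' sampled by weight, of a size that shrinks geometrically across rounds —
#' fits a PLS-DA to each, and accumulates absolute regression-coefficient
#' mass into new weights (soft shrinkage: bands are down-weighted, not
#' eliminated outright, until their weight reaches zero).  The retained
#' subset of the round with the best cross-validated accuracy wins.
#'
#' @param x,labels Data.
#' @param n_bootstrap Sub-models per round (default 500).
#' @param rounds Shrinkage rounds (default 30).
#' @param ncomp,folds Wrapper PLS-DA settings.
#' @param seed Integer seed.
#' @return A `"wavelength_subset"` (method `"BOSS"`) whose `details`
#'   include per-round weights and any constant bands removed up front.
#' @export
boss_select <- function(x, labels = NULL, n_bootstrap = 500, rounds = 30,
                        ncomp = 5, folds = 3, seed = 1L) {
  if (n_bootstrap < 2) stopf("n_bootstrap must be >= 2")
  d <- get_xy(x, labels)
  X <- d$X; y <- d$y; B <- ncol(X)
  const <- which(apply(X, 2, sd) < 1e-12)
  active <- setdiff(seq_len(B), const)
  if (length(active) < 2) stopf("fewer than 2 non-constant bands")
  with_seed(seed, {
    w <- rep(0, B)
    w[active] <- 1 / length(active)
    # geometric size schedule: from all active bands down to ~2
    sizes <- pmax(2, round(length(active) *
                             (2 / length(active))^((seq_len(rounds) - 1) /
                                                   max(1, rounds - 1))))
    trace <- numeric(rounds)
    best <- NULL
    weight_history <- vector("list", rounds)
    for (r in seq_len(rounds)) {
      k <- sizes[r]
      acc_coef <- rep(0, B)
      for (bs in seq_len(n_bootstrap)) {
        nonzero <- which(w > 0)
        if (length(nonzero) < 2) break
        idx <- sample(nonzero, min(k, length(nonzero)), prob = w[nonzero])
        idx <- unique(idx)
        fit <- nipals_pls2(X[, idx, drop = FALSE], class_indicator(y),
                           min(ncomp, length(idx)))
        acc_coef[idx] <- acc_coef[idx] + rowSums(abs(fit$coefficients))
      }
      if (sum(acc_coef) == 0) break
      w <- acc_coef / sum(acc_coef)
      weight_history[[r]] <- w
      retained <- order(w, decreasing = TRUE)[seq_len(k)]
      retained <- retained[w[retained] > 0]
      acc <- cv_accuracy_plsda(X[, retained, drop = FALSE], y,
                               ncomp = min(ncomp, length(retained)),
                               folds = folds, seed = seed)
      trace[r] <- acc
      if (is.null(best) || acc > best$acc)
        best <- list(idx = retained, acc = acc, round = r)
    }
    idx <- sort(best$idx)
    wavelength_subset("BOSS", idx, d$wl[idx], fitness_trace = trace,
                      seed = seed,
                      details = list(n_bootstrap = n_bootstrap,
                                     rounds = rounds,
                                     best_round = best$round,
                                     constant_bands_removed = const,
                                     weight_history = weight_history))
  })
}

#' Train a simplified model on selected bands
#'
#' Restricts the spectra to a wavelength subset and retrains the chosen
#' classifier, reporting calibration, cross-validation, and prediction
#' accuracy.
#'
#' @param x,labels Data as elsewhere.
#' @param subset A `"wavelength_subset"` or integer band indices.
#' @param kind `"plsda"` (default), `"selstm"` or `"lstm"`.
#' @param config [selstm_config()] for the recurrent kinds.
#' @param ncomp PLS-DA component count.
#' @param folds Cross-validation folds for the reported CV accuracy.
#' @param split Calibration fraction or index list.
#' @param seed Seed for split and CV.
#' @return A list of class `"simplified_model"`: the fit, the subset, and
#'   `report` with `accuracy_calibration`, `accuracy_cv`,
#'   `accuracy_prediction`.
#' @export
fit_simplified_model <- function(x, labels = NULL, subset,
                                 kind = c("plsda", "selstm", "lstm"),
                                 config = NULL, ncomp = 5, folds = 5,
                                 split = 0.7, seed = 1L) {
  kind <- match.arg(kind)
  d <- get_xy(x, labels)
  idx <- if (inherits(subset, "wavelength_subset")) subset$indices
         else sort(unique(as.integer(subset)))
  if (length(idx) == 0L) stopf("empty wavelength subset")
  if (any(idx < 1 | idx > ncol(d$X))) stopf("subset indices out of range")
  Xs <- d$X[, idx, drop = FALSE]
  y <- d$y
  if (is.numeric(split)) split <- stratified_split(y, split, seed)
  cal <- split$calibration; prd <- split$prediction
  if (kind == "plsda") {
    fit <- plsda(Xs[cal, , drop = FALSE], y[cal],
                 ncomp = min(ncomp, length(idx)))
    acc <- function(i) 100 * mean(as.character(predict(fit,
      Xs[i, , drop = FALSE])) == as.character(y[i]))
    cvacc <- 100 * cv_accuracy_plsda(Xs[cal, , drop = FALSE], y[cal],
                                     ncomp = min(ncomp, length(idx)),
                                     folds = folds, seed = seed)
    report <- list(accuracy_calibration = acc(cal), accuracy_cv = cvacc,
                   accuracy_prediction = acc(prd))
  } else {
    if (is.null(config)) config <- selstm_config()
    config$use_se <- kind == "selstm"
    # keep the SE bottleneck valid on arbitrary subset sizes
    if (config$use_se)
      config$reduction_ratio <- largest_divisor(length(idx),
                                                config$reduction_ratio)
    fit <- selstm(Xs, y, config = config, split = split)
    cvacc <- NA_real_
    report <- list(accuracy_calibration = fit$report$accuracy_calibration,
                   accuracy_cv = cvacc,
                   accuracy_prediction = fit$report$accuracy_prediction)
  }
  structure(list(fit = fit, kind = kind, indices = idx,
                 wavelengths_nm = d$wl[idx], report = report),
            class = "simplified_model")
}

largest_divisor <- function(n, at_most) {
  for (r in seq(min(at_most, n), 1)) if (n %% r == 0) return(r)
  1L
}

#' @export
print.simplified_model <- function(x, ...) {
  cat(sprintf("Simplified %s model on %d band(s)\n", x$kind,
              length(x$indices)))
  r <- x$report
  cat(sprintf("  calibration %.2f%% | cv %s | prediction %.2f%%\n",
              r$accuracy_calibration,
              if (is.na(r$accuracy_cv)) "-" else
                sprintf("%.2f%%", r$accuracy_cv),
              r$accuracy_prediction))
  invisible(x)
}
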