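#' Feature map for the maximum-entropy model
#'
#' Records, from the background sample only, the scaling constants of
#' every variable: min/max for continuous variables (whose linear
#' feature is the min-max scaled value and whose quadratic feature is
#' its square, both in [0, 1]) and the observed levels of categorical
#' variables (one 0/1 indicator feature per level).
#'
#' @param bg data frame / matrix of background environmental values.
#' @param kinds named character vector: `"continuous"` or
#'   `"categorical"` per variable; defaults to all continuous.
#' @return an object of class `feature_map`.
#' @export
feature_map <- function(bg, kinds = NULL) {
  bg <- as.data.frame(bg)
  vars <- names(bg)
  if (is.null(kinds)) kinds <- stats::setNames(rep("continuous", length(vars)), vars)
  fm <- lapply(vars, function(v) {
    if (kinds[[v]] == "continuous") {
      list(kind = "continuous", min = min(bg[[v]]), max = max(bg[[v]]))
    } else {
      list(kind = "categorical", levels = sort(unique(bg[[v]])))
    }
  })
  names(fm) <- vars
  structure(fm, class = "feature_map")
}

#' Build the feature matrix for a set of points
#'
#' @param fm a [feature_map()].
#' @param env environmental values (columns must cover the map's
#'   variables).
#' @param quadratic include quadratic features for continuous
#'   variables.
#' @return numeric matrix of features; columns named
#'   `<var>` (linear), `<var>^2` (quadratic) or `<var>=<level>`
#'   (indicator). Column attribute `"variable"` maps features back to
#'   variables.
#' @export
build_features <- function(fm, env, quadratic = TRUE) {
  env <- as.data.frame(env)
  cols <- list(); vars <- character(0)
  for (v in names(fm)) {
    f <- fm[[v]]
    if (f$kind == "continuous") {
      rng <- f$max - f$min
      z <- if (rng > 0) (env[[v]] - f$min) / rng else env[[v]] * 0
      z <- pmin(pmax(z, 0), 1)
      cols[[v]] <- z
      vars <- c(vars, v)
      if (quadratic) {
        cols[[paste0(v, "^2")]] <- z^2
        vars <- c(vars, v)
      }
    } else {
      for (lev in f$levels) {
        cols[[paste0(v, "=", lev)]] <- as.numeric(env[[v]] == lev)
        vars <- c(vars, v)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "variable") <- vars
  X
}

#' Uniform background sample of a landscape
#'
#' Samples `n` non-nodata cells without replacement (uniformly) and
#' returns their environmental values and cell-center coordinates.
#'
#' @param landscape named list of `raster_layer`s.
#' @param n number of background cells (default 10000, capped at the
#'   available cell count by the caller; oversampling is an error).
#' @param seed optional seed.
#' @param layers layer names to extract (default all).
#' @return data frame with `x`, `y` and one column per layer.
#' @export
sample_background <- function(landscape, n = 10000, seed = NULL,
                              layers = names(landscape)) {
  if (!is.null(seed)) set.seed(seed)
  l1 <- landscape[[layers[1]]]
  ok <- l1$values != l1$nodata
  for (ln in layers) ok <- ok & landscape[[ln]]$values != landscape[[ln]]$nodata
  idx <- which(ok)
  if (n > length(idx))
    stop("requested ", n, " background cells but only ", length(idx),
         " non-nodata cells exist")
  pick <- sample(idx, n)
  ctr <- cell_centers(l1)
  out <- data.frame(x = ctr$x[pick], y = ctr$y[pick])
  for (ln in layers) out[[ln]] <- landscape[[ln]]$values[pick]
  out
}

maxent_objective <- function(lambda, Fpres, Fbg, beta) {
  eta_bg <- as.vector(Fbg %*% lambda)
  zeta <- log_sum_exp(eta_bg)
  mean(Fpres %*% lambda) - zeta - sum(beta * abs(lambda))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a maximum-entropy distribution model
#'
#' Maximizes the L1-penalized presence log-likelihood
#' \deqn{\frac{1}{m}\sum_i \lambda \cdot f(x_i) - \zeta(\lambda)
#'   - \sum_j \beta_j |\lambda_j|}
#' over the background-normalized exponential family
#' (`zeta = log sum_bg exp(lambda . f)`), by proximal gradient ascent
#' with backtracking line search — a convex problem, so the solution is
#' deterministic given the inputs. Constant features are dropped with a
#' warning; non-convergence within `max_iter` warns with the attained
#' gradient norm. The entropy H of the fitted background distribution is
#' stored for the logistic output transform.
#'
#' @param pres_env presence environmental values.
#' @param bg_env background environmental values.
#' @param kinds per-variable kind passed to [feature_map()].
#' @param beta L1 regularization per feature (scalar or per-feature).
#' @param max_iter maximum proximal-gradient iterations.
#' @param tol convergence tolerance on the coefficient step.
#' @param quadratic include quadratic features (linear-only otherwise).
#' @return an object of class `sdm_model`: `feature_map`, `lambda`,
#'   `zeta`, `entropy`, background summaries for response curves, and
#'   the fitted background distribution.
#' @export
fit_maxent <- function(pres_env, bg_env, kinds = NULL, beta = 0.05,
                       max_iter = 5000, tol = 1e-6, quadratic = TRUE) {
  pres_env <- as.data.frame(pres_env)
  bg_env <- as.data.frame(bg_env)
  if (nrow(pres_env) < 2) stop("need >= 2 presence points")
  fm <- feature_map(bg_env, kinds)
  Fbg <- build_features(fm, bg_env, quadratic)
  Fpres <- build_features(fm, pres_env, quadratic)
  featvar <- attr(Fbg, "variable")

  const <- apply(Fbg, 2, function(x) max(x) - min(x)) == 0
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(Fbg)[const], collapse = ", "))
    Fbg <- Fbg[, !const, drop = FALSE]
    Fpres <- Fpres[, !const, drop = FALSE]
    featvar <- featvar[!const]
  }
  p <- ncol(Fbg)
  beta <- rep_len(beta, p)
  lambda <- rep(0, p)
  fbar <- colMeans(Fpres)
  step <- 1
  obj <- maxent_objective(lambda, Fpres, Fbg, beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Fbg %*% lambda)
    wz <- exp(eta - log_sum_exp(eta))
    grad <- fbar - as.vector(t(Fbg) %*% wz)
    repeat {
      cand <- lambda + step * grad
      ## soft-threshold (proximal operator of the L1 penalty)
      cand <- sign(cand) * pmax(abs(cand) - step * beta, 0)
      obj_new <- maxent_objective(cand, Fpres, Fbg, beta)
      if (obj_new >= obj - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    delta <- max(abs(cand - lambda))
    lambda <- cand
    obj <- obj_new
    step <- min(step * 1.25, 100)
    ## KKT optimality for the L1 problem: on active coordinates the
    ## gradient must match the penalty subgradient; on zero
    ## coordinates it must lie inside the penalty band
    eta <- as.vector(Fbg %*% lambda)
    g <- fbar - as.vector(t(Fbg) %*% exp(eta - log_sum_exp(eta)))
    active <- lambda != 0
    viol <- max(c(abs(g - beta * sign(lambda))[active],
                  pmax(abs(g) - beta, 0)[!active], 0))
    if (delta < tol || viol < 1e-6) { converged <- TRUE; break }
  }
  eta <- as.vector(Fbg %*% lambda)
  zeta <- log_sum_exp(eta)
  q <- exp(eta - zeta)
  H <- -sum(q * log(pmax(q, .Machine$double.xmin)))
  if (!converged)
    warning(sprintf("maxent fit did not converge in %d iterations (KKT violation %.2e)",
                    max_iter, viol))
  bg_summary <- lapply(names(fm), function(v) {
    if (fm[[v]]$kind == "continuous") mean(bg_env[[v]])
    else {
      tab <- table(bg_env[[v]])
      as.numeric(names(tab)[which.max(tab)])
    }
  })
  names(bg_summary) <- names(fm)
  names(lambda) <- colnames(Fbg)
  structure(list(feature_map = fm, lambda = lambda,
                 quadratic = quadratic,
                 feature_names = colnames(Fbg),
                 feature_variable = featvar,
                 zeta = zeta, entropy = H,
                 bg_summary = bg_summary,
                 n_background = nrow(Fbg),
                 converged = converged),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model: %d features over %d variables, entropy %.3f>\n",
              length(x$lambda), length(x$feature_map), x$entropy))
  invisible(x)
}

#' Logistic suitability output
#'
#' Raw output `r(x) = exp(lambda . f(x) - zeta)` (summing to 1 over the
#' background); logistic output
#' `s(x) = r e^H / (1 + r e^H)`, the conventional probability-of-
#' presence scale: a point with the typical background raw value
#' `e^(-H)` maps to 0.5.
#'
#' @param model a fitted [fit_maxent()] model.
#' @param env environmental values of the points to score.
#' @return numeric vector of suitabilities in (0, 1).
#' @export
logistic_output <- function(model, env) {
  X <- build_features(model$feature_map, env, model$quadratic)
  X <- X[, model$feature_names, drop = FALSE]
  r <- exp(as.vector(X %*% model$lambda) - model$zeta)
  reh <- r * exp(model$entropy)
  reh / (1 + reh)
}

#' Replicate train/test evaluation with AUC
#'
#' Repeatedly splits the presences into a training panel (75% by
#' default, rounding toward training) and a disjoint test panel, refits
#' the model on the training presences, and scores both panels against
#' the background with the rank (Mann-Whitney) AUC: the probability
#' that a random presence outscores a random background point, ties
#' counting one half.
#'
#' @param pres_env presence environmental values.
#' @param bg_env background environmental values.
#' @param n_replicates number of random splits.
#' @param split training fraction.
#' @param seed seed for the splits.
#' @param ... passed to [fit_maxent()].
#' @return list with `replicates` (data frame: replicate, train/test
#'   AUC), `summary` (mean and sd), and `models` (the fitted
#'   replicates).
#' @export
replicate_evaluate <- function(pres_env, bg_env, n_replicates = 15,
                               split = 0.75, seed = NULL, ...) {
  pres_env <- as.data.frame(pres_env)
  m <- nrow(pres_env)
  if (m < 4) stop("need >= 4 presences for a train/test split")
  n_train <- ceiling(split * m)
  if (n_train >= m) n_train <- m - 1
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_replicates)
  models <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    tr <- sample.int(m, n_train)
    fit <- fit_maxent(pres_env[tr, , drop = FALSE], bg_env, ...)
    s_bg <- logistic_output(fit, bg_env)
    s_tr <- logistic_output(fit, pres_env[tr, , drop = FALSE])
    s_te <- logistic_output(fit, pres_env[-tr, , drop = FALSE])
    rows[[rep_i]] <- data.frame(replicate = rep_i,
                                train_auc = rank_auc(s_tr, s_bg),
                                test_auc = rank_auc(s_te, s_bg))
    models[[rep_i]] <- fit
  }
  reps <- do.call(rbind, rows)
  list(replicates = reps,
       summary = c(mean_train_auc = mean(reps$train_auc),
                   sd_train_auc = stats::sd(reps$train_auc),
                   mean_test_auc = mean(reps$test_auc),
                   sd_test_auc = stats::sd(reps$test_auc)),
       models = models)
}

#' Rank (Mann-Whitney) AUC
#'
#' Probability that a random positive scores above a random negative,
#' ties counting one half.
#'
#' @param pos,neg score vectors.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Permutation variable importance
#'
#' For each variable, its values are permuted jointly across presences
#' and background, model scores are recomputed, and the drop in
#' training AUC (floored at zero) is recorded; drops are normalized to
#' sum to 100.
#'
#' @param model a fitted [fit_maxent()] model.
#' @param pres_env,bg_env the data the model was fitted on.
#' @param seed seed for the permutations.
#' @return named numeric vector of percentages summing to 100 (all zero
#'   when no variable matters).
#' @export
permutation_importance <- function(model, pres_env, bg_env, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pres_env <- as.data.frame(pres_env); bg_env <- as.data.frame(bg_env)
  all_env <- rbind(pres_env, bg_env)
  np <- nrow(pres_env)
  base_auc <- rank_auc(logistic_output(model, pres_env),
                       logistic_output(model, bg_env))
  vars <- names(model$feature_map)
  drops <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    perm <- all_env
    perm[[v]] <- sample(perm[[v]])
    s <- logistic_output(model, perm)
    drops[v] <- max(0, base_auc - rank_auc(s[seq_len(np)], s[-seq_len(np)]))
  }
  if (sum(drops) > 0) drops <- 100 * drops / sum(drops)
  drops
}

#' Predict a suitability map
#'
#' Cell-wise logistic suitability over a landscape; nodata cells
#' propagate.
#'
#' @param model a fitted [fit_maxent()] model.
#' @param landscape named list of `raster_layer`s covering the model's
#'   variables.
#' @return a continuous `raster_layer` named `"suitability"`.
#' @export
predict_map <- function(model, landscape) {
  vars <- names(model$feature_map)
  missing <- setdiff(vars, names(landscape))
  if (length(missing) > 0)
    stop("landscape lacks model variable layer(s): ",
         paste(missing, collapse = ", "))
  l1 <- landscape[[vars[1]]]
  env <- as.data.frame(lapply(landscape[vars], function(l) as.vector(l$values)))
  names(env) <- vars
  nod <- Reduce(`|`, lapply(vars, function(v)
    as.vector(landscape[[v]]$values) == landscape[[v]]$nodata))
  s <- rep(l1$nodata, nrow(env))
  s[!nod] <- logistic_output(model, env[!nod, , drop = FALSE])
  raster_layer(matrix(s, nrow(l1$values), ncol(l1$values)),
               name = "suitability", kind = "continuous",
               cellsize = l1$cellsize, xll = l1$xll, yll = l1$yll,
               nodata = l1$nodata)
}

#' Response curves
#'
#' For each variable, predicted logistic suitability along a grid
#' spanning its background range (or its levels), with every other
#' variable held at its background mean (continuous) or mode
#' (categorical).
#'
#' @param model a fitted [fit_maxent()] model.
#' @param n_grid grid points per continuous variable.
#' @return named list of data frames with columns `value` and
#'   `suitability`.
#' @export
response_curves <- function(model, n_grid = 100) {
  fm <- model$feature_map
  out <- list()
  for (v in names(fm)) {
    grid <- if (fm[[v]]$kind == "continuous")
      seq(fm[[v]]$min, fm[[v]]$max, length.out = n_grid)
    else fm[[v]]$levels
    env <- as.data.frame(model$bg_summary)[rep(1, length(grid)), , drop = FALSE]
    env[[v]] <- grid
    out[[v]] <- data.frame(value = grid,
                           suitability = logistic_output(model, env))
  }
  out
}

#' Pairwise linear correlation of continuous variables
#'
#' The collinearity pre-screen: reports the Pearson correlation matrix
#' of the continuous variables over the background; exclusion decisions
#' are left to the user.
#'
#' @param bg_env background environmental values.
#' @param kinds optional per-variable kinds; categorical columns are
#'   skipped.
#' @return correlation matrix.
#' @export
env_correlation <- function(bg_env, kinds = NULL) {
  bg_env <- as.data.frame(bg_env)
  if (!is.null(kinds))
    bg_env <- bg_env[, names(kinds)[kinds == "continuous"], drop = FALSE]
  stats::cor(bg_env)
}
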