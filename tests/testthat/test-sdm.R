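test_that("background sampling enumerates, reproduces, and is unbiased", {
  cfg <- small_sim(seed = 6)
  landscape <- gen_landscape(cfg)
  n_cells <- length(landscape[[1]]$values)
  full <- sample_background(landscape, n_cells, seed = 1)
  expect_equal(nrow(full), n_cells)
  expect_equal(sort(full$precipitation),
               sort(as.vector(landscape$precipitation$values)))
  s1 <- sample_background(landscape, 200, seed = 4)
  s2 <- sample_background(landscape, 200, seed = 4)
  expect_identical(s1, s2)
  expect_error(sample_background(landscape, n_cells + 1), "only")

  mu <- mean(landscape$precipitation$values)
  sdv <- stats::sd(landscape$precipitation$values)
  for (s in 1:10) {
    m <- mean(sample_background(landscape, 400, seed = s)$precipitation)
    expect_lt(abs(m - mu), 3 * sdv / sqrt(400))
  }
})

test_that("presences drawn uniformly from the background shrink to zero", {
  set.seed(30)
  bg <- data.frame(v = runif(2000), w = runif(2000))
  pres <- bg[sample(2000, 800), ]
  fit <- fit_maxent(pres, bg, beta = 0.05)
  expect_true(all(abs(fit$lambda) < 0.2))
})

test_that("the fitter recovers the 1-D exponential truth", {
  set.seed(31)
  bg <- data.frame(v = runif(3000))
  pres <- data.frame(v = sample(bg$v, 2000, replace = TRUE,
                                prob = exp(2 * bg$v)))
  fit <- suppressWarnings(fit_maxent(pres, bg, beta = 1e-4,
                                     quadratic = FALSE))
  expect_lt(abs(unname(fit$lambda["v"]) - 2), 0.15)
})

test_that("the optimizer is deterministic and order-invariant (concavity)", {
  set.seed(32)
  bg <- data.frame(a = runif(800), b = runif(800))
  pres <- data.frame(a = sample(bg$a, 300, replace = TRUE,
                                prob = exp(-2 * bg$a)),
                     b = runif(300))
  f1 <- fit_maxent(pres, bg, beta = 0.01)
  f2 <- fit_maxent(pres[sample(300), ], bg[sample(800), ], beta = 0.01)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-5)
})

test_that("the logistic transform has its stated fixed points", {
  set.seed(33)
  bg <- data.frame(v = runif(500))
  pres <- data.frame(v = runif(100))
  null_fit <- fit_maxent(pres, bg, beta = 10)   # heavy penalty -> lambda = 0
  expect_true(all(null_fit$lambda == 0))
  s <- logistic_output(null_fit, bg)
  # lambda = 0: every point carries the typical raw value e^(-H) -> 0.5
  expect_equal(s, rep(0.5, 500), tolerance = 1e-12)

  fit <- suppressWarnings(fit_maxent(
    data.frame(v = sample(bg$v, 400, TRUE, prob = exp(3 * bg$v))),
    bg, beta = 1e-3))
  grid <- data.frame(v = seq(0, 1, length.out = 100))
  sg <- logistic_output(fit, grid)
  eta <- as.vector(build_features(fit$feature_map, grid,
                                  fit$quadratic)[, fit$feature_names] %*%
                     fit$lambda)
  expect_true(all(diff(sg[order(eta)]) >= -1e-12))
  expect_true(all(sg > 0 & sg < 1))
})

test_that("the fitted background distribution is proper", {
  set.seed(34)
  bg <- data.frame(v = runif(600))
  pres <- data.frame(v = sample(bg$v, 200, TRUE, prob = exp(bg$v)))
  fit <- fit_maxent(pres, bg, beta = 0.01)
  X <- build_features(fit$feature_map, bg, fit$quadratic)[, fit$feature_names]
  q <- exp(as.vector(X %*% fit$lambda) - fit$zeta)
  expect_equal(sum(q), 1, tolerance = 1e-9)
  expect_gte(fit$entropy, 0)
})

test_that("rank AUC behaves at its extremes and under the null", {
  expect_equal(rank_auc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(rank_auc(c(1, 2), c(5, 6)), 0)
  expect_equal(rank_auc(c(1, 1), c(1, 1)), 0.5)   # all ties
  set.seed(35)
  bg <- data.frame(v = runif(1000))
  pres <- data.frame(v = sample(bg$v, 500, replace = TRUE))
  ev <- replicate_evaluate(pres, bg, n_replicates = 5, seed = 1, beta = 0.05)
  expect_lt(abs(ev$summary[["mean_test_auc"]] - 0.5), 0.05)
})

test_that("replicate splits are disjoint with the 75/25 rule", {
  set.seed(36)
  bg <- data.frame(v = runif(300))
  pres <- data.frame(v = runif(103))
  ev <- replicate_evaluate(pres, bg, n_replicates = 3, seed = 2, beta = 0.05)
  expect_equal(nrow(ev$replicates), 3)
  expect_true(all(ev$replicates$train_auc >= 0 & ev$replicates$train_auc <= 1))
  expect_error(replicate_evaluate(pres[1:3, , drop = FALSE], bg), ">= 4")
})

test_that("a strong two-variable signal reaches the high-AUC regime", {
  set.seed(37)
  bg <- data.frame(a = runif(2000), b = runif(2000))
  pres_idx <- sample(2000, 200, replace = TRUE,
                     prob = exp(-8 * bg$a + 4 * bg$b))
  pres <- bg[pres_idx, ]
  ev <- replicate_evaluate(pres, bg, n_replicates = 5, seed = 3, beta = 0.05)
  expect_gte(ev$summary[["mean_test_auc"]], 0.9)
})

test_that("permutation importance isolates the informative variable", {
  set.seed(38)
  bg <- data.frame(a = runif(1500), b = runif(1500))
  pres <- data.frame(a = sample(bg$a, 400, TRUE, prob = exp(-4 * bg$a)),
                     b = sample(bg$b, 400, TRUE))
  fit <- fit_maxent(pres, bg, beta = 0.02)
  imp <- permutation_importance(fit, pres, bg, seed = 1)
  expect_equal(sum(imp), 100, tolerance = 0.1)
  expect_gt(imp[["a"]], imp[["b"]])
  # a variable whose features all carry zero weight has zero importance
  fit0 <- fit
  fit0$lambda[grep("^b", names(fit0$lambda))] <- 0
  imp0 <- permutation_importance(fit0, pres, bg, seed = 1)
  expect_equal(imp0[["b"]], 0)
  # single-variable model -> importance 100
  fit1 <- fit_maxent(pres["a"], bg["a"], beta = 0.02)
  imp1 <- permutation_importance(fit1, pres["a"], bg["a"], seed = 1)
  expect_equal(unname(imp1), 100)
})

test_that("stronger coefficients dominate the importance ranking", {
  hits <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    bg <- data.frame(a = runif(800), b = runif(800))
    pres <- bg[sample(800, 250, TRUE, prob = exp(-4 * bg$a + 1 * bg$b)), ]
    fit <- fit_maxent(pres, bg, beta = 0.02)
    imp <- permutation_importance(fit, pres, bg, seed = s)
    if (imp[["a"]] > imp[["b"]]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("suitability maps agree with pointwise predictions", {
  cfg <- small_sim(seed = 8)
  landscape <- gen_landscape(cfg)
  acc <- gen_accessions(landscape, cfg)
  geo <- acc[acc$has_coordinates, ]
  kinds <- stats::setNames(vapply(landscape, `[[`, "", "kind"),
                           names(landscape))
  pres <- as.data.frame(extract_point_values(landscape, geo))
  bg <- sample_background(landscape, 800, seed = 1)[, names(landscape)]
  fit <- fit_maxent(pres, bg, kinds = kinds, beta = 0.05)
  map <- predict_map(fit, landscape)
  idx <- cbind(
    nrow(map$values) - floor((geo$y - map$yll) / map$cellsize),
    floor((geo$x - map$xll) / map$cellsize) + 1)
  expect_equal(unname(map$values[idx]),
               unname(logistic_output(fit, pres)), tolerance = 1e-10)
  expect_error(predict_map(fit, landscape["slope"]), "lacks")
})

test_that("response curves follow the sign of the fitted coefficient", {
  set.seed(39)
  bg <- data.frame(v = runif(1000))
  pres <- data.frame(v = sample(bg$v, 400, TRUE, prob = exp(-3 * bg$v)))
  fit <- fit_maxent(pres, bg, beta = 0.01)
  rc <- response_curves(fit, n_grid = 50)$v
  upper <- rc$suitability[rc$value > stats::median(bg$v)]
  expect_true(all(diff(upper) <= 1e-9))
  # constant model -> flat curve
  null_fit <- fit_maxent(pres, bg, beta = 10)
  rc0 <- response_curves(null_fit, n_grid = 10)$v
  expect_equal(rc0$suitability, rep(rc0$suitability[1], 10))
})

test_that("constant features are dropped with a warning", {
  bg <- data.frame(v = runif(100), k = rep(2, 100))
  pres <- data.frame(v = runif(30), k = rep(2, 30))
  kinds <- c(v = "continuous", k = "categorical")
  expect_warning(fit <- fit_maxent(pres, bg, kinds = kinds, beta = 0.05),
                 "constant feature")
  expect_false("k=2" %in% fit$feature_names)
})

test_that("the collinearity pre-screen reports a correlation matrix", {
  bg <- data.frame(a = 1:50, b = (1:50) * 2 + rnorm(50), c = rnorm(50))
  cm <- env_correlation(bg)
  expect_equal(dim(cm), c(3, 3))
  expect_gt(cm["a", "b"], 0.9)
})
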