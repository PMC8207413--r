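test_that("Gi* matches the brute-force formula on random configurations", {
  set.seed(101)
  for (r in 1:50) {
    n <- sample(5:30, 1)
    coords <- matrix(stats::runif(2 * n, 0, 10000), n, 2)
    x <- stats::rnorm(n)
    radius <- stats::runif(1, 500, 8000)
    z <- gi_star(x, coords, radius)
    expect_lt(max(abs(z - gi_star_brute(x, coords, radius))), 1e-10)
    p <- attr(z, "p")
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("degenerate Gi* denominators yield zero signal, not failure", {
  coords <- cbind(runif(10, 0, 1000), runif(10, 0, 1000))
  expect_equal(as.vector(gi_star(rep(3, 10), coords, 500)), rep(0, 10))
  # radius covering every point: W_i = n for all i
  expect_equal(as.vector(gi_star(rnorm(10), coords, 1e6)), rep(0, 10))
})

test_that("Gi* reproduces the collinear worked example", {
  coords <- cbind(seq(0, 4000, by = 1000), 0)
  z <- gi_star(1:5, coords, 1500)
  expect_lt(max(abs(z - gi_star_brute(1:5, coords, 1500))), 1e-12)
  expect_equal(z[3], 0)          # symmetric center
  expect_equal(z[1], -z[5])      # antisymmetric ends
})

test_that("single-cluster FCM has the closed form", {
  Z <- matrix(rnorm(40), 20, 2)
  f <- fcm(Z, 1)
  expect_equal(f$U, matrix(1, 20, 1))
  expect_equal(as.vector(f$V), colMeans(Z))
  expect_true(is.na(f$silhouette))
})

test_that("FCM memberships agree with a hand-coded update loop", {
  Z <- matrix(c(-0.1, 0, 0.1, 9.9, 10, 10.1), ncol = 1)
  f <- fcm(Z, 2, m = 2, seed = 1)
  expect_true(all(apply(f$U, 1, max) > 0.99))
  # independent oracle: explicit alternating updates from fixed centroids
  V <- matrix(c(0, 10), 2, 1)
  for (it in 1:200) {
    U <- matrix(0, 6, 2)
    for (i in 1:6) {
      d2 <- (Z[i, 1] - V[, 1])^2
      if (any(d2 == 0)) U[i, which.min(d2)] <- 1
      else U[i, ] <- (1 / d2) / sum(1 / d2)
    }
    for (c_ in 1:2) V[c_, 1] <- sum(U[, c_]^2 * Z[, 1]) / sum(U[, c_]^2)
  }
  ord <- if (f$V[1, 1] < f$V[2, 1]) 1:2 else 2:1
  expect_equal(f$U[, ord], U, tolerance = 1e-6)
  expect_equal(f$V[ord, , drop = FALSE], V, tolerance = 1e-6)
})

test_that("FCM memberships are a partition and the objective never increases", {
  set.seed(42)
  for (r in 1:5) {
    Z <- matrix(rnorm(60 * 3), 60, 3)
    f <- fcm(Z, 3, seed = r, restarts = 3)
    expect_equal(rowSums(f$U), rep(1, 60), tolerance = 1e-9)
    expect_true(all(f$U >= 0 & f$U <= 1))
    expect_true(all(diff(f$objective_trace) <= 1e-8))
    expect_identical(f$labels, apply(f$U, 1, which.max))
  }
})

test_that("FCM is equivariant under point reordering on separated data", {
  set.seed(7)
  Z <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 8, 0.3), 20, 2))
  perm <- sample(40)
  f1 <- fcm(Z, 2, seed = 1)
  f2 <- fcm(Z[perm, ], 2, seed = 2)
  # align cluster order via centroids
  ord <- if (sum(abs(f2$V[1, ] - f1$V[1, ])) < sum(abs(f2$V[2, ] - f1$V[1, ])))
    1:2 else 2:1
  expect_equal(f2$U[order(perm), ord], f1$U, tolerance = 1e-6)
})

test_that("FCM agrees with an established implementation on separated data", {
  skip_if_not_installed("e1071")
  set.seed(8)
  Z <- rbind(matrix(rnorm(60, 0, 0.5), 30, 2),
             matrix(rnorm(60, 6, 0.5), 30, 2))
  f <- fcm(Z, 2, seed = 1)
  cm <- e1071::cmeans(Z, 2, m = 2, iter.max = 500)
  ord <- if (sum(abs(cm$centers[1, ] - f$V[1, ])) <
             sum(abs(cm$centers[2, ] - f$V[1, ]))) 1:2 else 2:1
  expect_equal(unname(cm$membership[, ord]), unname(f$U), tolerance = 1e-3)
})

test_that("the silhouette index reproduces the worked example", {
  Z <- matrix(c(0, 1, 5), ncol = 1)
  s <- silhouette_index(Z, c(1, 1, 2))
  expect_equal(s, (0.8 + 0.75 + 0) / 3, tolerance = 1e-10)
})

test_that("silhouette stays in [-1, 1] and matches cluster::silhouette", {
  set.seed(9)
  for (r in 1:5) {
    Z <- matrix(rnorm(30 * 2), 30, 2)
    labels <- sample(1:3, 30, replace = TRUE)
    if (length(unique(labels)) < 2) next
    s <- silhouette_index(Z, labels)
    expect_gte(s, -1); expect_lte(s, 1)
    if (requireNamespace("cluster", quietly = TRUE) &&
        all(table(labels) > 1)) {
      ref <- mean(cluster::silhouette(labels, stats::dist(Z))[, "sil_width"])
      expect_equal(s, ref, tolerance = 1e-10)
    }
  }
  expect_error(silhouette_index(matrix(rnorm(10)), rep(1, 10)), "2 non-empty")
})

test_that("well-separated tight blobs approach silhouette 1", {
  Z <- rbind(matrix(rnorm(40, 0, 0.01), 20, 2),
             matrix(rnorm(40, 100, 0.01), 20, 2))
  expect_gt(silhouette_index(Z, rep(1:2, each = 20)), 0.95)
})

test_that("cluster-count selection finds the true number on blob data", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    Z <- rbind(matrix(rnorm(30 * 7, 0, 1), 30, 7),
               matrix(rnorm(30 * 7, 4, 1), 30, 7))
    sel <- select_clusters(Z, 2:4, seed = s, restarts = 5)
    if (sel$C == 2) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("an externally supplied C overrides the silhouette ranking", {
  set.seed(3)
  Z <- matrix(rnorm(50 * 3), 50, 3)
  sel <- select_clusters(Z, 2:4, seed = 1, C_external = 2, restarts = 5)
  expect_equal(sel$C, 2)
  tab <- attr(sel, "candidates")
  expect_equal(tab$C, 2:4)
})

test_that("a single candidate equals a plain best-of-restarts FCM fit", {
  set.seed(4)
  Z <- matrix(rnorm(40 * 2), 40, 2)
  sel <- select_clusters(Z, 2, seed = 11, restarts = 10)
  set.seed(11)
  ref <- fcm(Z, 2, restarts = 10)
  expect_equal(sel$objective, ref$objective, tolerance = 1e-12)
  expect_equal(sel$U, ref$U, tolerance = 1e-12)
})

test_that("degenerate clustering inputs are rejected", {
  Z <- matrix(rnorm(10), 5, 2)
  expect_error(fcm(Z, 6), "exceeds")
  expect_error(fcm(Z, 2, m = 1), "m must be > 1")
  expect_error(select_clusters(Z, integer(0)), "empty candidate")
  expect_error(select_clusters(Z, 5), "2..n-1")
})
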