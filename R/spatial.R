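#' Getis-Ord Gi* hot-spot statistic
#'
#' Local spatial-autocorrelation Z-score per point for one variable,
#' with binary distance-band weights (self included): `w_ij = 1` iff
#' `dist(i, j) <= radius`. For each point
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
#'   {S \sqrt{(n S1_i - W_i^2)/(n-1)}}}
#' with `W_i = sum_j w_ij`, `S1_i = sum_j w_ij^2` (equal to `W_i` for
#' binary weights), `X̄` the global mean and `S` the population standard
#' deviation. Degenerate denominators (constant variable, or a
#' neighborhood covering every point) carry no local signal and yield
#' Z = 0 rather than an error. A complementary two-sided standard-normal
#' p-value is attached as attribute `"p"`.
#'
#' @param x numeric vector of the variable at each point.
#' @param coords two-column matrix of point coordinates (m).
#' @param radius neighborhood radius in meters.
#' @return numeric vector of Z-scores with attribute `"p"`.
#' @export
gi_star <- function(x, coords, radius) {
  n <- length(x)
  stopifnot(n >= 2, radius > 0, nrow(coords) == n)
  d <- as.matrix(stats::dist(coords))
  W <- (d <= radius) * 1
  Wi <- rowSums(W)
  S1 <- Wi                       # binary weights
  xbar <- mean(x)
  S <- sqrt(mean(x^2) - xbar^2)
  num <- as.vector(W %*% x) - xbar * Wi
  den_inner <- (n * S1 - Wi^2) / (n - 1)
  z <- numeric(n)
  ok <- S > 0 & den_inner > 0
  z[ok] <- num[ok] / (S * sqrt(den_inner[ok]))
  p <- 2 * stats::pnorm(-abs(z))
  attr(z, "p") <- p
  z
}

#' Gi* Z-score matrix over all variables
#'
#' Applies [gi_star()] column-wise to an environmental matrix.
#'
#' @param env n x p matrix of environmental values (rownames = ids).
#' @param coords n x 2 coordinate matrix.
#' @param radius neighborhood radius in meters.
#' @return n x p matrix of Z-scores with attributes `"radius"` and
#'   `"p"` (matrix of two-sided p-values).
#' @export
gi_star_matrix <- function(env, coords, radius) {
  Z <- env * 0
  P <- env * 0
  for (j in seq_len(ncol(env))) {
    zj <- gi_star(env[, j], coords, radius)
    Z[, j] <- zj
    P[, j] <- attr(zj, "p")
  }
  attr(Z, "radius") <- radius
  attr(Z, "p") <- P
  Z
}

## one FCM run from given initial centroids; returns U, V, trace
fcm_run <- function(Z, V, m, tol, max_iter) {
  n <- nrow(Z); C <- nrow(V)
  expo <- 2 / (m - 1)
  U <- NULL
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(Z^2), rep(1, C)) +
      outer(rep(1, n), rowSums(V^2)) - 2 * Z %*% t(V)
    d2[d2 < 0] <- 0
    U <- matrix(0, n, C)
    zero <- d2 <= .Machine$double.eps
    has_zero <- rowSums(zero) > 0
    if (any(has_zero)) {
      U[has_zero, ] <- zero[has_zero, , drop = FALSE] /
        rowSums(zero[has_zero, , drop = FALSE])
    }
    if (any(!has_zero)) {
      ## u_ic = 1 / sum_k (d_ic/d_ik)^(2/(m-1)), written on squared
      ## distances: (d2_ic)^(-1/(m-1)) row-normalized
      inv <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
      U[!has_zero, ] <- inv / rowSums(inv)
    }
    Um <- U^m
    Vnew <- (t(Um) %*% Z) / colSums(Um)
    trace <- c(trace, sum(Um * d2))
    shift <- max(abs(Vnew - V))
    V <- Vnew
    if (shift < tol) break
  }
  ## final membership consistent with final centroids
  d2 <- outer(rowSums(Z^2), rep(1, C)) +
    outer(rep(1, n), rowSums(V^2)) - 2 * Z %*% t(V)
  d2[d2 < 0] <- 0
  zero <- d2 <= .Machine$double.eps
  U <- matrix(0, n, C)
  has_zero <- rowSums(zero) > 0
  if (any(has_zero))
    U[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  if (any(!has_zero)) {
    inv <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
    U[!has_zero, ] <- inv / rowSums(inv)
  }
  list(U = U, V = V, objective = sum(U^m * d2), trace = trace)
}

#' Fuzzy c-means clustering
#'
#' Alternating-update fuzzy c-means on a (Z-score) matrix with Euclidean
#' distances: membership `u_ic = 1 / sum_k (d_ic/d_ik)^(2/(m-1))`,
#' centroids `v_c = sum_i u_ic^m z_i / sum_i u_ic^m`. Points coincident
#' with a centroid get membership 1 there. Initial centroids are drawn
#' from distinct data rows; `restarts` independent starts are run and
#' the solution with the lowest objective is kept.
#'
#' @param Z numeric matrix (n x p), e.g. Gi* Z-scores.
#' @param C number of clusters (1 <= C <= n).
#' @param m fuzzifier (> 1); default 2.
#' @param tol convergence tolerance on the maximum centroid shift.
#' @param max_iter maximum alternating updates per start.
#' @param restarts number of random restarts.
#' @param seed optional seed controlling the restarts.
#' @return an object of class `fuzzy_clustering`: cluster count `C`,
#'   fuzzifier `m`, membership matrix `U` (rows sum to 1), centroids
#'   `V`, hard `labels` (argmax membership, ties to the lowest cluster
#'   index), `max_membership`, `objective`, per-iteration
#'   `objective_trace`, and `silhouette` (NA for C = 1).
#' @export
fcm <- function(Z, C, m = 2, tol = 1e-8, max_iter = 500, restarts = 20,
                seed = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (C < 1) stop("C must be >= 1")
  if (C > n) stop("C = ", C, " exceeds the number of points (", n, ")")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (!is.null(seed)) set.seed(seed)
  if (C == 1) {
    V <- matrix(colMeans(Z), 1, ncol(Z))
    U <- matrix(1, n, 1)
    d2 <- rowSums(sweep(Z, 2, V[1, ])^2)
    res <- list(U = U, V = V, objective = sum(d2), trace = sum(d2))
  } else {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- Z[sample.int(n, C), , drop = FALSE]
      ## nudge duplicated rows apart so centroids start distinct
      while (anyDuplicated(init) > 0)
        init <- Z[sample.int(n, C), , drop = FALSE]
      cand <- fcm_run(Z, init, m, tol, max_iter)
      if (is.null(best) || cand$objective < best$objective) best <- cand
    }
    res <- best
  }
  labels <- apply(res$U, 1L, which.max)   # ties -> lowest index
  sil <- if (C >= 2 && length(unique(labels)) >= 2)
    silhouette_index(Z, labels) else NA_real_
  structure(list(C = C, m = m, U = res$U, V = res$V,
                 labels = labels,
                 max_membership = apply(res$U, 1L, max),
                 silhouette = sil,
                 objective = res$objective,
                 objective_trace = res$trace),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf("<fuzzy_clustering: C = %d, m = %g, objective = %.4g, silhouette = %s>\n",
              x$C, x$m, x$objective,
              ifelse(is.na(x$silhouette), "NA", sprintf("%.3f", x$silhouette))))
  invisible(x)
}

#' Mean silhouette index
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean
#' within-cluster distance (self excluded) and `b(i)` the smallest mean
#' distance to another cluster; members of singleton clusters score 0.
#'
#' @param Z data matrix (Euclidean distances are used).
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @return mean silhouette over points, in [-1, 1].
#' @export
silhouette_index <- function(Z, labels) {
  Z <- as.matrix(Z)
  labs <- unique(labels)
  if (length(labs) < 2) stop("silhouette requires >= 2 non-empty clusters")
  d <- as.matrix(stats::dist(Z))
  n <- nrow(Z)
  s <- numeric(n)
  sizes <- table(factor(labels, levels = labs))
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1L) { s[i] <- 0; next }
    a <- mean(d[i, labels == own & seq_len(n) != i])
    b <- min(vapply(labs[labs != own],
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the number of fuzzy clusters
#'
#' Runs [fcm()] for every candidate C, computes the silhouette index of
#' each hard partition, and returns either the silhouette-optimal
#' clustering or, when `C_external` is supplied (e.g. the K chosen by
#' the genetic clustering), the clustering at that C regardless of
#' silhouette rank.
#'
#' @param Z input matrix (Gi* Z-scores).
#' @param candidates candidate cluster counts (subset of 2..n-1).
#' @param seed seed controlling the FCM restarts.
#' @param C_external optional externally imposed C.
#' @inheritParams fcm
#' @return the selected `fuzzy_clustering`, with a data frame of
#'   candidate silhouettes attached as attribute `"candidates"`.
#' @export
select_clusters <- function(Z, candidates, seed = NULL, C_external = NULL,
                            m = 2, restarts = 20, tol = 1e-8,
                            max_iter = 500) {
  if (length(candidates) == 0) stop("empty candidate set")
  n <- nrow(as.matrix(Z))
  if (any(candidates < 2 | candidates > n - 1))
    stop("candidates must lie in {2..n-1}")
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(candidates, function(C)
    fcm(Z, C, m = m, tol = tol, max_iter = max_iter, restarts = restarts))
  sil <- vapply(fits, function(f) f$silhouette, numeric(1))
  tab <- data.frame(C = candidates, silhouette = sil)
  pick <- if (!is.null(C_external)) {
    if (!C_external %in% candidates) {
      fits <- c(fits, list(fcm(Z, C_external, m = m, tol = tol,
                               max_iter = max_iter, restarts = restarts)))
      length(fits)
    } else which(candidates == C_external)
  } else which.max(sil)
  out <- fits[[pick]]
  attr(out, "candidates") <- tab
  out
}
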