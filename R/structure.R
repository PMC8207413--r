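## Recode allele sizes as per-locus state indices 1..A_l (0 = missing).
encode_alleles <- function(g) {
  n <- n_ind(g); L <- n_loci(g)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  n_alleles <- integer(L)
  states <- vector("list", L)
  for (l in seq_len(L)) {
    a <- c(g$alleles[, l, 1], g$alleles[, l, 2])
    lev <- sort(unique(a[a != 0]))
    states[[l]] <- lev
    n_alleles[l] <- length(lev)
    a1[, l] <- match(g$alleles[, l, 1], lev, nomatch = 0L)
    a2[, l] <- match(g$alleles[, l, 2], lev, nomatch = 0L)
  }
  list(a1 = a1, a2 = a2, n_alleles = n_alleles, states = states)
}

#' Bayesian admixture clustering (STRUCTURE-style Gibbs sampler)
#'
#' Gibbs sampler over the admixture model with independent
#' Dirichlet(lambda) cluster allele frequencies: allele-copy origins are
#' sampled proportional to `q_ik p_k(allele)`, ancestry rows from
#' `Dirichlet(alpha + origin counts)`, and cluster allele frequencies
#' from `Dirichlet(lambda + allele counts)`; missing alleles are
#' skipped. The reported Q and P are posterior means over the
#' post-burn-in sweeps, and the model evidence is summarized as
#' `lnPD = mean(lnL) - var(lnL)/2`.
#'
#' @param g an [ssr_matrix()].
#' @param K number of clusters (>= 1).
#' @param burn_in discarded initial sweeps.
#' @param n_sweeps post-burn-in sweeps kept for the posterior means.
#' @param alpha Dirichlet parameter of the ancestry prior.
#' @param lambda Dirichlet parameter of the allele-frequency prior.
#' @param seed optional seed (the sampler uses R's RNG).
#' @return an object of class `structure_run`: `K`, `Q` (n x K
#'   posterior-mean ancestry, rows sum to 1), `P` (per-locus K x A
#'   allele-frequency matrices with allele sizes as colnames),
#'   `lnl_trace`, `lnpd`, and `seed`.
#' @export
structure_gibbs <- function(g, K, burn_in = 500, n_sweeps = 2000,
                            alpha = 1, lambda = 1, seed = NULL) {
  if (K < 1) stop("K must be >= 1")
  if (n_sweeps < 2) stop("need at least 2 post-burn-in sweeps")
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_alleles(g)
  res <- gibbs_admix_cpp(enc$a1, enc$a2, enc$n_alleles, as.integer(K),
                         alpha, lambda, as.integer(burn_in),
                         as.integer(n_sweeps))
  Q <- res$Q
  Q <- Q / rowSums(Q)
  rownames(Q) <- g$ids
  P <- res$P
  for (l in seq_along(P)) colnames(P[[l]]) <- enc$states[[l]]
  names(P) <- g$loci
  lnl <- as.numeric(res$lnl)
  structure(list(K = K, Q = Q, P = P, lnl_trace = lnl,
                 lnpd = mean(lnl) - stats::var(lnl) / 2,
                 seed = seed),
            class = "structure_run")
}

#' @export
print.structure_run <- function(x, ...) {
  cat(sprintf("<structure_run: K = %d, n = %d, lnPD = %.2f>\n",
              x$K, nrow(x$Q), x$lnpd))
  invisible(x)
}

#' Evanno delta-K model choice
#'
#' For replicate runs at consecutive K: per K, the mean and standard
#' deviation of lnPD over runs, and
#' `deltaK = |mean(K+1) - 2 mean(K) + mean(K-1)| / sd(K)` for interior
#' K. The selected K is the argmax of deltaK. Interior K with zero sd
#' across runs are flagged and reported as NA.
#'
#' @param runs list of `structure_run` objects covering >= 3 consecutive
#'   K values with >= 2 runs each.
#' @return an object of class `delta_k_table`: data frame (`K`,
#'   `mean_lnpd`, `sd_lnpd`, `delta_k`, `flagged`) with the selected K
#'   as attribute `"selected_K"`.
#' @export
delta_k <- function(runs) {
  Ks <- vapply(runs, function(r) r$K, numeric(1))
  lnpd <- vapply(runs, function(r) r$lnpd, numeric(1))
  uK <- sort(unique(Ks))
  if (length(uK) < 3) stop("delta-K needs >= 3 consecutive K values")
  if (any(diff(uK) != 1)) stop("K values must be consecutive")
  if (any(table(Ks) < 2)) stop("each K needs >= 2 runs")
  mean_l <- vapply(uK, function(k) mean(lnpd[Ks == k]), numeric(1))
  sd_l <- vapply(uK, function(k) stats::sd(lnpd[Ks == k]), numeric(1))
  dk <- rep(NA_real_, length(uK))
  flagged <- rep(FALSE, length(uK))
  for (i in seq_along(uK)[-c(1, length(uK))]) {
    if (sd_l[i] == 0) { flagged[i] <- TRUE; next }
    dk[i] <- abs(mean_l[i + 1] - 2 * mean_l[i] + mean_l[i - 1]) / sd_l[i]
  }
  tab <- data.frame(K = uK, mean_lnpd = mean_l, sd_lnpd = sd_l,
                    delta_k = dk, flagged = flagged)
  sel <- if (all(is.na(dk))) NA_integer_ else uK[which.max(dk)]
  structure(tab, selected_K = sel, class = c("delta_k_table", "data.frame"))
}

#' Align cluster labels across replicate runs
#'
#' Greedy column matching of ancestry matrices to the first run:
#' repeatedly pairs the remaining reference/run column pair with the
#' highest correlation. Deterministic given run order.
#'
#' @param runs list of `structure_run` objects, all with the same K.
#' @return the runs with Q (and P) columns permuted into the reference
#'   order.
#' @export
align_labels <- function(runs) {
  Ks <- vapply(runs, function(r) r$K, numeric(1))
  if (length(unique(Ks)) != 1) stop("all runs must share the same K")
  K <- Ks[1]
  if (K == 1 || length(runs) < 2) return(runs)
  ref <- runs[[1]]$Q
  for (r in seq_along(runs)[-1]) {
    Q <- runs[[r]]$Q
    cm <- suppressWarnings(stats::cor(ref, Q))
    cm[!is.finite(cm)] <- 0
    perm <- integer(K)
    used_ref <- logical(K); used_q <- logical(K)
    for (step in seq_len(K)) {
      cm2 <- cm
      cm2[used_ref, ] <- -Inf
      cm2[, used_q] <- -Inf
      idx <- which(cm2 == max(cm2), arr.ind = TRUE)[1, ]
      perm[idx[1]] <- idx[2]
      used_ref[idx[1]] <- TRUE
      used_q[idx[2]] <- TRUE
    }
    runs[[r]]$Q <- Q[, perm, drop = FALSE]
    runs[[r]]$P <- lapply(runs[[r]]$P, function(m) m[perm, , drop = FALSE])
  }
  runs
}
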