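# analytic Dirichlet-multinomial marginal likelihood for K = 1, lambda = 1
k1_log_marginal <- function(g) {
  tot <- 0
  for (l in seq_along(g$loci)) {
    a <- c(g$alleles[, l, 1], g$alleles[, l, 2])
    a <- a[a != 0]
    tab <- table(a)
    A <- length(tab)
    tot <- tot + lgamma(A) - lgamma(A + length(a)) + sum(lgamma(1 + tab))
  }
  tot
}

test_that("ancestry rows are a partition and the sampler is reproducible", {
  g <- sim_two_pop(seed = 16, n_per = 15, L = 8, missing_rate = 0.1)
  r1 <- structure_gibbs(g, 3, burn_in = 100, n_sweeps = 300, seed = 5)
  r2 <- structure_gibbs(g, 3, burn_in = 100, n_sweeps = 300, seed = 5)
  expect_equal(unname(rowSums(r1$Q)), rep(1, 30), tolerance = 1e-9)
  expect_true(all(is.finite(r1$lnl_trace)))
  expect_true(is.finite(r1$lnpd))
  expect_identical(r1$Q, r2$Q)
  expect_identical(r1$lnl_trace, r2$lnl_trace)
})

test_that("K = 1 reduces to the analytic integrated likelihood", {
  g <- make_fixed_ssr(n_per = 3, L = 3)
  ana <- k1_log_marginal(g)
  for (s in 1:3) {
    r <- structure_gibbs(g, 1, burn_in = 500, n_sweeps = 4000, seed = s)
    expect_equal(unname(r$Q), matrix(1, 6, 1))
    expect_lt(abs(r$lnpd - ana), 2)
  }
})

test_that("fixed-allele populations are recovered almost perfectly", {
  g <- make_fixed_ssr(n_per = 25, L = 20)
  r <- structure_gibbs(g, 2, burn_in = 200, n_sweeps = 600, seed = 1)
  truth <- cbind(rep(c(1, 0), each = 25), rep(c(0, 1), each = 25))
  mae <- min(mean(abs(r$Q - truth)), mean(abs(r$Q - truth[, 2:1])))
  expect_lt(mae, 0.05)
  hard <- max.col(r$Q)
  acc <- max(mean(hard == rep(1:2, each = 25)),
             mean(hard == rep(2:1, each = 25)))
  expect_gte(acc, 0.95)
})

test_that("boundary-band individuals show intermediate ancestry", {
  cfg <- sim_config(seed = 19, target_fst = 0.3, n_loci = 20,
                    missing_rate = 0, n_populations = 2L)
  acc <- data.frame(id = sprintf("S%03d", 1:90),
                    true_population = rep(c(1L, 2L, 1L), c(40, 40, 10)))
  Q_true <- cbind(c(rep(1, 40), rep(0, 40), rep(0.5, 10)),
                  c(rep(0, 40), rep(1, 40), rep(0.5, 10)))
  attr(acc, "Q_true") <- Q_true
  g <- gen_ssr_genotypes(acc, cfg)
  r <- structure_gibbs(g, 2, burn_in = 300, n_sweeps = 1000, seed = 3)
  ## align to truth by the pure individuals
  ord <- if (mean(r$Q[1:40, 1]) > 0.5) 1:2 else 2:1
  Q <- r$Q[, ord]
  expect_gt(mean(Q[1:40, 1]), 0.9)
  expect_gt(mean(Q[41:80, 2]), 0.9)
  admixed <- Q[81:90, 1]
  expect_true(all(admixed > 0.2 & admixed < 0.8))
})

test_that("posterior means are stable when the kept chain is doubled", {
  g <- make_fixed_ssr(n_per = 10, L = 10)
  r1 <- structure_gibbs(g, 2, burn_in = 300, n_sweeps = 1000, seed = 2)
  r2 <- structure_gibbs(g, 2, burn_in = 300, n_sweeps = 2000, seed = 9)
  al <- align_labels(list(r1, r2))
  expect_lt(max(abs(al[[1]]$Q - al[[2]]$Q)), 0.02)
})

test_that("label alignment undoes column swaps and is a no-op for K = 1", {
  g <- sim_two_pop(seed = 17, n_per = 10, L = 8)
  r <- structure_gibbs(g, 3, burn_in = 100, n_sweeps = 300, seed = 1)
  swapped <- r
  swapped$Q <- r$Q[, c(3, 1, 2)]
  swapped$P <- lapply(r$P, function(m) m[c(3, 1, 2), , drop = FALSE])
  out <- align_labels(list(r, swapped))
  expect_equal(out[[2]]$Q, r$Q)
  r1 <- structure_gibbs(g, 1, burn_in = 50, n_sweeps = 100, seed = 1)
  expect_identical(align_labels(list(r1, r1)), list(r1, r1))
  expect_error(align_labels(list(r, r1)), "same K")
})

test_that("replicate runs agree after alignment on separable data", {
  g <- make_fixed_ssr(n_per = 15, L = 10)
  runs <- lapply(1:5, function(s)
    structure_gibbs(g, 2, burn_in = 200, n_sweeps = 500, seed = s))
  al <- align_labels(runs)
  Qs <- simplify2array(lapply(al, `[[`, "Q"))
  sds <- apply(Qs, 1:2, stats::sd)
  expect_lt(mean(sds), 0.1)
})

test_that("delta-K reproduces the hand table and degenerate cases", {
  mk <- function(K, lnpd) list(K = K, lnpd = lnpd)
  runs <- c(lapply(c(-5010, -4990), function(x) mk(1, x)),
            lapply(c(-4510, -4490), function(x) mk(2, x)),
            lapply(c(-4490, -4470), function(x) mk(3, x)),
            lapply(c(-4480, -4460), function(x) mk(4, x)))
  ## means (-5000, -4500, -4480, -4470), sds ~ 14.14
  tab <- delta_k(runs)
  sd2 <- stats::sd(c(-4510, -4490))
  expect_equal(tab$delta_k[2], 480 / sd2)
  expect_equal(tab$delta_k[3], 10 / stats::sd(c(-4490, -4470)))
  expect_equal(attr(tab, "selected_K"), 2)
  # all-equal sds of 10 recover the canonical 48 / 1 pair
  runs10 <- c(lapply(c(-5010, -5000, -4990), function(x) mk(1, x)),
              lapply(c(-4510, -4500, -4490), function(x) mk(2, x)),
              lapply(c(-4490, -4480, -4470), function(x) mk(3, x)),
              lapply(c(-4480, -4470, -4460), function(x) mk(4, x)))
  tab10 <- delta_k(runs10)
  expect_equal(tab10$sd_lnpd, rep(10, 4))
  expect_equal(tab10$delta_k[2], 48)
  expect_equal(tab10$delta_k[3], 1)

  # a linear lnPD profile has zero second differences everywhere
  lin <- unlist(lapply(1:4, function(K)
    lapply(c(-10, 10), function(e) mk(K, -6000 + 100 * K + e))),
    recursive = FALSE)
  expect_equal(delta_k(lin)$delta_k[2:3], c(0, 0))

  # zero spread at an interior K is flagged
  zs <- c(lapply(c(-5010, -4990), function(x) mk(1, x)),
          lapply(c(-4500, -4500), function(x) mk(2, x)),
          lapply(c(-4490, -4470), function(x) mk(3, x)))
  tz <- delta_k(zs)
  expect_true(tz$flagged[2])
  expect_true(is.na(tz$delta_k[2]))
  expect_error(delta_k(runs[1:4]), ">= 3 consecutive")
})
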