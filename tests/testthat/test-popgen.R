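test_that("diversity statistics reproduce the hand-worked locus", {
  # 4 individuals: (1/1), (1/2), (2/2), (1/2) coded as sizes 150/152
  g <- make_ssr(list(list(c(150, 150)), list(c(150, 152)),
                     list(c(152, 152)), list(c(150, 152))),
                pops = rep("p1", 4))
  d <- diversity_stats(g)$per_locus
  expect_equal(d$N, 4)
  expect_equal(d$Na, 2)
  expect_equal(d$Ne, 2)
  expect_equal(d$Ho, 0.5)
  expect_equal(d$He, 0.5)
  expect_equal(d$uHe, (8 / 7) * 0.5)
  expect_equal(d$F, 0)
})

test_that("monomorphic loci report fixed-allele statistics", {
  g <- make_ssr(list(list(c(150, 150)), list(c(150, 150)),
                     list(c(150, 150))), pops = rep("p1", 3))
  d <- diversity_stats(g)$per_locus
  expect_equal(d$Na, 1)
  expect_equal(d$Ne, 1)
  expect_equal(d$Ho, 0)
  expect_equal(d$He, 0)
  expect_true(is.na(d$F))
  expect_true(is.na(d$hwe_p))
})

test_that("per-population summaries carry means and standard errors", {
  g <- sim_two_pop(seed = 6, n_per = 20, L = 8)
  s <- diversity_stats(g)
  expect_setequal(unique(s$by_pop$population), c("pop1", "pop2"))
  ho <- s$by_pop[s$by_pop$statistic == "Ho", ]
  expect_true(all(ho$mean >= 0 & ho$mean <= 1))
  expect_true(all(is.finite(ho$se)))
})

test_that("the HWE chi-squared test reproduces hand arithmetic", {
  # 30 AA, 40 Aa, 30 aa; p = 0.5 -> expected 25/50/25 -> chi2 = 4
  genos <- c(rep(list(list(c(150, 150))), 30),
             rep(list(list(c(150, 152))), 40),
             rep(list(list(c(152, 152))), 30))
  g <- make_ssr(genos, pops = rep("p1", 100))
  hw <- hwe_test(g, 1)
  expect_equal(unname(hw["chi2"]), 4)
  expect_equal(unname(hw["df"]), 1)
  expect_equal(unname(hw["p"]), stats::pchisq(4, 1, lower.tail = FALSE))
})

test_that("counts at exact HWE proportions give chi2 = 0 and p = 1", {
  genos <- c(rep(list(list(c(150, 150))), 25),
             rep(list(list(c(150, 152))), 50),
             rep(list(list(c(152, 152))), 25))
  g <- make_ssr(genos, pops = rep("p1", 100))
  hw <- hwe_test(g, 1)
  expect_equal(unname(hw["chi2"]), 0)
  expect_equal(unname(hw["p"]), 1)
})

test_that("strong null-allele contamination is caught by the HWE test", {
  cfg <- sim_config(seed = 13, target_fst = 0.1, n_loci = 20,
                    null_allele_rate = 0.3, missing_rate = 0,
                    n_populations = 1L)
  acc <- data.frame(id = sprintf("S%03d", 1:200), true_population = 1L)
  g <- gen_ssr_genotypes(acc, cfg)
  p <- vapply(seq_along(g$loci), function(l) hwe_test(g, l)["p"], numeric(1))
  expect_gte(mean(p < 0.05, na.rm = TRUE), 0.8)
})

test_that("private alleles are counted per population", {
  same <- make_ssr(list(list(c(150, 152)), list(c(150, 152)),
                        list(c(150, 152)), list(c(150, 152))),
                   pops = rep(c("A", "B"), each = 2))
  expect_equal(unname(private_alleles(same)), c(0L, 0L))
  toy <- make_ssr(list(list(c(100, 104)), list(c(100, 104)),
                       list(c(100, 108)), list(c(100, 108))),
                  pops = rep(c("A", "B"), each = 2))
  expect_equal(private_alleles(toy), c(A = 1L, B = 1L))
})

test_that("null-allele estimators reproduce hand arithmetic", {
  # construct He = 0.75 (4 equifrequent alleles), Ho = 0.5
  genos <- list(list(c(150, 150)), list(c(152, 152)),
                list(c(154, 156)), list(c(150, 152)),
                list(c(154, 154)), list(c(156, 156)),
                list(c(150, 154)), list(c(152, 156)))
  g <- make_ssr(genos, pops = rep("p", 8))
  r <- null_allele_freq(g, 1)
  expect_equal(unname(r["chakraborty"]), (0.75 - 0.5) / (0.75 + 0.5))
  expect_equal(unname(r["brookfield1"]), (0.75 - 0.5) / 1.75)
  # Ho = He -> both zero: all heterozygotes over two equifrequent alleles
  g2 <- make_ssr(rep(list(list(c(150, 152))), 4), pops = rep("p", 4))
  r2 <- null_allele_freq(g2, 1)
  expect_equal(unname(r2["chakraborty"]), (0.5 - 1) / 1.5)
  expect_equal(unname(r2["brookfield1"]), (0.5 - 1) / 1.5 * 1.5 / 1.5)
})

test_that("AMOVA reproduces the hand-computed worked example exactly", {
  # 2 groups x 3 individuals, 2 loci; oracle = explicit enumeration of
  # all 12 gene copies per locus (frozen values)
  genos <- list(list(c(150, 150), c(150, 150)),
                list(c(150, 152), c(150, 154)),
                list(c(152, 152), c(154, 154)),
                list(c(160, 160), c(162, 164)),
                list(c(160, 162), c(164, 164)),
                list(c(160, 162), c(162, 162)))
  g <- make_ssr(genos, pops = rep(c("A", "B"), each = 3))
  am <- amova_fst(g, n_permutations = 99, seed = 1)
  expect_equal(am$table$SS[1], 37 / 12, tolerance = 1e-10)
  expect_equal(am$table$SS[2], 35 / 6, tolerance = 1e-10)
  expect_equal(am$table$SS[3], 107 / 12, tolerance = 1e-10)
  expect_equal(am$table$variance[1], 5 / 12, tolerance = 1e-10)
  expect_equal(am$table$variance[2], 7 / 12, tolerance = 1e-10)
  expect_equal(am$phi_st, 5 / 12, tolerance = 1e-10)
  expect_equal(sum(am$table$percent[1:2]), 100, tolerance = 0.1)
  expect_gt(am$p, 0); expect_lte(am$p, 1)
})

test_that("maximal differentiation yields FST = 1 with all variance among", {
  g <- make_fixed_ssr(n_per = 6, L = 5)
  am <- amova_fst(g, n_permutations = 99, seed = 1)
  expect_equal(am$phi_st, 1)
  expect_equal(am$table$percent[1], 100)
  expect_lt(am$p, 0.05)
})

test_that("a split panmictic sample shows no differentiation", {
  cfg <- sim_config(seed = 21, target_fst = 0.2, n_loci = 10,
                    missing_rate = 0, n_populations = 1L)
  acc <- data.frame(id = sprintf("S%03d", 1:60), true_population = 1L)
  g <- gen_ssr_genotypes(acc, cfg)
  fake <- rep(c("X", "Y"), each = 30)
  am <- amova_fst(g, grouping = fake, n_permutations = 99, seed = 2)
  expect_lt(abs(am$phi_st), 0.05)
  expect_gt(am$p, 0.05)
})

test_that("the FST estimate is invariant to relabeling and ordering", {
  g <- sim_two_pop(seed = 8, n_per = 15, L = 8)
  base <- amova_fst(g, n_permutations = 0)$phi_st
  # shift every allele size by one repeat unit (relabeling)
  g2 <- g; g2$alleles[g2$alleles != 0] <- g2$alleles[g2$alleles != 0] + 2L
  expect_equal(amova_fst(g2, n_permutations = 0)$phi_st, base,
               tolerance = 1e-12)
  # permute individuals
  perm <- sample(length(g$ids))
  g3 <- ssr_subset(g, perm)
  expect_equal(amova_fst(g3, n_permutations = 0)$phi_st, base,
               tolerance = 1e-12)
  expect_equal(wc_fst(g3), wc_fst(g), tolerance = 1e-12)
})

test_that("AMOVA and Weir-Cockerham agree on the drift-model scale", {
  phis <- c(); thetas <- c()
  for (s in 1:3) {
    g <- sim_two_pop(seed = 30 + s, fst = 0.15, n_per = 50)
    phis <- c(phis, amova_fst(g, n_permutations = 0)$phi_st)
    thetas <- c(thetas, wc_fst(g))
  }
  expect_lt(abs(mean(phis) - mean(thetas)), 0.03)
  expect_lt(abs(mean(phis) - 0.15), 0.05)
})

test_that("gene-flow estimates satisfy the island-model identity", {
  g <- sim_two_pop(seed = 12, n_per = 20, L = 10)
  am <- amova_fst(g, n_permutations = 0)
  fst <- am$pairwise$fst[1, 2]
  nm <- am$pairwise$nm[1, 2]
  expect_equal(nm * 4 * fst + fst, 1, tolerance = 1e-10)
  # the published pairing FST ~ 0.0367 <-> Nm ~ 6.5666 satisfies it too
  expect_equal((1 - 0.036675) / (4 * 0.036675), 6.5666, tolerance = 1e-3)
})
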