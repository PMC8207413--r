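# shared fixture builders (everything is generated in code)

# diploid SSR matrix from an n x L list of c(a1, a2) allele-size pairs
make_ssr <- function(genos, pops, repeat_lengths = 2L,
                     ids = sprintf("I%03d", seq_along(pops))) {
  n <- length(pops)
  L <- length(genos[[1]])
  al <- array(0L, dim = c(n, L, 2))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    al[i, l, 1] <- genos[[i]][[l]][1]
    al[i, l, 2] <- genos[[i]][[l]][2]
  }
  ssr_matrix(ids, pops, sprintf("L%02d", seq_len(L)),
             rep_len(as.integer(repeat_lengths), L), al)
}

# two-population toy fixed for different alleles at every locus
make_fixed_ssr <- function(n_per = 25, L = 20, sizes = c(152L, 158L)) {
  n <- 2 * n_per
  al <- array(0L, dim = c(n, L, 2))
  al[seq_len(n_per), , ] <- sizes[1]
  al[(n_per + 1):n, , ] <- sizes[2]
  ssr_matrix(sprintf("I%03d", seq_len(n)),
             rep(c("pop1", "pop2"), each = n_per),
             sprintf("L%02d", seq_len(L)), rep(2L, L), al)
}

# Balding-Nichols two-population simulation without spatial structure
sim_two_pop <- function(seed, fst = 0.15, n_per = 50, L = 20,
                        alleles = 8L, missing_rate = 0) {
  cfg <- sim_config(seed = seed, target_fst = fst, n_loci = L,
                    alleles_per_locus = alleles,
                    missing_rate = missing_rate,
                    n_populations = 2L)
  acc <- data.frame(id = sprintf("S%03d", seq_len(2 * n_per)),
                    true_population = rep(1:2, each = n_per))
  gen_ssr_genotypes(acc, cfg)
}

# independent brute-force Gi* (explicit loops, no matrix algebra)
gi_star_brute <- function(x, coords, radius) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    w <- numeric(n)
    for (j in seq_len(n))
      w[j] <- as.numeric(sqrt(sum((coords[i, ] - coords[j, ])^2)) <= radius)
    Wi <- sum(w)
    S1 <- sum(w^2)
    inner <- (n * S1 - Wi^2) / (n - 1)
    z[i] <- if (S > 0 && inner > 0)
      (sum(w * x) - xbar * Wi) / (S * sqrt(inner)) else 0
  }
  z
}

# tiny landscape config used across files
small_sim <- function(seed = 1, ...) {
  sim_config(seed = seed, nrow = 40L, ncol = 40L, n_accessions = 60L,
             n_no_coords = 5L, ...)
}
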