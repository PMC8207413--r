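## Allele frequency table for one locus within a set of individuals:
## named vector over observed allele sizes, from typed individuals only.
allele_freqs <- function(g, locus, ind = seq_along(g$ids)) {
  a <- c(g$alleles[ind, locus, 1], g$alleles[ind, locus, 2])
  a <- a[a != 0]
  if (length(a) == 0) return(numeric(0))
  tab <- table(a)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Per-locus, per-population diversity statistics
#'
#' For every population and locus: sample size N (typed individuals),
#' observed allele count Na, effective allele number `Ne = 1/sum p^2`,
#' observed heterozygosity Ho, expected heterozygosity
#' `He = 1 - sum p^2`, its unbiased version `uHe = 2N/(2N-1) * He`, the
#' fixation index `F = (He - Ho)/He` (NA when He = 0), and the
#' chi-squared Hardy-Weinberg test of [hwe_test()]. Per-population means
#' and standard errors over loci are attached.
#'
#' @param g an [ssr_matrix()].
#' @param grouping population label per individual; defaults to `g$pops`.
#' @return list with `per_locus` (data frame) and `by_pop` (means and
#'   SEs over loci per population).
#' @export
diversity_stats <- function(g, grouping = g$pops) {
  pops <- unique(grouping)
  rows <- list()
  for (pop in pops) {
    ind <- which(grouping == pop)
    if (length(ind) == 0) stop("empty group: ", pop)
    for (l in seq_along(g$loci)) {
      al <- g$alleles[ind, l, , drop = FALSE]
      typed <- al[, 1, 1] != 0
      N <- sum(typed)
      p <- allele_freqs(g, l, ind)
      if (N == 0) {
        rows[[length(rows) + 1]] <-
          data.frame(population = pop, locus = g$loci[l], N = 0,
                     Na = NA, Ne = NA, Ho = NA, He = NA, uHe = NA, F = NA,
                     hwe_chi2 = NA, hwe_df = NA, hwe_p = NA)
        next
      }
      Na <- length(p)
      Ne <- 1 / sum(p^2)
      Ho <- mean(al[typed, 1, 1] != al[typed, 1, 2])
      He <- 1 - sum(p^2)
      uHe <- (2 * N / (2 * N - 1)) * He
      Fi <- if (He > 0) (He - Ho) / He else NA_real_
      hw <- hwe_test(g, l, grouping = grouping, population = pop)
      rows[[length(rows) + 1]] <-
        data.frame(population = pop, locus = g$loci[l], N = N, Na = Na,
                   Ne = Ne, Ho = Ho, He = He, uHe = uHe, F = Fi,
                   hwe_chi2 = hw[1], hwe_df = hw[2], hwe_p = hw[3])
    }
  }
  per_locus <- do.call(rbind, rows)
  stat_cols <- c("N", "Na", "Ne", "Ho", "He", "uHe", "F")
  by_pop <- do.call(rbind, lapply(pops, function(pop) {
    sub <- per_locus[per_locus$population == pop, stat_cols, drop = FALSE]
    means <- vapply(sub, function(x) mean(x, na.rm = TRUE), numeric(1))
    ses <- vapply(sub, function(x) {
      x <- x[!is.na(x)]
      stats::sd(x) / sqrt(length(x))
    }, numeric(1))
    data.frame(population = pop, statistic = stat_cols,
               mean = means, se = ses, row.names = NULL)
  }))
  list(per_locus = per_locus, by_pop = by_pop)
}

#' Chi-squared Hardy-Weinberg equilibrium test
#'
#' Goodness-of-fit of observed genotype counts against Hardy-Weinberg
#' expectations computed from the observed allele frequencies. With k
#' alleles the degrees of freedom are `k(k-1)/2` (genotype classes minus
#' estimated frequencies). Genotype classes with expected count < 1 are
#' pooled into a single residual class for the chi-squared sum to keep
#' the statistic valid with many rare SSR alleles. Monomorphic loci are
#' reported as NA (test undefined).
#'
#' @param g an [ssr_matrix()].
#' @param locus locus index or name.
#' @param grouping population label per individual; by default all
#'   individuals are tested together.
#' @param population optional single population to restrict to.
#' @return named vector `c(chi2, df, p)`.
#' @export
hwe_test <- function(g, locus, grouping = NULL, population = NULL) {
  if (is.character(locus)) locus <- match(locus, g$loci)
  ind <- seq_along(g$ids)
  if (!is.null(population)) {
    if (is.null(grouping)) grouping <- g$pops
    ind <- which(grouping == population)
  }
  a1 <- g$alleles[ind, locus, 1]
  a2 <- g$alleles[ind, locus, 2]
  typed <- a1 != 0
  a1 <- a1[typed]; a2 <- a2[typed]
  N <- length(a1)
  if (N == 0) return(c(chi2 = NA, df = NA, p = NA))
  p <- allele_freqs(g, locus, ind)
  k <- length(p)
  if (k < 2) return(c(chi2 = NA, df = NA, p = NA))
  alleles <- as.integer(names(p))
  ## observed genotype counts (unordered pairs)
  key <- paste(pmin(a1, a2), pmax(a1, a2))
  obs_tab <- table(key)
  obs <- numeric(0); exp_ <- numeric(0)
  for (i in seq_len(k)) for (j in i:k) {
    kij <- paste(min(alleles[i], alleles[j]), max(alleles[i], alleles[j]))
    o <- if (kij %in% names(obs_tab)) as.numeric(obs_tab[[kij]]) else 0
    e <- if (i == j) N * p[i]^2 else 2 * N * p[i] * p[j]
    obs <- c(obs, o); exp_ <- c(exp_, e)
  }
  pool <- exp_ < 1
  if (any(pool)) {
    obs <- c(obs[!pool], sum(obs[pool]))
    exp_ <- c(exp_[!pool], sum(exp_[pool]))
  }
  keep <- exp_ > 0
  chi2 <- sum((obs[keep] - exp_[keep])^2 / exp_[keep])
  df <- k * (k - 1) / 2
  c(chi2 = chi2, df = df,
    p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Private allele counts per population
#'
#' Number of alleles observed in exactly one population, summed over
#' loci.
#'
#' @param g an [ssr_matrix()].
#' @param grouping population label per individual.
#' @return named integer vector, one count per population.
#' @export
private_alleles <- function(g, grouping = g$pops) {
  pops <- unique(grouping)
  if (length(pops) < 2) stop("private alleles require >= 2 groups")
  counts <- stats::setNames(integer(length(pops)), pops)
  for (l in seq_along(g$loci)) {
    sets <- lapply(pops, function(pop) {
      a <- c(g$alleles[grouping == pop, l, 1],
             g$alleles[grouping == pop, l, 2])
      unique(a[a != 0])
    })
    all_alleles <- unlist(sets)
    priv <- names(which(table(all_alleles) == 1))
    for (pi in seq_along(pops)) {
      counts[pi] <- counts[pi] + sum(sets[[pi]] %in% as.integer(priv))
    }
  }
  counts
}

#' Null allele frequency estimators
#'
#' Heterozygote-deficit estimators of the null allele frequency at one
#' locus: Chakraborty `r = (He - Ho)/(He + Ho)` and Brookfield-1
#' `r = (He - Ho)/(1 + He)`; both 0 by convention when He = Ho = 0.
#'
#' @param g an [ssr_matrix()].
#' @param locus locus index or name.
#' @param grouping optional restriction (label per individual plus
#'   `population`).
#' @param population optional single population.
#' @return named vector `c(chakraborty, brookfield1)`.
#' @export
null_allele_freq <- function(g, locus, grouping = NULL, population = NULL) {
  if (is.character(locus)) locus <- match(locus, g$loci)
  ind <- seq_along(g$ids)
  if (!is.null(population)) {
    if (is.null(grouping)) grouping <- g$pops
    ind <- which(grouping == population)
  }
  a1 <- g$alleles[ind, locus, 1]; a2 <- g$alleles[ind, locus, 2]
  typed <- a1 != 0
  if (!any(typed)) return(c(chakraborty = NA, brookfield1 = NA))
  Ho <- mean(a1[typed] != a2[typed])
  p <- allele_freqs(g, locus, ind)
  He <- 1 - sum(p^2)
  if (He == 0 && Ho == 0) return(c(chakraborty = 0, brookfield1 = 0))
  c(chakraborty = (He - Ho) / (He + Ho),
    brookfield1 = (He - Ho) / (1 + He))
}

#' Weir-Cockerham theta (FST)
#'
#' Multi-allele, multi-population Weir-Cockerham (1984) estimator,
#' combined over loci as the ratio of summed variance components. Used
#' as an independent cross-check of the AMOVA-based Phi-statistic.
#'
#' @param g an [ssr_matrix()].
#' @param grouping population label per individual.
#' @return theta estimate over all loci.
#' @export
wc_fst <- function(g, grouping = g$pops) {
  pops <- unique(grouping)
  r <- length(pops)
  if (r < 2) stop("wc_fst requires >= 2 populations")
  num <- 0; den <- 0
  for (l in seq_along(g$loci)) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    typed <- a1 != 0
    ni <- vapply(pops, function(pop) sum(typed & grouping == pop), numeric(1))
    if (sum(ni > 0) < 2) next
    use <- ni > 0
    ni <- ni[use]
    pops_l <- pops[use]
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (length(ni) - 1)
    alleles <- unique(c(a1[typed], a2[typed]))
    for (al in alleles) {
      pi_ <- vapply(pops_l, function(pop) {
        sel <- typed & grouping == pop
        mean(c(a1[sel], a2[sel]) == al)
      }, numeric(1))
      hi <- vapply(pops_l, function(pop) {
        sel <- typed & grouping == pop
        mean((a1[sel] == al) != (a2[sel] == al))
      }, numeric(1))
      pbar <- sum(ni * pi_) / sum(ni)
      s2 <- sum(ni * (pi_ - pbar)^2) / ((length(ni) - 1) * nbar)
      hbar <- sum(ni * hi) / sum(ni)
      rr <- length(ni)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (rr - 1) / rr * s2 -
                                hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (rr - 1) / rr * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}
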