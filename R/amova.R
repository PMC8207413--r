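#' Squared allele-mismatch distances between individuals
#'
#' Simple codominant genotype distance: per locus, the number of allele
#' differences between two diploid genotypes (two minus the size of the
#' best multiset match), summed over the loci typed in both individuals
#' and renormalized to the full locus count (`d2 * L / L_shared`). Used
#' as the alternative ordination metric next to [bruvo_distance()]. A
#' pair sharing no typed locus is an error naming the pair.
#'
#' @param g an [ssr_matrix()].
#' @return n x n symmetric matrix of squared distances (zero diagonal),
#'   with individual ids as dimnames.
#' @export
genotype_sqdist <- function(g) {
  n <- n_ind(g); L <- n_loci(g)
  diff <- matrix(0, n, n)
  shared <- matrix(0, n, n)
  for (l in seq_len(L)) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    typed <- a1 != 0
    m11 <- outer(a1, a1, "==")
    m12 <- outer(a1, a2, "==")
    m21 <- outer(a2, a1, "==")
    m22 <- outer(a2, a2, "==")
    ## best pairing of the two allele pairs: 2 matches iff the
    ## genotypes are equal as multisets, else 1 iff any allele is shared
    both <- (m11 & m22) | (m12 & m21)
    any1 <- m11 | m12 | m21 | m22
    matches <- matrix(0, n, n)
    matches[any1] <- 1
    matches[both] <- 2
    ok <- outer(typed, typed, "&")
    dl <- 2 - matches
    dl[!ok] <- 0
    diff <- diff + dl
    shared <- shared + ok
  }
  diag(shared) <- pmax(diag(shared), 1)
  if (any(shared == 0)) {
    w <- which(shared == 0, arr.ind = TRUE)[1, ]
    stop("individuals '", g$ids[w[1]], "' and '", g$ids[w[2]],
         "' share no typed locus")
  }
  d2 <- diff * L / shared
  diag(d2) <- 0
  dimnames(d2) <- list(g$ids, g$ids)
  d2
}

## Gene-copy cross-mismatch matrix: entry (i, j) is the number of
## differing pairs among the four allele-copy pairs between individuals
## i and j (the diagonal counts the two ordered within-individual
## pairs, i.e. 2 for a heterozygote), summed over loci typed in both
## and renormalized to the full locus count. Summing this matrix over
## (i, j) enumerates every ordered pair of the 2N gene copies, so the
## AMOVA built on it operates at the allele level without needing
## phase.
copy_mismatch_matrix <- function(g) {
  n <- n_ind(g); L <- n_loci(g)
  cross <- matrix(0, n, n)
  shared <- matrix(0, n, n)
  for (l in seq_len(L)) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    typed <- a1 != 0
    m11 <- outer(a1, a1, "!=")
    m12 <- outer(a1, a2, "!=")
    m21 <- outer(a2, a1, "!=")
    m22 <- outer(a2, a2, "!=")
    cl <- m11 + m12 + m21 + m22
    ok <- outer(typed, typed, "&")
    cl[!ok] <- 0
    cross <- cross + cl
    shared <- shared + ok
  }
  if (any(shared == 0)) {
    w <- which(shared == 0, arr.ind = TRUE)[1, ]
    stop("individuals '", g$ids[w[1]], "' and '", g$ids[w[2]],
         "' share no typed locus")
  }
  cross <- cross * L / shared
  dimnames(cross) <- list(g$ids, g$ids)
  cross
}

## Two-level AMOVA at the gene-copy level (2N units) from the
## individual cross-mismatch matrix. SS_total = sum of squared
## distances over ordered copy pairs / (2 * 2N); SS_within sums the
## same quantity per group. Variance components follow the standard
## mean-square equations with n0 the average (copy) group size
## correction; Phi_ST = sigma2_among / (sigma2_among + sigma2_within).
amova_components <- function(cross, grouping) {
  N <- nrow(cross)
  M <- 2 * N
  groups <- unique(grouping)
  G <- length(groups)
  ss_total <- sum(cross) / (2 * M)
  ss_within <- 0
  mg <- numeric(G)
  for (gi in seq_len(G)) {
    sel <- grouping == groups[gi]
    mg[gi] <- 2 * sum(sel)
    ss_within <- ss_within + sum(cross[sel, sel]) / (2 * mg[gi])
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1
  df_within <- M - G
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (M - sum(mg^2) / M) / (G - 1)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  phi <- if (max(0, sigma_among) + sigma_within <= 0) 0
         else max(0, sigma_among) / (max(0, sigma_among) + sigma_within)
  ## untruncated statistic for permutation comparisons: truncating at 0
  ## would pile permutation p-values at 1 under the null
  phi_raw <- if (sigma_among + sigma_within == 0) 0
             else sigma_among / (sigma_among + sigma_within)
  list(ss = c(among = ss_among, within = ss_within, total = ss_total),
       df = c(among = df_among, within = df_within, total = M - 1),
       ms = c(among = ms_among, within = ms_within),
       sigma = c(among = sigma_among, within = sigma_within),
       phi = phi, phi_raw = phi_raw)
}

#' Two-level AMOVA with permutation test, plus pairwise FST and Nm
#'
#' Analysis of molecular variance on allele mismatch counts, partitioned
#' among and within groups at the gene-copy level (the codominant
#' route, so the Phi-statistic estimates FST on the usual
#' allele-frequency scale). Loci missing in either member of a pair are
#' skipped with per-pair renormalization. Significance comes from
#' permuting individuals across groups
#' (`p = (count of permuted Phi >= observed + 1) / (n_perm + 1)`).
#' Pairwise FST between group pairs uses the same machinery on each
#' pair's submatrix; gene flow is `Nm = (1 - FST) / (4 FST)` (infinite
#' when FST = 0).
#'
#' @param g an [ssr_matrix()].
#' @param grouping group label per individual (>= 2 groups, each with
#'   >= 2 individuals); defaults to `g$pops`.
#' @param n_permutations permutations for the significance test.
#' @param seed seed for the permutations.
#' @param cross optional precomputed [copy-mismatch] matrix.
#' @return list with `table` (data frame: level, df, SS, variance
#'   component, percent of total), `phi_st` (reported as FST), `p`, and
#'   `pairwise` (matrices `fst`, `p`, `nm`).
#' @export
amova_fst <- function(g, grouping = NULL, n_permutations = 999,
                      seed = NULL, cross = NULL) {
  if (is.null(grouping)) grouping <- g$pops
  if (is.null(cross)) cross <- copy_mismatch_matrix(g)
  groups <- unique(grouping)
  if (length(groups) < 2) stop("AMOVA requires >= 2 groups")
  if (any(table(grouping) < 2)) stop("every group needs >= 2 individuals")
  if (!is.null(seed)) set.seed(seed)

  comp <- amova_components(cross, grouping)
  p <- NA_real_
  if (n_permutations > 0) {
    perm_phi <- replicate(n_permutations,
                          amova_components(cross, sample(grouping))$phi_raw)
    p <- (sum(perm_phi >= comp$phi_raw) + 1) / (n_permutations + 1)
  }

  sig <- pmax(comp$sigma, 0)
  pct <- if (sum(sig) > 0) 100 * sig / sum(sig) else c(0, 100)
  tab <- data.frame(
    level = c("among clusters", "within clusters", "total"),
    df = comp$df,
    SS = comp$ss,
    variance = c(comp$sigma, sum(comp$sigma)),
    percent = c(pct, 100),
    row.names = NULL
  )

  G <- length(groups)
  fst_m <- matrix(0, G, G, dimnames = list(groups, groups))
  p_m <- fst_m; nm_m <- fst_m
  diag(nm_m) <- Inf
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    sel <- grouping %in% groups[c(i, j)]
    sub <- amova_components(cross[sel, sel], grouping[sel])
    fst_m[i, j] <- fst_m[j, i] <- sub$phi
    if (n_permutations > 0) {
      pp <- replicate(n_permutations,
                      amova_components(cross[sel, sel],
                                       sample(grouping[sel]))$phi_raw)
      p_m[i, j] <- p_m[j, i] <- (sum(pp >= sub$phi_raw) + 1) / (n_permutations + 1)
    } else p_m[i, j] <- p_m[j, i] <- NA_real_
    nm_m[i, j] <- nm_m[j, i] <- if (sub$phi > 0)
      (1 - sub$phi) / (4 * sub$phi) else Inf
  }
  list(table = tab, phi_st = comp$phi, p = p,
       pairwise = list(fst = fst_m, p = p_m, nm = nm_m))
}
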