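#' Bruvo genetic distance matrix
#'
#' Microsatellite distance in repeat-unit space. For two alleles x, y at
#' a locus with repeat length u, the allele distance is
#' `d_a = 1 - 2^(-|x - y| / u)`. The distance between two diploid
#' genotypes is the minimum over the two perfect matchings of the mean
#' matched allele distance; the distance between two individuals is the
#' mean over loci typed in both (a pair with no shared typed locus is an
#' error naming the pair).
#'
#' @param g an [ssr_matrix()] with per-locus repeat lengths.
#' @param loci locus indices to use (the bootstrap resamples these).
#' @return n x n symmetric matrix (zero diagonal, entries in [0, 1)),
#'   ids as dimnames, with attribute `metric = "bruvo"`.
#' @export
bruvo_distance <- function(g, loci = seq_along(g$loci)) {
  n <- n_ind(g)
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  da <- function(x, y, u) 1 - 2^(-abs(x - y) / u)
  for (l in loci) {
    u <- g$repeat_lengths[l]
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    typed <- a1 != 0
    d11 <- da(outer(a1, a1, "-"), 0, u)
    d12 <- da(outer(a1, a2, "-"), 0, u)
    d21 <- da(outer(a2, a1, "-"), 0, u)
    d22 <- da(outer(a2, a2, "-"), 0, u)
    m1 <- (d11 + d22) / 2
    m2 <- (d12 + d21) / 2
    dl <- pmin(m1, m2)
    ok <- outer(typed, typed, "&")
    acc <- acc + dl * ok
    cnt <- cnt + ok
  }
  diag(cnt) <- pmax(diag(cnt), 1)
  if (any(cnt == 0)) {
    w <- which(cnt == 0, arr.ind = TRUE)[1, ]
    stop("individuals '", g$ids[w[1]], "' and '", g$ids[w[2]],
         "' share no typed locus")
  }
  d <- acc / cnt
  diag(d) <- 0
  dimnames(d) <- list(g$ids, g$ids)
  attr(d, "metric") <- "bruvo"
  d
}

#' Neighbor-joining tree with locus bootstrap support
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a genetic distance
#' matrix. Bootstrap support resamples loci with replacement,
#' recomputes the Bruvo distance and the NJ tree, and scores each
#' internal bipartition of the reported tree by the percentage of
#' replicates containing it. When outgroup ids are given the reported
#' tree is rooted on them.
#'
#' @param d distance matrix (e.g. from [bruvo_distance()]).
#' @param genotypes the [ssr_matrix()] used for locus resampling; when
#'   NULL no bootstrap is run.
#' @param n_boot number of bootstrap replicates.
#' @param seed seed for the resampling.
#' @param outgroup optional character vector of outgroup individual ids.
#' @return list with `tree` (an [ape::phylo] object), `support`
#'   (percent support per internal node, NA without bootstrap) and
#'   `newick` (the tree with supports as node labels).
#' @export
nj_tree <- function(d, genotypes = NULL, n_boot = 1000, seed = NULL,
                    outgroup = NULL) {
  if (any(!is.finite(as.matrix(d)))) stop("non-finite distances")
  if (nrow(as.matrix(d)) < 3) stop("NJ requires >= 3 leaves")
  tree <- ape::nj(stats::as.dist(d))
  support <- NULL
  if (!is.null(genotypes) && n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    L <- n_loci(genotypes)
    boots <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      loci <- sample.int(L, L, replace = TRUE)
      db <- bruvo_distance(genotypes, loci = loci)
      boots[[b]] <- ape::nj(stats::as.dist(db))
    }
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- 100 * counts / n_boot
    tree$node.label <- round(support, 1)
  }
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  list(tree = tree,
       support = support,
       newick = ape::write.tree(tree))
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square roots of their
#' (positive) eigenvalues. Negative eigenvalues are dropped from the
#' percent-variance denominator with a warning.
#'
#' @param d symmetric zero-diagonal distance matrix (n >= 3).
#' @param k number of axes to keep (default all positive).
#' @return list with `coordinates` (n x k, ids as rownames),
#'   `eigenvalues`, and `percent` variance per retained axis.
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("PCoA requires n >= 3")
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  if (any(ev < -sqrt(.Machine$double.eps) * max(abs(ev))))
    warning("negative eigenvalues dropped from the percent-variance denominator")
  pos <- which(ev > sqrt(.Machine$double.eps) * max(abs(ev)))
  if (length(pos) == 0) stop("no positive eigenvalues")
  if (is.null(k)) k <- length(pos)
  k <- min(k, length(pos))
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(k))
  list(coordinates = coords,
       eigenvalues = ev[pos],
       percent = 100 * ev[pos] / sum(ev[pos]))
}
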