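#' Aligned 2x2 cross-tabulation of two binary partitions
#'
#' Both partitions must label the same entities with exactly two
#' labels. The label correspondence maximizing the agreement count
#' `a + d` is chosen; the paired table (a = agree on cluster 1, b/c =
#' the two discordant cells, d = agree on cluster 2) and the chosen
#' mapping are returned.
#'
#' @param labels_a,labels_b named vectors (names = entity ids) or plain
#'   vectors in matching order.
#' @return list with `a`, `b`, `c`, `d`, `n` and `mapping`.
#' @export
crosstab_aligned <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (length(common) == 0) stop("no shared entity ids")
    labels_a <- labels_a[common]
    labels_b <- labels_b[common]
  }
  if (length(labels_a) != length(labels_b))
    stop("partitions must cover the same entities")
  la <- unique(labels_a); lb <- unique(labels_b)
  if (length(la) != 2 || length(lb) != 2)
    stop("both partitions must be binary")
  count <- function(map_b) {
    a <- sum(labels_a == la[1] & labels_b == map_b[1])
    b <- sum(labels_a == la[1] & labels_b == map_b[2])
    cc <- sum(labels_a == la[2] & labels_b == map_b[1])
    d <- sum(labels_a == la[2] & labels_b == map_b[2])
    list(a = a, b = b, c = cc, d = d)
  }
  t1 <- count(lb)
  t2 <- count(rev(lb))
  pick <- if (t1$a + t1$d >= t2$a + t2$d) list(tab = t1, map = lb)
          else list(tab = t2, map = rev(lb))
  c(pick$tab,
    list(n = length(labels_a),
         mapping = stats::setNames(as.character(pick$map), as.character(la))))
}

#' McNemar's chi-squared test on the discordant cells
#'
#' `chi2 = (|b - c| - 1)^2 / (b + c)` with the continuity correction
#' (the default), `(b - c)^2 / (b + c)` without; p from the upper tail
#' of chi-squared with 1 df. Both corrected and uncorrected statistics
#' are always reported. When `b + c = 0` the test is undefined and NA
#' is returned with an explanatory flag.
#'
#' @param table list with discordant counts `b` and `c` (e.g. from
#'   [crosstab_aligned()]), or the two counts themselves.
#' @param continuity_correction use the corrected statistic for the
#'   headline chi2/p.
#' @return list with `chi2`, `p`, `chi2_corrected`, `chi2_uncorrected`,
#'   `p_corrected`, `p_uncorrected`, and `undefined` flag.
#' @export
mcnemar_chi2 <- function(table, continuity_correction = TRUE) {
  b <- table$b; cc <- table$c
  if (b + cc == 0)
    return(list(chi2 = NA_real_, p = NA_real_,
                chi2_corrected = NA_real_, chi2_uncorrected = NA_real_,
                p_corrected = NA_real_, p_uncorrected = NA_real_,
                undefined = TRUE))
  chi_c <- (abs(b - cc) - 1)^2 / (b + cc)
  chi_u <- (b - cc)^2 / (b + cc)
  p_c <- stats::pchisq(chi_c, 1, lower.tail = FALSE)
  p_u <- stats::pchisq(chi_u, 1, lower.tail = FALSE)
  list(chi2 = if (continuity_correction) chi_c else chi_u,
       p = if (continuity_correction) p_c else p_u,
       chi2_corrected = chi_c, chi2_uncorrected = chi_u,
       p_corrected = p_c, p_uncorrected = p_u,
       undefined = FALSE)
}

#' PCA of ordinal morphology scores
#'
#' Principal component analysis of centered, unit-variance ordinal
#' codes (descriptors with zero variance are dropped with a warning).
#'
#' @param morph data frame from [gen_morphology()] /
#'   [read_morphology()]: `id`, optional `population`, then descriptor
#'   columns.
#' @return list with `scores`, `loadings`, `percent` variance per axis,
#'   and the retained descriptor names.
#' @export
morph_pca <- function(morph) {
  meta <- intersect(c("id", "population"), names(morph))
  X <- as.matrix(morph[, setdiff(names(morph), meta), drop = FALSE])
  if (nrow(X) < 3) stop("PCA needs >= 3 individuals")
  v <- apply(X, 2, stats::var)
  if (all(v == 0)) stop("all descriptors are constant")
  if (any(v == 0)) {
    warning("dropping zero-variance descriptor(s): ",
            paste(colnames(X)[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  rownames(pc$x) <- if ("id" %in% meta) morph$id else rownames(X)
  list(scores = pc$x, loadings = pc$rotation, percent = pct,
       descriptors = colnames(X))
}

#' Two-sample rank-sum test with mid-ranks and tie correction
#'
#' Wilcoxon-Mann-Whitney rank-sum test for two independent groups of
#' ordinal scores: mid-ranks for ties, the tie-corrected normal
#' approximation, and a two-sided p-value. The statistic is the rank
#' sum of the first group.
#'
#' @param scores numeric/ordinal scores.
#' @param groups two-level grouping vector (each group n >= 2).
#' @return list with `statistic` (rank sum of group 1), `z`, and `p`.
#' @export
rank_test <- function(scores, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  n <- n1 + n2
  r <- rank(scores)   # mid-ranks
  W <- sum(r[groups == levels(groups)[1]])
  mu <- n1 * (n + 1) / 2
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(statistic = W, z = 0, p = 1))
  z <- (W - mu) / sqrt(v)
  list(statistic = W, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Per-descriptor rank tests between two groups
#'
#' @param morph morphology data frame (`id`, descriptors).
#' @param groups two-level grouping aligned with the rows of `morph`.
#' @return data frame: descriptor, rank-sum statistic, z, p, and
#'   Benjamini-Hochberg adjusted p.
#' @export
morph_rank_tests <- function(morph, groups) {
  meta <- intersect(c("id", "population"), names(morph))
  desc <- setdiff(names(morph), meta)
  rows <- lapply(desc, function(d) {
    rt <- rank_test(morph[[d]], groups)
    data.frame(descriptor = d, statistic = rt$statistic, z = rt$z, p = rt$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
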