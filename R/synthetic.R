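#' Simulation configuration with known ground truth
#'
#' Collects every knob of the synthetic-data generators. Defaults define
#' the bundled desk-scale scenario: a 4.5 km x 4.5 km landscape at 30 m
#' resolution, 119 georeferenced accessions (plus 10 sampled but not
#' georeferenced) in two populations differentiated at FST 0.2 under a
#' Balding-Nichols drift model, 20 diploid SSR loci, and 20 ordinal
#' morphology descriptors with a group shift on the four hairiness
#' traits.
#'
#' @param seed integer master seed for the generators.
#' @param nrow,ncol grid shape in cells (each must be >= 8).
#' @param cellsize cell size in meters.
#' @param n_accessions number of georeferenced accessions.
#' @param n_no_coords additional accessions sampled without coordinates.
#' @param n_populations true number of populations (K_true).
#' @param target_fst Balding-Nichols drift parameter in (0, 1).
#' @param n_loci number of SSR loci.
#' @param alleles_per_locus ancestral allele count per locus.
#' @param repeat_length_bp SSR repeat unit length(s) in bp (recycled).
#' @param missing_rate per-genotype missing-data probability.
#' @param null_allele_rate per-allele-copy null (non-amplifying) rate.
#' @param admixture_gradient_width width (m) of the boundary band over
#'   which ancestry decays linearly between adjacent populations.
#' @param sdm_true_coefficients named vector of true suitability
#'   coefficients on min-max scaled continuous layers; these are what the
#'   niche model is expected to recover.
#' @param n_morph_descriptors number of ordinal descriptors.
#' @param morph_effect_sizes per-descriptor ordinal shift applied to
#'   population 1 (recycled/padded to `n_morph_descriptors`).
#' @param morph_levels number of ordinal levels (scores 1..morph_levels).
#' @param autocorr_range_cells Gaussian smoothing range (cells) used for
#'   every spatially autocorrelated continuous field.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       nrow = 150L, ncol = 150L, cellsize = 30,
                       n_accessions = 119L, n_no_coords = 10L,
                       n_populations = 2L,
                       target_fst = 0.2,
                       n_loci = 20L, alleles_per_locus = 8L,
                       repeat_length_bp = 3L,
                       missing_rate = 0.02, null_allele_rate = 0,
                       admixture_gradient_width = 600,
                       sdm_true_coefficients = c(dist_water = -4,
                                                 ndvi_summer = 2,
                                                 precipitation = 1),
                       n_morph_descriptors = 20L,
                       morph_effect_sizes = c(2, 2, 2, 2),
                       morph_levels = 9L,
                       autocorr_range_cells = 10) {
  cfg <- list(seed = as.integer(seed), nrow = as.integer(nrow),
              ncol = as.integer(ncol), cellsize = cellsize,
              n_accessions = as.integer(n_accessions),
              n_no_coords = as.integer(n_no_coords),
              n_populations = as.integer(n_populations),
              target_fst = target_fst, n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              repeat_length_bp = rep_len(as.integer(repeat_length_bp), n_loci),
              missing_rate = missing_rate,
              null_allele_rate = null_allele_rate,
              admixture_gradient_width = admixture_gradient_width,
              sdm_true_coefficients = sdm_true_coefficients,
              n_morph_descriptors = as.integer(n_morph_descriptors),
              morph_effect_sizes = {
                e <- rep(0, n_morph_descriptors)
                e[seq_along(morph_effect_sizes)] <- morph_effect_sizes
                e
              },
              morph_levels = as.integer(morph_levels),
              autocorr_range_cells = autocorr_range_cells)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$nrow < 8L || cfg$ncol < 8L)
    stop("degenerate grid: both dimensions must be >= 8 cells")
  if (cfg$cellsize <= 0) stop("cellsize must be positive")
  if (cfg$n_populations < 1L) stop("n_populations (K_true) must be >= 1")
  for (nm in c("missing_rate", "null_allele_rate"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(nm, " must lie in [0, 1]")
  if (cfg$target_fst <= 0 || cfg$target_fst >= 1)
    stop("target_fst must lie in the open interval (0, 1)")
  if (any(abs(cfg$morph_effect_sizes) > cfg$morph_levels - 1))
    stop("morphology effect sizes exceed the ordinal range")
  invisible(cfg)
}

## Dirichlet draws via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

## Separable Gaussian smoothing with edge replication; `range` is the
## kernel standard deviation in cells.
gauss_smooth <- function(m, range) {
  if (range <= 0) return(m)
  half <- max(1L, ceiling(3 * range))
  k <- stats::dnorm(seq(-half, half), sd = range)
  k <- k / sum(k)
  pad_rows <- function(x) x[c(rep(1L, half), seq_len(nrow(x)),
                              rep(nrow(x), half)), , drop = FALSE]
  smooth_cols <- function(x) {
    xp <- pad_rows(x)
    f <- stats::filter(xp, k, sides = 2)
    f[(half + 1L):(half + nrow(x)), , drop = FALSE]
  }
  out <- smooth_cols(m)
  out <- t(smooth_cols(t(out)))
  matrix(as.numeric(out), nrow(m), ncol(m))
}

## Smooth standardized random field (mean ~0, sd ~1).
smooth_field <- function(nr, nc, range) {
  f <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), range)
  (f - mean(f)) / stats::sd(f)
}

rescale01 <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

## Meandering north-south stream: one column index per row. `band`
## bounds the starting position (fractions of the grid width) so each
## subarea carries its own stream.
stream_path <- function(nr, nc, band = c(0.25, 0.75)) {
  start <- stats::runif(1, band[1], band[2]) * nc
  steps <- stats::rnorm(nr, 0, 1.2)
  path <- start + cumsum(stats::filter(c(rep(0, 10), steps), rep(0.2, 5),
                                       sides = 1)[-(1:10)])
  pmin(pmax(round(path), 1L), nc)
}

## Exact Euclidean distance (m) from every cell center to the nearest
## source cell center, brute force over source cells.
distance_transform <- function(nr, nc, cellsize, src_rc) {
  cx <- (seq_len(nc) - 0.5) * cellsize
  cy <- (nr - seq_len(nr) + 0.5) * cellsize
  sx <- (src_rc[, 2] - 0.5) * cellsize
  sy <- (nr - src_rc[, 1] + 0.5) * cellsize
  out <- matrix(Inf, nr, nc)
  dx2 <- outer(cx, sx, function(a, b) (a - b)^2)
  for (r in seq_len(nr)) {
    dy2 <- (cy[r] - sy)^2
    out[r, ] <- sqrt(apply(dx2 + rep(dy2, each = nc), 1L, min))
  }
  out
}

#' Generate a synthetic environmental landscape
#'
#' Produces 7 spatially autocorrelated continuous layers (slope, aspect,
#' distance-to-water, spring NDVI, summer NDVI, land surface temperature,
#' precipitation) and 3 categorical layers (soil, lithology, land cover).
#' Distance-to-water is the exact Euclidean distance transform of a
#' generated stream raster; summer NDVI declines with distance to water;
#' LST is negatively coupled to summer NDVI; precipitation is a linear
#' south-to-north gradient plus smooth noise; slope and aspect come from
#' a smooth synthetic elevation field by central finite differences.
#'
#' @param config a [sim_config()].
#' @return named list of `raster_layer`s (a landscape stack); the true
#'   stream mask is attached as attribute `"stream"`.
#' @export
gen_landscape <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nr <- config$nrow; nc <- config$ncol; cs <- config$cellsize
  rng <- config$autocorr_range_cells

  ## elevation -> slope/aspect
  yfrac <- matrix(rep((nr - seq_len(nr) + 0.5) / nr, nc), nr, nc)
  xfrac <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  elev <- 120 * smooth_field(nr, nc, rng) + 250 * xfrac + 60 * yfrac
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (elev[, 3:nc] - elev[, 1:(nc - 2)]) / (2 * cs)
  gx[, 1] <- (elev[, 2] - elev[, 1]) / cs
  gx[, nc] <- (elev[, nc] - elev[, nc - 1]) / cs
  gy[2:(nr - 1), ] <- (elev[1:(nr - 2), ] - elev[3:nr, ]) / (2 * cs)
  gy[1, ] <- (elev[1, ] - elev[2, ]) / cs
  gy[nr, ] <- (elev[nr - 1, ] - elev[nr, ]) / cs
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(gx, gy) * 180 / pi) %% 360

  ## streams and exact distance transform
  stream <- matrix(FALSE, nr, nc)
  for (band in list(c(0.10, 0.30), c(0.70, 0.90))) {
    cols <- stream_path(nr, nc, band)
    stream[cbind(seq_len(nr), cols)] <- TRUE
  }
  dist_water <- distance_transform(nr, nc, cs, which(stream, arr.ind = TRUE))

  ## the regional contrast (precipitation, temperature, spring NDVI)
  ## runs west-to-east, the axis along which the populations are split:
  ## two ecogeographically distinct subareas joined by a smooth
  ## transition of about the admixture-band width
  region <- stats::plogis((xfrac - 0.5) / 0.02)
  precipitation <- 350 + 60 * region + 12 * smooth_field(nr, nc, rng)
  dscale <- rescale01(dist_water)
  ndvi_summer <- pmin(pmax(0.75 - 0.35 * dscale +
                             0.10 * smooth_field(nr, nc, rng), 0.02), 0.95)
  ndvi_spring <- pmin(pmax(0.50 + 0.12 * smooth_field(nr, nc, rng) +
                             0.08 * (1 - dscale) + 0.15 * region, 0.05), 0.95)
  lst <- 46 - 20 * ndvi_summer - 6 * region + 1.5 * smooth_field(nr, nc, rng)

  cut_field <- function(k) {
    f <- smooth_field(nr, nc, rng)
    codes <- as.numeric(cut(f, stats::quantile(f, probs = seq(0, 1, length.out = k + 1)),
                            include.lowest = TRUE))
    matrix(codes, nr, nc)
  }
  soil <- cut_field(4L)
  lithology <- cut_field(3L)
  landcover <- cut_field(9L)

  mk <- function(v, name, kind = "continuous")
    raster_layer(v, name = name, kind = kind, cellsize = cs)
  landscape <- list(
    slope = mk(slope, "slope"),
    aspect = mk(aspect, "aspect"),
    dist_water = mk(dist_water, "dist_water"),
    ndvi_spring = mk(ndvi_spring, "ndvi_spring"),
    ndvi_summer = mk(ndvi_summer, "ndvi_summer"),
    lst = mk(lst, "lst"),
    precipitation = mk(precipitation, "precipitation"),
    soil = mk(soil, "soil", "categorical"),
    lithology = mk(lithology, "lithology", "categorical"),
    landcover = mk(landcover, "landcover", "categorical")
  )
  attr(landscape, "stream") <- stream
  landscape
}

continuous_layers <- function(landscape)
  names(landscape)[vapply(landscape, function(l) l$kind == "continuous",
                          logical(1))]

## True linear predictor eta from the configured coefficients on
## min-max scaled continuous layers. The logistic suitability surface
## is plogis(eta); occupancy weights are exp(eta), the exponential
## family the niche model fits, so the true coefficients are
## recoverable from the sampled presences.
true_eta <- function(landscape, config) {
  co <- config$sdm_true_coefficients
  l1 <- landscape[[1]]
  eta <- matrix(0, nrow(l1$values), ncol(l1$values))
  for (nm in names(co)) {
    if (!nm %in% names(landscape))
      stop("sdm_true_coefficients names an unknown layer: ", nm)
    eta <- eta + co[[nm]] * rescale01(landscape[[nm]]$values)
  }
  eta
}

true_suitability <- function(landscape, config)
  stats::plogis(true_eta(landscape, config))

#' Sample accession locations with known population structure
#'
#' Accession cells are drawn with occupancy weight `exp(eta)`, where
#' eta is the true linear predictor behind the logistic suitability
#' surface (uniform sampling when all true coefficients are zero), and
#' jittered uniformly within the cell. True populations are
#' vertical geographic bands of equal width; ancestry decays linearly
#' across a boundary band of width `admixture_gradient_width`, giving
#' admixed ground-truth ancestry near the interface. `n_no_coords`
#' additional accessions are emitted without coordinates.
#'
#' @param landscape output of [gen_landscape()].
#' @param config the same [sim_config()].
#' @return data frame with columns `id`, `x`, `y`, `region_label`,
#'   `true_population`, `sex`, `has_coordinates`; the true ancestry
#'   matrix is attached as attribute `"Q_true"`.
#' @export
gen_accessions <- function(landscape, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  l1 <- landscape[[1]]
  nr <- nrow(l1$values); nc <- ncol(l1$values); cs <- l1$cellsize
  wgt <- exp(true_eta(landscape, config))
  ok <- l1$values != l1$nodata
  idx_ok <- which(ok)
  n_geo <- config$n_accessions
  if (n_geo > length(idx_ok))
    stop("requested ", n_geo, " accessions but only ", length(idx_ok),
         " non-nodata cells are available")
  cells <- sample(idx_ok, n_geo, replace = TRUE, prob = wgt[idx_ok])
  rc <- arrayInd(cells, c(nr, nc))
  x <- (rc[, 2] - 1 + stats::runif(n_geo)) * cs + l1$xll
  y <- (nr - rc[, 1] + stats::runif(n_geo)) * cs + l1$yll

  K <- config$n_populations
  w <- config$admixture_gradient_width
  xmax <- nc * cs
  bounds <- seq(0, xmax, length.out = K + 1)
  Q <- matrix(0, n_geo, K)
  band <- pmin(pmax(findInterval(x, bounds, rightmost.closed = TRUE), 1L), K)
  for (i in seq_len(n_geo)) {
    Q[i, band[i]] <- 1
    if (K > 1 && w > 0) {
      for (b in 2:K) {
        d <- x[i] - bounds[b]
        if (abs(d) < w / 2) {
          frac <- 0.5 + d / w   # share of the right-hand population
          Q[i, ] <- 0
          Q[i, b - 1] <- 1 - frac
          Q[i, b] <- frac
        }
      }
    }
  }

  n_extra <- config$n_no_coords
  n_tot <- n_geo + n_extra
  if (n_extra > 0) {
    extra_pop <- sample.int(K, n_extra, replace = TRUE)
    Qe <- matrix(0, n_extra, K)
    Qe[cbind(seq_len(n_extra), extra_pop)] <- 1
    Q <- rbind(Q, Qe)
    x <- c(x, rep(NA_real_, n_extra))
    y <- c(y, rep(NA_real_, n_extra))
  }
  truepop <- max.col(Q, ties.method = "first")
  acc <- data.frame(
    id = sprintf("ACC%03d", seq_len(n_tot)),
    x = x, y = y,
    region_label = paste0("region", truepop),
    true_population = truepop,
    sex = sample(c("male", "female"), n_tot, replace = TRUE),
    has_coordinates = !is.na(x),
    stringsAsFactors = FALSE
  )
  attr(acc, "Q_true") <- Q
  acc
}

#' Simulate diploid SSR genotypes under a Balding-Nichols drift model
#'
#' Ancestral allele frequencies per locus are symmetric-Dirichlet draws;
#' population frequencies are Dirichlet with parameters
#' `p * (1 - F) / F`, so allele-frequency variance across populations is
#' calibrated to the target FST. Each allele copy of an individual is
#' drawn from the admixture-weighted mixture of population frequencies.
#' Allele states are emitted as fragment sizes `150 + state * repeat_bp`.
#' Null alleles silence individual allele copies: a heterozygote with one
#' silenced copy appears homozygous for the amplifying allele, and a
#' fully silenced genotype is missing. Missing genotypes use code 0.
#'
#' @param accessions data frame with a `true_population` column;
#'   ancestry weights are taken from its `"Q_true"` attribute when
#'   present (one-hot otherwise).
#' @param config a [sim_config()].
#' @return an [ssr_matrix()]; true population allele frequencies are
#'   attached as attribute `"true_freqs"`.
#' @export
gen_ssr_genotypes <- function(accessions, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(accessions)
  K <- config$n_populations
  L <- config$n_loci
  A <- config$alleles_per_locus
  Fst <- config$target_fst
  Q <- attr(accessions, "Q_true")
  if (is.null(Q)) {
    Q <- matrix(0, n, K)
    Q[cbind(seq_len(n), accessions$true_population)] <- 1
  }
  alleles <- array(0L, dim = c(n, L, 2))
  freqs <- vector("list", L)
  for (l in seq_len(L)) {
    p_anc <- rdirichlet1(rep(1, A))
    P <- matrix(0, K, A)
    for (k in seq_len(K))
      P[k, ] <- rdirichlet1(p_anc * (1 - Fst) / Fst)
    freqs[[l]] <- P
    rep_bp <- config$repeat_length_bp[l]
    for (copy in 1:2) {
      pop <- vapply(seq_len(n), function(i)
        sample.int(K, 1L, prob = Q[i, ]), integer(1))
      state <- vapply(seq_len(n), function(i)
        sample.int(A, 1L, prob = P[pop[i], ]), integer(1))
      alleles[, l, copy] <- 150L + state * rep_bp
    }
    ## null alleles: each copy silenced independently
    if (config$null_allele_rate > 0) {
      nul <- matrix(stats::runif(n * 2) < config$null_allele_rate, n, 2)
      one_null <- xor(nul[, 1], nul[, 2])
      both_null <- nul[, 1] & nul[, 2]
      keep <- ifelse(nul[, 1], alleles[, l, 2], alleles[, l, 1])
      alleles[one_null, l, 1] <- keep[one_null]
      alleles[one_null, l, 2] <- keep[one_null]
      alleles[both_null, l, ] <- 0L
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(n) < config$missing_rate
      alleles[miss, l, ] <- 0L
    }
  }
  g <- ssr_matrix(ids = accessions$id,
                  pops = paste0("pop", accessions$true_population),
                  loci = sprintf("SSR%02d", seq_len(L)),
                  repeat_lengths = config$repeat_length_bp,
                  alleles = alleles)
  attr(g, "true_freqs") <- freqs
  g
}

#' Simulate ordinal morphology scores
#'
#' Scores on an OIV-style ordinal scale (1..`morph_levels`), with a
#' configurable additive shift applied to population 1 on the designated
#' descriptors (by default the four leading "hairiness" descriptors).
#' Descriptors are correlated in two trait blocks — a hairiness block
#' (the four shifted descriptors) and a leaf-shape block (the next
#' three) — through shared per-individual latent factors, the way
#' related ampelographic traits co-vary on real plants.
#'
#' @param accessions data frame with `id` and `true_population`.
#' @param config a [sim_config()].
#' @return data frame: `id`, `population`, then one column per
#'   descriptor (`OIV004`, `OIV053`, `OIV084`, `OIV087`, `OIV067`, ...).
#' @export
gen_morphology <- function(accessions, config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  n <- nrow(accessions)
  D <- config$n_morph_descriptors
  lev <- config$morph_levels
  base_codes <- c("OIV004", "OIV053", "OIV084", "OIV087", "OIV067",
                  "OIV068", "OIV094")
  codes <- c(base_codes, sprintf("OIV%03d", 100 + seq_len(max(0, D - length(base_codes)))))[seq_len(D)]
  mu <- stats::runif(D, 3, lev - 2)
  shift <- config$morph_effect_sizes
  scores <- matrix(0L, n, D, dimnames = list(accessions$id, codes))
  grp1 <- accessions$true_population == 1L
  u_hair <- stats::rnorm(n)
  u_shape <- stats::rnorm(n)
  u_vigor <- stats::rnorm(n)   # weak general factor across all traits
  for (d in seq_len(D)) {
    block <- if (d <= 4) 1.4 * u_hair else if (d <= 7) 1.4 * u_shape else 0
    latent <- mu[d] + shift[d] * grp1 + block + 0.7 * u_vigor +
      stats::rnorm(n, 0, 0.9)
    scores[, d] <- pmin(pmax(round(latent), 1L), lev)
  }
  out <- cbind(data.frame(id = accessions$id,
                          population = accessions$true_population,
                          stringsAsFactors = FALSE),
               as.data.frame(scores))
  rownames(out) <- NULL
  out
}
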