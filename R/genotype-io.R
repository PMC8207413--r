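#' Diploid SSR genotype matrix
#'
#' Container for codominant microsatellite data: two allele fragment
#' sizes (bp) per individual per locus, with 0 marking a missing
#' genotype. Half-missing genotypes (one allele 0, the other typed) are
#' rejected.
#'
#' @param ids character vector of unique individual ids.
#' @param pops population label per individual.
#' @param loci locus names.
#' @param repeat_lengths repeat unit length (bp) per locus.
#' @param alleles integer array `n x L x 2` of allele sizes (0 missing).
#' @return an object of class `ssr_matrix`.
#' @export
ssr_matrix <- function(ids, pops, loci, repeat_lengths, alleles) {
  n <- length(ids); L <- length(loci)
  stopifnot(length(pops) == n, length(repeat_lengths) == L,
            identical(dim(alleles), c(n, L, 2L)) ||
              identical(dim(alleles), as.integer(c(n, L, 2))))
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (any(alleles < 0)) stop("allele sizes must be 0 (missing) or positive")
  half <- (alleles[, , 1, drop = FALSE] == 0) != (alleles[, , 2, drop = FALSE] == 0)
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype for individual '", ids[w[1]],
         "' at locus '", loci[w[2]], "'")
  }
  structure(list(ids = ids, pops = pops, loci = loci,
                 repeat_lengths = repeat_lengths,
                 alleles = alleles),
            class = "ssr_matrix")
}

#' @export
print.ssr_matrix <- function(x, ...) {
  cat(sprintf("<ssr_matrix: %d individuals x %d loci, %d populations>\n",
              length(x$ids), length(x$loci), length(unique(x$pops))))
  invisible(x)
}

n_ind <- function(g) length(g$ids)
n_loci <- function(g) length(g$loci)

## logical n x L: genotype typed at locus
typed_mask <- function(g) g$alleles[, , 1] != 0

#' Subset an ssr_matrix by individuals and/or loci
#' @param g an `ssr_matrix`.
#' @param ind indices or logical over individuals.
#' @param loci indices or logical over loci.
#' @export
ssr_subset <- function(g, ind = seq_along(g$ids), loci = seq_along(g$loci)) {
  ssr_matrix(g$ids[ind], g$pops[ind], g$loci[loci],
             g$repeat_lengths[loci],
             g$alleles[ind, loci, , drop = FALSE])
}

#' Write genotypes in a GenAlEx-style CSV layout
#'
#' Layout: row 1 = `n_loci, n_samples, n_pops, pop sizes...`; row 2 = a
#' free-text title; row 3 = header (`id, pop`, then two columns per
#' locus, the first carrying the locus name); data rows follow with
#' allele sizes in bp and 0 for missing. Repeat lengths are carried in
#' the title row as `name:repeat` tokens so files round-trip exactly.
#'
#' @param g an [ssr_matrix()].
#' @param path output path.
#' @export
write_genalex <- function(g, path) {
  pops <- unique(g$pops)
  sizes <- vapply(pops, function(p) sum(g$pops == p), integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(length(g$loci), length(g$ids), length(pops), sizes),
                   collapse = ","), con)
  writeLines(paste(c("ssr",
                     paste0(g$loci, ":", g$repeat_lengths)), collapse = ","),
             con)
  hdr <- c("id", "pop",
           as.vector(rbind(g$loci, rep("", length(g$loci)))))
  writeLines(paste(hdr, collapse = ","), con)
  for (i in seq_along(g$ids)) {
    row <- c(g$ids[i], g$pops[i],
             as.vector(t(g$alleles[i, , ])))
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

#' Write genotypes in STRUCTURE two-row format
#'
#' Two rows per individual (one per allele copy): `id pop a_1 ... a_L`,
#' whitespace-separated, with -9 coding missing data.
#'
#' @param g an [ssr_matrix()].
#' @param path output path.
#' @export
write_structure <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(g$loci, collapse = " "), con)
  pop_index <- as.integer(factor(g$pops, levels = unique(g$pops)))
  for (i in seq_along(g$ids)) {
    for (copy in 1:2) {
      a <- g$alleles[i, , copy]
      a[a == 0] <- -9L
      writeLines(paste(c(g$ids[i], pop_index[i], a), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read SSR genotypes
#'
#' Parses either the GenAlEx-style CSV written by [write_genalex()] or
#' the STRUCTURE two-row format of [write_structure()]. Loci whose
#' missing-data rate exceeds `max_missing` are flagged in the
#' `"flagged_loci"` attribute (marker-exclusion rule); parsing errors
#' report line numbers; half-missing genotypes are rejected with the
#' individual and locus named.
#'
#' @param path input file.
#' @param format `"genalex"` or `"structure"`.
#' @param max_missing missing-rate threshold above which a locus is
#'   flagged.
#' @param repeat_lengths repeat lengths for the STRUCTURE reader (that
#'   format does not carry them); recycled over loci.
#' @return an [ssr_matrix()].
#' @export
read_genotypes <- function(path, format = c("genalex", "structure"),
                           max_missing = 0.2, repeat_lengths = 2L) {
  format <- match.arg(format)
  g <- if (format == "genalex") read_genalex_file(path)
       else read_structure_file(path, repeat_lengths)
  miss <- colMeans(!typed_mask(g))
  attr(g, "flagged_loci") <- g$loci[miss > max_missing]
  g
}

read_genalex_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("GenAlEx file ", path, ": too short (line 1)")
  hdr <- suppressWarnings(as.integer(strsplit(lines[1], ",")[[1]]))
  if (length(hdr) < 3 || anyNA(hdr[1:3]))
    stop("GenAlEx file ", path, ": malformed counts header (line 1)")
  L <- hdr[1]; n <- hdr[2]
  title <- strsplit(lines[2], ",")[[1]]
  loci_tok <- title[-1]
  if (length(loci_tok) == L && all(grepl(":", loci_tok))) {
    loci <- sub(":.*$", "", loci_tok)
    rep_len <- as.integer(sub("^.*:", "", loci_tok))
  } else {
    h3 <- strsplit(lines[3], ",")[[1]]
    loci <- h3[seq(3, by = 2, length.out = L)]
    rep_len <- rep(2L, L)
  }
  if (length(lines) < 3 + n)
    stop("GenAlEx file ", path, ": expected ", n, " data rows, file ends at line ",
         length(lines))
  ids <- character(n); pops <- character(n)
  alleles <- array(0L, dim = c(n, L, 2))
  for (i in seq_len(n)) {
    ln <- 3 + i
    parts <- strsplit(lines[ln], ",")[[1]]
    if (length(parts) < 2 + 2 * L)
      stop("GenAlEx file ", path, ": too few fields on line ", ln)
    ids[i] <- parts[1]; pops[i] <- parts[2]
    vals <- suppressWarnings(as.integer(parts[3:(2 + 2 * L)]))
    if (anyNA(vals))
      stop("GenAlEx file ", path, ": non-numeric allele on line ", ln)
    m <- matrix(vals, nrow = 2)
    alleles[i, , 1] <- m[1, ]
    alleles[i, , 2] <- m[2, ]
  }
  ssr_matrix(ids, pops, loci, rep_len, alleles)
}

read_structure_file <- function(path, repeat_lengths) {
  lines <- readLines(path)
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  L <- length(loci)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) %% 2 != 0)
    stop("STRUCTURE file ", path, ": odd number of genotype rows (line ",
         length(lines), ")")
  n <- length(body) / 2
  ids <- character(n); pops <- character(n)
  alleles <- array(0L, dim = c(n, L, 2))
  for (i in seq_len(n)) {
    for (copy in 1:2) {
      ln <- 1 + (i - 1) * 2 + copy
      parts <- strsplit(trimws(body[(i - 1) * 2 + copy]), "\\s+")[[1]]
      if (length(parts) != 2 + L)
        stop("STRUCTURE file ", path, ": expected ", 2 + L,
             " fields on line ", ln, ", found ", length(parts))
      if (copy == 1) {
        ids[i] <- parts[1]; pops[i] <- paste0("pop", parts[2])
      } else if (parts[1] != ids[i]) {
        stop("STRUCTURE file ", path, ": row pair mismatch at line ", ln)
      }
      vals <- suppressWarnings(as.integer(parts[-(1:2)]))
      if (anyNA(vals))
        stop("STRUCTURE file ", path, ": non-numeric allele on line ", ln)
      vals[vals == -9L] <- 0L
      alleles[i, , copy] <- vals
    }
  }
  ssr_matrix(ids, pops, loci,
             repeat_lengths = rep_len_recycle(repeat_lengths, L),
             alleles = alleles)
}

rep_len_recycle <- function(x, L) rep_len(as.integer(x), L)

#' Write a Maxent-style samples-with-data CSV
#'
#' @param accessions data frame with `id`, `x`, `y` (georeferenced rows
#'   only are written).
#' @param env matrix of environmental values (rownames = ids).
#' @param path output path.
#' @param species species label for the first column.
#' @export
write_swd <- function(accessions, env, path, species = "species") {
  geo <- accessions[accessions$has_coordinates, , drop = FALSE]
  df <- data.frame(species = species, x = geo$x, y = geo$y,
                   env[geo$id, , drop = FALSE], check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a samples-with-data CSV
#' @param path input path.
#' @return data frame with `species`, `x`, `y` and variable columns.
#' @export
read_swd <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read the ordinal morphology table
#' @param morph data frame from [gen_morphology()].
#' @param path file path.
#' @export
write_morphology <- function(morph, path) {
  utils::write.csv(morph, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_morphology
#' @export
read_morphology <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
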