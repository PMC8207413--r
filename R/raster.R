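#' Environmental raster layer
#'
#' A light-weight in-memory grid used for all landscape data. Values are
#' stored as a numeric matrix whose first row is the northernmost row
#' (the ESRI ASCII grid convention). Coordinates are projected planar
#' meters; the grid origin is the lower-left corner of the extent.
#'
#' @param values numeric matrix (rows x cols), row 1 = north.
#' @param name layer name.
#' @param kind `"continuous"` or `"categorical"`.
#' @param cellsize cell edge length in meters.
#' @param xll,yll x/y coordinate of the lower-left corner of the extent.
#' @param nodata sentinel value marking missing cells.
#' @param levels for categorical layers, the declared category codes.
#' @return an object of class `raster_layer`.
#' @export
raster_layer <- function(values, name, kind = c("continuous", "categorical"),
                         cellsize = 30, xll = 0, yll = 0, nodata = -9999,
                         levels = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (cellsize <= 0) stop("`cellsize` must be positive")
  if (kind == "categorical") {
    if (is.null(levels)) levels <- sort(unique(values[values != nodata & !is.na(values)]))
    bad <- values[values != nodata & !is.na(values) & !(values %in% levels)]
    if (length(bad) > 0)
      stop("categorical layer '", name, "' contains undeclared codes: ",
           paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  structure(
    list(name = name, kind = kind, values = values, cellsize = cellsize,
         xll = xll, yll = yll, nodata = nodata, levels = levels),
    class = "raster_layer"
  )
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf("<raster_layer '%s' (%s): %d x %d cells @ %g m, origin (%g, %g)>\n",
              x$name, x$kind, nrow(x$values), ncol(x$values), x$cellsize,
              x$xll, x$yll))
  invisible(x)
}

#' @export
dim.raster_layer <- function(x) dim(x$values)

raster_extent <- function(layer) {
  c(xmin = layer$xll, xmax = layer$xll + ncol(layer$values) * layer$cellsize,
    ymin = layer$yll, ymax = layer$yll + nrow(layer$values) * layer$cellsize)
}

#' Matrix of non-missing cell values
#' @param layer a `raster_layer`.
#' @return numeric vector of values excluding nodata cells.
#' @export
raster_values <- function(layer) {
  v <- as.vector(layer$values)
  v[v != layer$nodata & !is.na(v)]
}

## Row/column of the cell containing each point (nearest-cell rule: a
## point anywhere strictly inside a cell maps to that cell; points on the
## shared edge between two cells belong to the cell to the north/east,
## matching floor() on the offset; points on the outer max edge are
## clamped into the grid).
cell_index <- function(layer, x, y) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  col <- floor((x - layer$xll) / layer$cellsize) + 1L
  row_from_bottom <- floor((y - layer$yll) / layer$cellsize) + 1L
  ext <- raster_extent(layer)
  col[x == ext["xmax"]] <- nc
  row_from_bottom[y == ext["ymax"]] <- nr
  inside <- col >= 1L & col <= nc & row_from_bottom >= 1L & row_from_bottom <= nr
  row <- nr - row_from_bottom + 1L
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  cbind(row = row, col = col)
}

## Center coordinates of every cell, in raster storage order
## (row-major, north row first).
cell_centers <- function(layer) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  cs <- layer$cellsize
  xs <- layer$xll + (seq_len(nc) - 0.5) * cs
  ys <- layer$yll + (nr - seq_len(nr) + 0.5) * cs
  list(x = matrix(rep(xs, each = nr), nr, nc),
       y = matrix(rep(ys, nc), nr, nc))
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param layer a `raster_layer`.
#' @param path output path (conventionally `.asc`).
#' @export
write_asc <- function(layer, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- layer$values
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", layer$xll),
    sprintf("yllcorner %.10g", layer$yll),
    sprintf("cellsize %.10g", layer$cellsize),
    sprintf("NODATA_value %.10g", layer$nodata)
  ), con)
  writeLines(apply(v, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to an `.asc` file.
#' @param name layer name; defaults to the file stem.
#' @param kind `"continuous"` or `"categorical"`.
#' @return a `raster_layer`.
#' @export
read_asc <- function(path, name = NULL,
                     kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path, " (line ", i, ")")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ESRI ASCII grid ", path, ": expected ", hdr$ncols * hdr$nrows,
         " values, found ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raster_layer(m, name = name, kind = kind, cellsize = hdr$cellsize,
               xll = hdr$xllcorner, yll = hdr$yllcorner, nodata = nodata)
}

#' Extract raster values at point locations
#'
#' Returns the value of the cell containing each point (nearest-cell
#' rule). Points outside the raster extent, or falling on a nodata
#' cell, are a hard error naming the offending accession.
#'
#' @param landscape named list of `raster_layer`s.
#' @param accessions data frame with columns `id`, `x`, `y`.
#' @param layers names of layers to extract; default all.
#' @return numeric matrix, one row per accession (rownames = ids), one
#'   column per layer.
#' @export
extract_point_values <- function(landscape, accessions,
                                 layers = names(landscape)) {
  stopifnot(all(layers %in% names(landscape)))
  out <- matrix(NA_real_, nrow(accessions), length(layers),
                dimnames = list(accessions$id, layers))
  for (ln in layers) {
    layer <- landscape[[ln]]
    idx <- cell_index(layer, accessions$x, accessions$y)
    bad <- which(is.na(idx[, "row"]))
    if (length(bad) > 0)
      stop("accession '", accessions$id[bad[1]],
           "' lies outside the extent of layer '", ln, "'")
    v <- layer$values[idx]
    nod <- which(v == layer$nodata)
    if (length(nod) > 0)
      stop("accession '", accessions$id[nod[1]],
           "' falls on a nodata cell of layer '", ln, "'")
    out[, ln] <- v
  }
  out
}
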