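# Single-band raster grids with geotransform metadata.
#
# Rasters are held in memory as a plain matrix plus an affine geotransform
# (lower-left corner, square cell size). On disk they are exchanged as ESRI
# ASCII grid (.asc), a header + whitespace-separated values text format that
# any GIS reads; coordinates are in the package's equal-area projection
# (reprojection of third-party rasters is the caller's concern).

#' Construct a raster layer
#'
#' @param values numeric matrix of cell values; row 1 is the northernmost
#'   row (map orientation).
#' @param xll,yll coordinates (m) of the lower-left corner of the grid.
#' @param cellsize cell edge length in metres (> 0); cells are square.
#' @param name layer name, e.g. `"bio01"` or `"elevation"`.
#' @param nodata value marking missing cells; converted to `NA` on read.
#' @return object of class `raster_layer`.
#' @export
raster_layer <- function(values, xll, yll, cellsize, name = "layer",
                         nodata = -9999) {
  values <- as.matrix(values)
  if (!nrow(values) || !ncol(values)) stop_divnn("raster grid is empty")
  if (!is.numeric(cellsize) || cellsize <= 0) {
    stop_divnn("raster cell size must be positive")
  }
  structure(
    list(values = values, xll = xll, yll = yll,
         cellsize = cellsize, name = name, nodata = nodata),
    class = "raster_layer"
  )
}

#' @export
print.raster_layer <- function(x, ...) {
  ext <- raster_extent(x)
  cat(sprintf(
    "raster_layer '%s': %d x %d cells of %g m, extent x [%g, %g] y [%g, %g]\n",
    x$name, nrow(x$values), ncol(x$values), x$cellsize,
    ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"]))
  invisible(x)
}

#' Raster extent
#'
#' @param layer a [raster_layer()].
#' @return named numeric vector `xmin, xmax, ymin, ymax` in metres.
#' @export
raster_extent <- function(layer) {
  c(xmin = layer$xll,
    xmax = layer$xll + ncol(layer$values) * layer$cellsize,
    ymin = layer$yll,
    ymax = layer$yll + nrow(layer$values) * layer$cellsize)
}

#' Read a raster from an ESRI ASCII grid file
#'
#' @param path path to a `.asc` file.
#' @param name layer name; defaults to the file name without extension.
#' @return a [raster_layer()]; nodata cells are `NA`.
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop_divnn("raster file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines)) stop_divnn("raster file is empty: %s", path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop_divnn("raster header missing field(s): %s", paste(miss, collapse = ", "))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop_divnn("raster %s: expected %d values, found %d",
               path, hdr$ncols * hdr$nrows, length(vals))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA_real_
  raster_layer(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
               name = name %||% tools::file_path_sans_ext(basename(path)),
               nodata = nodata)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param layer a [raster_layer()].
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path) {
  stopifnot(inherits(layer, "raster_layer"))
  m <- layer$values
  m[is.na(m)] <- layer$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", layer$xll),
    sprintf("yllcorner %.10g", layer$yll),
    sprintf("cellsize %.10g", layer$cellsize),
    sprintf("NODATA_value %.10g", layer$nodata)
  )
  rows <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Extract raster values at point locations
#'
#' Nearest-cell (point-in-cell) lookup: each point takes the value of the
#' cell containing it, with no interpolation. Nodata cells propagate as
#' `NA`. A point outside a layer's extent is an error naming the point.
#'
#' @param layers a single [raster_layer()] or a (named) list of them.
#' @param points data.frame with columns `x`, `y` in metres.
#' @return data.frame with one column per layer, rows parallel to `points`.
#' @export
extract_raster_values <- function(layers, points) {
  if (inherits(layers, "raster_layer")) layers <- list(layers)
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  out <- lapply(layers, function(layer) {
    ext <- raster_extent(layer)
    bad <- which(points$x < ext["xmin"] | points$x >= ext["xmax"] |
                 points$y < ext["ymin"] | points$y >= ext["ymax"])
    if (length(bad)) {
      stop_divnn("point %d (x=%g, y=%g) outside extent of raster '%s'",
                 bad[1], points$x[bad[1]], points$y[bad[1]], layer$name)
    }
    col <- floor((points$x - layer$xll) / layer$cellsize) + 1L
    row_from_bottom <- floor((points$y - layer$yll) / layer$cellsize) + 1L
    row <- nrow(layer$values) - row_from_bottom + 1L
    layer$values[cbind(row, col)]
  })
  names(out) <- vapply(layers, function(l) l$name, character(1))
  as.data.frame(out, optional = TRUE)
}
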