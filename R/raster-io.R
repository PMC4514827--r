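# Raster file I/O.
#
# Two formats are supported interchangeably:
#  * ESRI ASCII grid (.asc) — plain text, self-describing (carries the grid
#    origin and cell size in its header), nodata = -9999. The canonical
#    exchange format of this package.
#  * single-band float TIFF (.tif, via the `tiff` package) with a JSON
#    sidecar (<file>.grid.json) carrying the grid georeferencing, since a
#    plain TIFF has no geo tags.

ASC_NODATA <- -9999

#' Write a raster layer to an ESRI ASCII grid
#'
#' @param layer a \linkS4class{RasterLayer}.
#' @param path output path (conventionally \code{.asc}).
#' @param digits significant digits written (default 9, ample for float32
#'   round-trips).
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(layer, path, digits = 9) {
  g <- layer@grid
  v <- layer@values
  v[is.na(v)] <- ASC_NODATA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g@nCols),
    sprintf("nrows %d", g@nRows),
    sprintf("xllcorner %.10g", g@originX),
    sprintf("yllcorner %.10g", g@originY),
    sprintf("cellsize %.10g", g@cellSizeKm),
    sprintf("NODATA_value %d", ASC_NODATA)
  ), con)
  # ASCII grids store the northernmost row first; internal storage is
  # south-up, so flip.
  for (r in seq(g@nRows, 1L)) {
    writeLines(paste(formatC(v[r, ], digits = digits, format = "g"),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path input path.
#' @param name,units metadata for the returned layer (name defaults to the
#'   file stem).
#' @return a \linkS4class{RasterLayer}.
#' @export
readAsciiGrid <- function(path, name = NULL, units = "") {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("malformed ASCII grid header in ", path,
                         " (missing ", paste(miss, collapse = ", "), ")")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[seq(nr, 1L), , drop = FALSE]   # back to south-up storage
  nd <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else ASC_NODATA
  m[m == nd] <- NA
  g <- gridSpec(nr, nc, hdr$cellsize, hdr$xllcorner, hdr$yllcorner)
  rasterLayer(g, m, name = name %||% sub("\\.[^.]*$", "", basename(path)),
              units = units)
}

#' Write / read a raster layer, dispatching on file extension
#'
#' \code{.asc} uses the ESRI ASCII grid format; \code{.tif}/\code{.tiff}
#' writes a single-band 32-bit float TIFF plus a \code{.grid.json} sidecar
#' holding the grid georeferencing.
#'
#' @param layer a \linkS4class{RasterLayer}.
#' @param path file path.
#' @return \code{writeRasterLayer}: \code{path} invisibly;
#'   \code{readRasterLayer}: a \linkS4class{RasterLayer}.
#' @export
writeRasterLayer <- function(layer, path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "asc") return(writeAsciiGrid(layer, path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF output")
    g <- layer@grid
    v <- layer@values
    # the tiff package stores [0,1] floats; encode affinely and record the
    # transform in the sidecar (0 is reserved for nodata)
    rng <- range(v, na.rm = TRUE)
    span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    w <- (v - rng[1]) / span * 0.8 + 0.1
    w[is.na(v)] <- 0
    # TIFF rows run north to south
    tiff::writeTIFF(w[seq(g@nRows, 1L), , drop = FALSE], path,
                    bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(
      list(nrows = g@nRows, ncols = g@nCols, cellsize = g@cellSizeKm,
           xllcorner = g@originX, yllcorner = g@originY, crs = g@crsTag,
           value_min = rng[1], value_span = span,
           name = layer@name, units = layer@units),
      paste0(path, ".grid.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  stop("unsupported raster extension: .", ext)
}

#' @rdname writeRasterLayer
#' @param name,units metadata for the returned layer.
#' @export
readRasterLayer <- function(path, name = NULL, units = "") {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "asc") return(readAsciiGrid(path, name = name, units = units))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF input")
    side <- paste0(path, ".grid.json")
    if (!file.exists(side)) stop("missing grid sidecar: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    m <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m <- m[seq(nrow(m), 1L), , drop = FALSE]
    nodata <- m < 0.05
    m <- (m - 0.1) / 0.8 * meta$value_span + meta$value_min
    m[nodata] <- NA
    g <- gridSpec(meta$nrows, meta$ncols, meta$cellsize, meta$xllcorner,
                  meta$yllcorner, meta$crs)
    return(rasterLayer(g, m, name = name %||% meta$name,
                       units = if (nzchar(units)) units else meta$units))
  }
  stop("unsupported raster extension: .", ext)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
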