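#' Create a grid specification
#'
#' @param nRows,nCols grid dimensions.
#' @param cellSizeKm pixel edge length (km); the standard analysis frame uses
#'   1-km square pixels.
#' @param originX,originY planar coordinates (km) of the lower-left corner.
#' @param crsTag free-text label of the equal-area planar frame.
#' @return a \linkS4class{GridSpec}.
#' @examples
#' g <- gridSpec(100, 100)
#' pointToPixel(g, 5.5, 0.0)   # half-open convention: y = 0 is in row 1
#' @export
gridSpec <- function(nRows, nCols, cellSizeKm = 1, originX = 0, originY = 0,
                     crsTag = "synthetic-equal-area-km") {
  new("GridSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      cellSizeKm = as.numeric(cellSizeKm), originX = as.numeric(originX),
      originY = as.numeric(originY), crsTag = crsTag)
}

#' @keywords internal
sameGrid <- function(a, b, tol = 1e-9) {
  a@nRows == b@nRows && a@nCols == b@nCols &&
    abs(a@cellSizeKm - b@cellSizeKm) < tol &&
    abs(a@originX - b@originX) < tol && abs(a@originY - b@originY) < tol
}

#' Map planar points to pixel indices
#'
#' Uses the half-open pixel convention (lower-left edge inclusive): a point on
#' a shared pixel edge belongs to the pixel whose lower-left corner it touches.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param x,y planar coordinates (km), vectorized.
#' @return data.frame with integer columns \code{row}, \code{col}; \code{NA}
#'   for points outside the grid footprint.
#' @export
pointToPixel <- function(grid, x, y) {
  s <- grid@cellSizeKm
  col <- floor((x - grid@originX) / s) + 1L
  row <- floor((y - grid@originY) / s) + 1L
  bad <- col < 1L | col > grid@nCols | row < 1L | row > grid@nRows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Pixel center coordinates
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param row,col pixel indices (1-based, row 1 = southernmost), vectorized.
#' @return data.frame with planar \code{x}, \code{y} (km) of pixel centers.
#' @export
pixelCenter <- function(grid, row, col) {
  s <- grid@cellSizeKm
  data.frame(x = grid@originX + (col - 0.5) * s,
             y = grid@originY + (row - 0.5) * s)
}

#' Create a raster layer
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param values numeric matrix (nRows x nCols, row 1 = southernmost) or a
#'   single value to fill the grid; \code{NA} = nodata.
#' @param name,units layer metadata.
#' @return a \linkS4class{RasterLayer}.
#' @export
rasterLayer <- function(grid, values, name = "layer", units = "") {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid@nRows, grid@nCols)
  storage.mode(values) <- "double"
  new("RasterLayer", grid = grid, name = name, values = values, units = units)
}

# ---- deterministic per-stage seeding -----------------------------------

#' Derive a stage seed from a master seed and a label
#'
#' Random streams are isolated per pipeline stage: each stage's seed is a
#' stable hash of the master seed and the stage label, so changing one stage
#' (or adding a new one) never perturbs the draws of another.
#'
#' @param masterSeed integer master seed.
#' @param label stage label, e.g. \code{"sample_background:winter_pooled"}.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
stageSeed <- function(masterSeed, label) {
  stopifnot(length(label) == 1L, is.character(label))
  h <- as.numeric(masterSeed) %% 2147483647
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
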