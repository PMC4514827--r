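# Binary maps, the five-form ensemble, and point-exposure summaries.

#' Threshold a suitability surface into a binary map
#'
#' Pixel = 1 where suitability >= threshold, else 0 (the >= rule matches the
#' minimum-training-presence convention). Nodata propagates.
#'
#' @param surface a \linkS4class{RasterLayer} with values in [0, 1].
#' @param threshold classification threshold (typically the model's
#'   minimum-training-presence value).
#' @return a binary \linkS4class{RasterLayer}.
#' @export
binarize <- function(surface, threshold) {
  v <- surface@values
  out <- ifelse(v >= threshold, 1, 0)
  out[is.na(v)] <- NA
  rasterLayer(surface@grid, out, name = paste0(surface@name, "_binary"),
              units = "binary")
}

#' Average binary maps into an ensemble map
#'
#' Per-pixel arithmetic mean of the contributing binary maps — with five
#' forms, the fraction of forms classifying the pixel suitable, in
#' \{0, 0.2, 0.4, 0.6, 0.8, 1.0\}. A pixel that is nodata in any contributor
#' is nodata in the ensemble.
#'
#' @param binaryMaps named list of aligned binary \linkS4class{RasterLayer}s
#'   (names = contributing forms).
#' @param subset subset key label.
#' @return an \linkS4class{EnsembleMap}.
#' @export
ensembleMap <- function(binaryMaps, subset = "subset") {
  if (!length(binaryMaps)) stop("no binary maps supplied")
  g <- binaryMaps[[1]]@grid
  for (b in binaryMaps) {
    if (!sameGrid(b@grid, g)) stop("binary maps are not grid-aligned")
    v <- b@values
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop("map '", b@name, "' contains non-binary values")
  }
  acc <- Reduce(`+`, lapply(binaryMaps, function(b) b@values))
  new("EnsembleMap", grid = g, name = paste0("ensemble_", subset),
      values = acc / length(binaryMaps), units = "fraction of forms",
      subset = subset,
      forms = names(binaryMaps) %||% paste0("form", seq_along(binaryMaps)))
}

#' Extract map values at point locations
#'
#' Looks up the containing pixel of each point (half-open pixel convention,
#' consistent with occurrence rasterization). Points outside the grid or on
#' nodata pixels are excluded and counted.
#'
#' @param map a \linkS4class{RasterLayer} (e.g. an
#'   \linkS4class{EnsembleMap}).
#' @param points data.frame with planar \code{x_km}, \code{y_km} columns.
#' @return list with \code{values} (one per usable point, duplicates per
#'   pixel preserved) and \code{nExcluded}.
#' @export
extractAtPoints <- function(map, points) {
  if (!nrow(points)) stop("empty point list")
  px <- pointToPixel(map@grid, points$x_km, points$y_km)
  inGrid <- !is.na(px$row)
  vals <- rep(NA_real_, nrow(points))
  vals[inGrid] <- map@values[cbind(px$row[inGrid], px$col[inGrid])]
  ok <- !is.na(vals)
  list(values = vals[ok], nExcluded = sum(!ok))
}

#' @keywords internal
adjustedSkewness <- function(v) {
  n <- length(v)
  if (n < 3) return(NA_real_)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((v - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Summarize point-exposure values
#'
#' Mean, range, a 10-bin (by default) equal-width histogram on [0, 1]
#' (right-closed last bin), and adjusted Fisher-Pearson sample skewness.
#' Left (negative) skewness indicates values piled toward high suitability —
#' i.e. strong overlap between suitable habitat and the point set.
#'
#' @param values numeric vector of extracted suitabilities.
#' @param nBins number of histogram bins.
#' @param subset subset key label.
#' @param nExcluded count of excluded points to carry in the summary.
#' @return an \linkS4class{ExposureSummary}.
#' @export
exposureSummary <- function(values, nBins = 10, subset = "subset",
                            nExcluded = 0) {
  if (length(values) < 2)
    stop("need at least two values to summarize exposure")
  breaks <- seq(0, 1, length.out = nBins + 1)
  idx <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L),
              nBins)
  counts <- tabulate(idx, nbins = nBins)
  new("ExposureSummary", subset = subset, n = length(values),
      nExcluded = as.integer(nExcluded),
      mean = mean(values), min = min(values), max = max(values),
      histBreaks = breaks, histCounts = as.integer(counts),
      skewness = adjustedSkewness(values))
}
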