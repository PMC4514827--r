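# Seasonal predictor construction from monthly rasters, pairwise correlation
# screening, background sampling and training-table assembly.

#' Months contributing to each seasonal covariate
#'
#' Matches the occurrence season bins: winter = Dec, Jan, Feb; spring =
#' Mar-May; summer = Jun, Jul; autumn = Aug-Nov. (The source monthly climate
#' layers are calendar-month summaries; using the same month sets for the
#' response and the covariates keeps the two aligned.)
#'
#' @param season season name.
#' @return integer vector of month numbers.
#' @export
seasonMonths <- function(season) {
  switch(season, winter = c(12L, 1L, 2L), spring = 3:5, summer = 6:7,
         autumn = 8:11, stop("unknown season: ", season))
}

#' @keywords internal
checkMonthlyStack <- function(monthly) {
  if (length(monthly) != 12L) stop("need 12 monthly layers")
  g <- monthly[[1]]@grid
  for (ly in monthly) if (!sameGrid(ly@grid, g))
    stop("monthly layers are not grid-aligned")
  g
}

#' Mean seasonal temperature from monthly means
#'
#' Per-pixel arithmetic mean of the season's monthly mean-temperature layers.
#' Nodata in any contributing month propagates to the output pixel. Inputs
#' in the WorldClim integer convention (tenths of a degree C) are rescaled to
#' degrees C when \code{inTenths = TRUE}.
#'
#' @param monthlyMeans list of 12 aligned \linkS4class{RasterLayer}s
#'   (January first).
#' @param season season name.
#' @param inTenths logical; divide inputs by 10 (WorldClim \code{degC*10}).
#' @return a \linkS4class{RasterLayer} named \code{temp_season}.
#' @export
seasonalMeanTemperature <- function(monthlyMeans, season, inTenths = FALSE) {
  g <- checkMonthlyStack(monthlyMeans)
  months <- seasonMonths(season)
  acc <- Reduce(`+`, lapply(monthlyMeans[months], function(l) l@values))
  v <- acc / length(months)
  if (inTenths) v <- v / 10
  rasterLayer(g, v, name = "temp_season", units = "degC")
}

#' Adjacent-season mean temperature
#'
#' Prior-season mean temperature is a predictor for winter, spring and
#' summer (e.g. autumn conditions may shape where bats settle for winter);
#' the autumn models instead use the mean temperature of the following
#' winter. Any other season/direction pair is rejected.
#'
#' @inheritParams seasonalMeanTemperature
#' @param direction \code{"prior"} or \code{"next"}.
#' @return a \linkS4class{RasterLayer} named \code{temp_adjacent}.
#' @export
adjacentSeasonTemperature <- function(monthlyMeans, season,
                                      direction = c("prior", "next"),
                                      inTenths = FALSE) {
  direction <- match.arg(direction)
  allowed <- list(winter = "prior", spring = "prior", summer = "prior",
                  autumn = "next")
  if (!identical(allowed[[season]], direction))
    stop("direction '", direction, "' is not defined for season '", season,
         "' (winter/spring/summer use prior, autumn uses next)")
  cycle <- c("winter", "spring", "summer", "autumn")
  i <- match(season, cycle)
  adj <- if (direction == "prior") cycle[(i - 2) %% 4 + 1] else cycle[i %% 4 + 1]
  out <- seasonalMeanTemperature(monthlyMeans, adj, inTenths = inTenths)
  out@name <- "temp_adjacent"
  out
}

#' Mean seasonal temperature range from monthly range layers
#'
#' Per-pixel mean of the season's monthly temperature-range (BIO7-style)
#' values, rescaled from tenths of a degree when \code{inTenths = TRUE}
#' (the WorldClim-derived convention). Nodata propagates.
#'
#' @param monthlyRanges list of 12 aligned \linkS4class{RasterLayer}s.
#' @param season season name.
#' @param inTenths logical; divide inputs by 10.
#' @return a \linkS4class{RasterLayer} named \code{temp_range}.
#' @export
seasonalTemperatureRange <- function(monthlyRanges, season, inTenths = TRUE) {
  out <- seasonalMeanTemperature(monthlyRanges, season, inTenths = inTenths)
  out@name <- "temp_range"
  out
}

#' Assemble one season's predictor stack
#'
#' Builds the season's covariate set in the standard layout: seasonal mean
#' temperature, adjacent-season temperature (prior season, or next season
#' for autumn), seasonal temperature range, and the static layers
#' (precipitation seasonality, growing-season length, tree cover, ...).
#'
#' @param season season name.
#' @param monthlyMeans,monthlyRanges lists of 12 aligned layers.
#' @param static named list of static \linkS4class{RasterLayer}s.
#' @param meansInTenths,rangesInTenths unit conventions of the monthly inputs.
#' @return a \linkS4class{PredictorStack}.
#' @export
buildSeasonStack <- function(season, monthlyMeans, monthlyRanges, static,
                             meansInTenths = FALSE, rangesInTenths = TRUE) {
  dirn <- if (season == "autumn") "next" else "prior"
  layers <- list(
    temp_season = seasonalMeanTemperature(monthlyMeans, season,
                                          inTenths = meansInTenths),
    temp_adjacent = adjacentSeasonTemperature(monthlyMeans, season, dirn,
                                              inTenths = meansInTenths),
    temp_range = seasonalTemperatureRange(monthlyRanges, season,
                                          inTenths = rangesInTenths))
  layers <- c(layers, static)
  prov <- c(
    temp_season = sprintf("mean of monthly means, months %s%s",
                          paste(seasonMonths(season), collapse = ","),
                          if (meansInTenths) ", rescaled degC*10 -> degC" else ""),
    temp_adjacent = sprintf("%s-season mean temperature", dirn),
    temp_range = sprintf("mean of monthly ranges, months %s%s",
                         paste(seasonMonths(season), collapse = ","),
                         if (rangesInTenths) ", rescaled degC*10 -> degC" else ""),
    setNames(rep("static input layer", length(static)), names(static)))
  new("PredictorStack", season = season, layers = layers, provenance = prov)
}

#' Pairwise correlation screen for candidate predictors
#'
#' Flags every candidate pair whose Pearson \emph{or} Spearman correlation
#' exceeds the threshold in absolute value (computed on a fixed-seed random
#' sample of pixels where all candidates are unmasked) and drops one member
#' per flagged pair until no retained pair exceeds the threshold.
#'
#' The drop choice is deterministic: variables named in \code{dropPriority}
#' are dropped first (encoding the standard narrative choices — e.g. drop
#' elevation in favor of temperature, drop diurnal range and raw
#' precipitation totals in favor of season length / precipitation
#' seasonality); for pairs not covered, the member with the larger mean
#' absolute correlation to all other candidates is dropped, with an
#' alphabetical tie-break. A zero-variance candidate has undefined
#' correlations; it is retained and flagged.
#'
#' @param layers named list of aligned \linkS4class{RasterLayer}s, or a
#'   \linkS4class{PredictorStack}.
#' @param threshold correlation cutoff (default 0.70; pairs with r strictly
#'   greater are screened).
#' @param samplePixels pixels sampled for the correlation estimate (all
#'   complete pixels if fewer).
#' @param seed seed for the pixel sample.
#' @param dropPriority character vector of drop-first variable names.
#' @return list with \code{retained} (names), \code{report} (one row per
#'   flagged pair: both correlations and which member was dropped), and
#'   \code{constant} (zero-variance layer names, retained but unscreenable).
#' @export
correlationScreen <- function(layers, threshold = 0.70, samplePixels = 50000,
                              seed = 1,
                              dropPriority = c("elevation", "diurnal_range",
                                               "annual_precip",
                                               "seasonal_precip")) {
  if (is(layers, "PredictorStack")) layers <- layers@layers
  if (length(layers) < 2) stop("need at least two candidate layers")
  nms <- names(layers)
  mat <- vapply(layers, function(l) as.vector(l@values),
                numeric(length(layers[[1]]@values)))
  ok <- stats::complete.cases(mat)
  idx <- which(ok)
  if (length(idx) > samplePixels)
    idx <- withSeed(seed, sample(idx, samplePixels))
  m <- mat[idx, , drop = FALSE]

  sds <- apply(m, 2, sd)
  constant <- nms[sds == 0]
  live <- nms[sds > 0]
  pearson <- suppressWarnings(cor(m, method = "pearson"))
  spearman <- suppressWarnings(cor(m, method = "spearman"))
  strength <- pmax(abs(pearson), abs(spearman))
  diag(strength) <- 0

  retained <- live
  report <- data.frame(var1 = character(0), var2 = character(0),
                       pearson = numeric(0), spearman = numeric(0),
                       dropped = character(0), stringsAsFactors = FALSE)
  repeat {
    s <- strength[retained, retained, drop = FALSE]
    if (all(s <= threshold, na.rm = TRUE)) break
    hit <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- retained[hit[1]]; b <- retained[hit[2]]
    pr <- match(c(a, b), dropPriority)
    drop <- if (!is.na(pr[1]) && (is.na(pr[2]) || pr[1] <= pr[2])) a
    else if (!is.na(pr[2])) b
    else {
      ma <- mean(strength[a, setdiff(retained, a)])
      mb <- mean(strength[b, setdiff(retained, b)])
      if (ma > mb) a else if (mb > ma) b else sort(c(a, b))[2]
    }
    report <- rbind(report, data.frame(
      var1 = a, var2 = b, pearson = pearson[a, b], spearman = spearman[a, b],
      dropped = drop, stringsAsFactors = FALSE))
    retained <- setdiff(retained, drop)
  }
  list(retained = nms[nms %in% c(retained, constant)], report = report,
       constant = constant)
}

#' @keywords internal
pixelId <- function(grid, row, col) (as.integer(col) - 1L) * grid@nRows + as.integer(row)

#' Sample background pixels uniformly without replacement
#'
#' Draws \code{n} distinct pixels from all available (unmasked) pixels in
#' the extent, reproducibly under the seed. The standard analysis draws
#' 10,000 background pixels.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param n number of pixels.
#' @param seed integer seed.
#' @param excludeMask optional \linkS4class{RasterLayer} whose \code{NA}
#'   pixels are unavailable.
#' @return integer matrix with columns \code{row}, \code{col}.
#' @export
sampleBackground <- function(grid, n, seed, excludeMask = NULL) {
  total <- grid@nRows * grid@nCols
  avail <- if (is.null(excludeMask)) seq_len(total)
           else which(!is.na(as.vector(excludeMask@values)))
  if (n > length(avail))
    stop("requested ", n, " background pixels but only ", length(avail),
         " are available")
  cells <- withSeed(seed, {
    if (n == length(avail)) avail else sort(sample(avail, n, replace = FALSE))
  })
  cbind(row = ((cells - 1L) %% grid@nRows) + 1L,
        col = ((cells - 1L) %/% grid@nRows) + 1L)
}

#' Extract stack values at pixel indices
#' @keywords internal
stackValuesAt <- function(stack, pixels) {
  out <- vapply(stack@layers, function(l)
    l@values[cbind(pixels[, 1], pixels[, 2])], numeric(nrow(pixels)))
  if (nrow(pixels) == 1L) out <- matrix(out, nrow = 1,
                                        dimnames = list(NULL, names(stack@layers)))
  out
}

#' Assemble the labeled presence/background training table
#'
#' Rows are the occupied pixels (label 1) united with the background pixels
#' (label 0); a background pixel that coincides with an occupied pixel
#' appears once, labeled 1 (it is known occupied). Covariate columns come
#' from the screened stack; rows with nodata in any covariate are dropped
#' and counted.
#'
#' @param occupied an \linkS4class{OccupiedPixelSet}.
#' @param backgroundPixels integer matrix (row, col) from
#'   \code{\link{sampleBackground}}.
#' @param stack a \linkS4class{PredictorStack}.
#' @return list with \code{table} (a \linkS4class{TrainingTable}) and
#'   \code{nDroppedNodata}.
#' @export
assembleTrainingTable <- function(occupied, backgroundPixels, stack) {
  if (nrow(occupied@pixels) < 1) stop("empty presence set")
  g <- stack@layers[[1]]@grid
  occId <- pixelId(g, occupied@pixels[, 1], occupied@pixels[, 2])
  bgId <- pixelId(g, backgroundPixels[, 1], backgroundPixels[, 2])
  bgOnly <- backgroundPixels[!(bgId %in% occId), , drop = FALSE]
  pixels <- rbind(occupied@pixels, bgOnly)
  label <- c(rep(1L, nrow(occupied@pixels)), rep(0L, nrow(bgOnly)))
  vals <- stackValuesAt(stack, pixels)
  ok <- stats::complete.cases(vals)
  d <- data.frame(row = pixels[ok, 1], col = pixels[ok, 2], label = label[ok],
                  vals[ok, , drop = FALSE])
  tab <- new("TrainingTable", subset = occupied@subset, data = d,
             covariateNames = names(stack@layers))
  list(table = tab, nDroppedNodata = sum(!ok))
}
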