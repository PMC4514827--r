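#' @import methods
#' @importFrom stats binomial complete.cases cor glm.fit lm.fit plogis
#'   predict qlogis quantile rexp rnorm runif sd setNames var
#' @importFrom utils head read.csv write.csv
NULL

#' Planar equal-area grid specification
#'
#' Describes the raster frame every layer, occurrence record and turbine point
#' in an analysis shares: a regular grid of square 1-km (by default) pixels in
#' a planar equal-area coordinate frame, indexed from the lower-left corner.
#' Pixel \code{(r, c)} covers the half-open square
#' \eqn{[x_0 + (c-1)s, x_0 + cs) \times [y_0 + (r-1)s, y_0 + rs)}, so a point
#' on a shared edge belongs to the pixel to its upper right (lower-left
#' inclusive convention).
#'
#' @slot nRows,nCols integer grid dimensions (rows increase northward).
#' @slot cellSizeKm pixel edge length in km (1 km for the standard analysis).
#' @slot originX,originY planar coordinates (km) of the lower-left grid corner.
#' @slot crsTag free-text label for the equal-area planar frame.
#' @export
setClass("GridSpec", representation(
  nRows = "integer", nCols = "integer", cellSizeKm = "numeric",
  originX = "numeric", originY = "numeric", crsTag = "character"
))

setValidity("GridSpec", function(object) {
  msgs <- character()
  if (length(object@nRows) != 1L || object@nRows < 1L) msgs <- c(msgs, "nRows must be a single value >= 1")
  if (length(object@nCols) != 1L || object@nCols < 1L) msgs <- c(msgs, "nCols must be a single value >= 1")
  if (length(object@cellSizeKm) != 1L || !is.finite(object@cellSizeKm) ||
      object@cellSizeKm <= 0) msgs <- c(msgs, "cellSizeKm must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Single raster layer on a shared grid
#'
#' A named, single-band raster aligned to a \linkS4class{GridSpec}. Values are
#' stored as an \code{nRows x nCols} matrix with row 1 the southernmost grid
#' row; \code{NA} marks nodata.
#'
#' @slot grid the \linkS4class{GridSpec} the layer is aligned to.
#' @slot name variable name (e.g. \code{"season_length"}).
#' @slot values numeric matrix, \code{NA} = nodata.
#' @slot units free-text units label.
#' @export
setClass("RasterLayer", representation(
  grid = "GridSpec", name = "character", values = "matrix", units = "character"
))

setValidity("RasterLayer", function(object) {
  msgs <- character()
  if (!is.numeric(object@values)) msgs <- c(msgs, "values must be numeric")
  if (nrow(object@values) != object@grid@nRows ||
      ncol(object@values) != object@grid@nCols)
    msgs <- c(msgs, "values matrix must be nRows x nCols")
  v <- object@values
  if (any(!is.finite(v) & !is.na(v))) msgs <- c(msgs, "unmasked values must be finite (use NA for nodata)")
  if (length(msgs)) msgs else TRUE
})

#' One season's screened predictor raster set
#'
#' An ordered, grid-aligned collection of covariate layers for one season,
#' together with provenance notes recording how each layer was constructed
#' (e.g. which months were averaged, unit rescaling applied on ingest).
#'
#' @slot season one of \code{"winter"}, \code{"spring"}, \code{"summer"},
#'   \code{"autumn"}.
#' @slot layers named list of \linkS4class{RasterLayer}s, all on one grid.
#' @slot provenance named character vector of construction notes.
#' @export
setClass("PredictorStack", representation(
  season = "character", layers = "list", provenance = "character"
))

setValidity("PredictorStack", function(object) {
  msgs <- character()
  if (!object@season %in% c("winter", "spring", "summer", "autumn"))
    msgs <- c(msgs, "season must be winter/spring/summer/autumn")
  if (length(object@layers)) {
    if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
      msgs <- c(msgs, "layers must be uniquely named")
    g <- object@layers[[1]]@grid
    for (ly in object@layers) {
      if (!is(ly, "RasterLayer")) { msgs <- c(msgs, "layers must be RasterLayer objects"); break }
      if (!sameGrid(ly@grid, g)) { msgs <- c(msgs, "all layers must share one grid"); break }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Occupied-pixel set for one modeling subset
#'
#' The rasterized form of one season-by-sex occurrence subset: the set of
#' distinct 1-km pixels containing at least one record ("locations"), plus the
#' number of contributing records. Multiple records can share a pixel, so the
#' number of locations never exceeds the number of records.
#'
#' @slot subset subset key, e.g. \code{"winter_pooled"}.
#' @slot pixels two-column integer matrix (row, col), one row per distinct pixel.
#' @slot nRecords number of occurrence records that produced the set.
#' @export
setClass("OccupiedPixelSet", representation(
  subset = "character", pixels = "matrix", nRecords = "integer"
))

setValidity("OccupiedPixelSet", function(object) {
  msgs <- character()
  if (ncol(object@pixels) != 2L) msgs <- c(msgs, "pixels must have two columns (row, col)")
  if (nrow(object@pixels) > object@nRecords)
    msgs <- c(msgs, "distinct pixels cannot exceed record count")
  if (length(msgs)) msgs else TRUE
})

#' Labeled presence/background training table
#'
#' One row per modeling pixel: occupied pixels labeled 1, background pixels
#' labeled 0, with one column per screened covariate. A background pixel that
#' coincides with an occupied pixel appears once, labeled 1.
#'
#' @slot subset subset key the table belongs to.
#' @slot data data.frame with columns \code{row}, \code{col}, \code{label}
#'   and the covariates.
#' @slot covariateNames ordered covariate column names.
#' @export
setClass("TrainingTable", representation(
  subset = "character", data = "data.frame", covariateNames = "character"
))

setValidity("TrainingTable", function(object) {
  msgs <- character()
  d <- object@data
  need <- c("row", "col", "label", object@covariateNames)
  miss <- setdiff(need, names(d))
  if (length(miss)) msgs <- c(msgs, paste("missing columns:", paste(miss, collapse = ", ")))
  else {
    if (!all(d$label %in% c(0, 1))) msgs <- c(msgs, "labels must be 0/1")
    if (sum(d$label == 1) < 1 || sum(d$label == 0) < 1)
      msgs <- c(msgs, "need at least one presence and one background row")
    if (anyNA(d[object@covariateNames])) msgs <- c(msgs, "covariate values must be complete")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted species distribution model (virtual base)
#'
#' Common contract of the five model forms: an opaque fitted object plus the
#' metadata needed to predict a suitability value in [0, 1] for any covariate
#' vector. Concrete classes exist per form; all are produced by
#' \code{\link{fitModel}} and queried through \code{\link{predictSuitability}}.
#'
#' @slot form one of \code{"GLM"}, \code{"MARS"}, \code{"BRT"}, \code{"RF"},
#'   \code{"MAXENT"}.
#' @slot covariateNames covariate names the model was trained on, in order.
#' @slot fit engine-specific fitted object.
#' @slot meta list of training metadata (seed, hyperparameters, flags).
#' @export
setClass("SDMModel", representation(
  form = "character", covariateNames = "character", fit = "ANY", meta = "list",
  "VIRTUAL"
))

#' @rdname SDMModel-class
#' @export
setClass("GLMModel", contains = "SDMModel")
#' @rdname SDMModel-class
#' @export
setClass("MARSModel", contains = "SDMModel")
#' @rdname SDMModel-class
#' @export
setClass("BRTModel", contains = "SDMModel")
#' @rdname SDMModel-class
#' @export
setClass("RFModel", contains = "SDMModel")
#' @rdname SDMModel-class
#' @export
setClass("MaxentModel", contains = "SDMModel")

#' Cross-validation result for one model form on one subset
#'
#' @slot form model form name.
#' @slot subset subset key.
#' @slot folds data.frame with one row per fold: \code{fold}, \code{auc},
#'   \code{sensitivity}, \code{specificity}, \code{threshold}.
#' @slot means named numeric vector of the fold means.
#' @export
setClass("CVResult", representation(
  form = "character", subset = "character", folds = "data.frame",
  means = "numeric"
))

setValidity("CVResult", function(object) {
  msgs <- character()
  need <- c("fold", "auc", "sensitivity", "specificity", "threshold")
  if (!all(need %in% names(object@folds))) msgs <- c(msgs, "folds must carry fold/auc/sensitivity/specificity/threshold")
  if (length(msgs)) msgs else TRUE
})

#' Binary-average ensemble map
#'
#' Per-pixel mean of the thresholded binary suitability maps of the
#' contributing model forms. With five contributors every unmasked pixel takes
#' one of the six values \{0, 0.2, 0.4, 0.6, 0.8, 1.0\} — the fraction of
#' forms that classify the pixel as suitable.
#'
#' @slot subset subset key.
#' @slot forms contributing form names.
#' @export
setClass("EnsembleMap", contains = "RasterLayer",
         representation(subset = "character", forms = "character"))

#' Point-exposure summary of an ensemble map
#'
#' Distributional summary of ensemble suitability values extracted at a point
#' set (e.g. wind turbines): mean, range, an equal-width histogram on [0, 1],
#' and adjusted Fisher-Pearson sample skewness (negative skewness indicates
#' mass piled toward high suitability).
#'
#' @slot subset subset key.
#' @slot n number of points with usable values.
#' @slot nExcluded points dropped (outside grid or on nodata).
#' @slot mean,min,max summary statistics of the extracted values.
#' @slot histBreaks,histCounts histogram bin edges and counts.
#' @slot skewness adjusted Fisher-Pearson skewness (NA when n < 3).
#' @export
setClass("ExposureSummary", representation(
  subset = "character", n = "integer", nExcluded = "integer",
  mean = "numeric", min = "numeric", max = "numeric",
  histBreaks = "numeric", histCounts = "integer", skewness = "numeric"
))
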