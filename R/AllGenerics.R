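#' Predict suitability for covariate vectors
#'
#' Every fitted model form maps a matrix (or data.frame) of covariate values
#' to a suitability score in [0, 1], one per row. Columns must cover the
#' model's training covariates by name; extra columns are ignored.
#'
#' @param model a fitted \linkS4class{SDMModel}.
#' @param newdata matrix or data.frame of covariate values.
#' @return numeric vector of suitabilities in [0, 1].
#' @export
setGeneric("predictSuitability", function(model, newdata)
  standardGeneric("predictSuitability"))

#' Number of rows / columns of a gridded object
#' @param x a \linkS4class{GridSpec} or \linkS4class{RasterLayer}.
#' @return integer count.
#' @export
setGeneric("nGridRows", function(x) standardGeneric("nGridRows"))
#' @rdname nGridRows
#' @export
setGeneric("nGridCols", function(x) standardGeneric("nGridCols"))

#' Raster cell values
#' @param x a \linkS4class{RasterLayer}.
#' @return numeric matrix (row 1 = southernmost grid row), NA = nodata.
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' Layer names of a predictor stack
#' @param x a \linkS4class{PredictorStack}.
#' @return character vector of layer names in order.
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' Extract one layer from a predictor stack
#' @param x a \linkS4class{PredictorStack}.
#' @param name layer name.
#' @return a \linkS4class{RasterLayer}.
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

setMethod("nGridRows", "GridSpec", function(x) x@nRows)
setMethod("nGridCols", "GridSpec", function(x) x@nCols)
setMethod("nGridRows", "RasterLayer", function(x) x@grid@nRows)
setMethod("nGridCols", "RasterLayer", function(x) x@grid@nCols)
setMethod("rasterValues", "RasterLayer", function(x) x@values)
setMethod("layerNames", "PredictorStack", function(x) names(x@layers))
setMethod("getLayer", "PredictorStack", function(x, name) {
  if (!name %in% names(x@layers))
    stop("no layer named '", name, "' in stack (have: ",
         paste(names(x@layers), collapse = ", "), ")")
  x@layers[[name]]
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d pixels of %.3g km, origin (%.6g, %.6g) [%s]\n",
              object@nRows, object@nCols, object@cellSizeKm,
              object@originX, object@originY, object@crsTag))
})

setMethod("show", "RasterLayer", function(object) {
  v <- object@values
  ok <- v[!is.na(v)]
  cat(sprintf("RasterLayer '%s' (%s): %d x %d, %d nodata\n",
              object@name, object@units, nrow(v), ncol(v), sum(is.na(v))))
  if (length(ok))
    cat(sprintf("  range [%.4g, %.4g], mean %.4g\n", min(ok), max(ok), mean(ok)))
})

setMethod("show", "PredictorStack", function(object) {
  cat(sprintf("PredictorStack (%s): %d layers\n", object@season,
              length(object@layers)))
  for (nm in names(object@layers))
    cat("  -", nm, if (nm %in% names(object@provenance))
      paste0("[", object@provenance[[nm]], "]") else "", "\n")
})

setMethod("show", "TrainingTable", function(object) {
  cat(sprintf("TrainingTable (%s): %d rows (%d presence, %d background), %d covariates\n",
              object@subset, nrow(object@data), sum(object@data$label == 1),
              sum(object@data$label == 0), length(object@covariateNames)))
})

setMethod("show", "OccupiedPixelSet", function(object) {
  cat(sprintf("OccupiedPixelSet (%s): %d records, %d occupied pixels\n",
              object@subset, object@nRecords, nrow(object@pixels)))
})

setMethod("show", "SDMModel", function(object) {
  cat(sprintf("Fitted %s model on %d covariates (%s)\n", object@form,
              length(object@covariateNames),
              paste(object@covariateNames, collapse = ", ")))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult %s / %s over %d folds:\n", object@form, object@subset,
              nrow(object@folds)))
  m <- object@means
  cat(sprintf("  mean AUC %.3f, sensitivity %.3f, specificity %.3f\n",
              m[["auc"]], m[["sensitivity"]], m[["specificity"]]))
})

setMethod("show", "EnsembleMap", function(object) {
  cat(sprintf("EnsembleMap (%s) from %d forms [%s]\n", object@subset,
              length(object@forms), paste(object@forms, collapse = ", ")))
  callNextMethod()
})

setMethod("show", "ExposureSummary", function(object) {
  cat(sprintf("ExposureSummary (%s): n=%d (excluded %d) mean %.3f range [%.3f, %.3f] skewness %.3f\n",
              object@subset, object@n, object@nExcluded, object@mean,
              object@min, object@max, object@skewness))
})
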