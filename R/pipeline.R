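# End-to-end orchestration: simulate (or load) -> prep -> stacks -> screen ->
# fit -> evaluate -> ensemble -> exposure, from a single validated config,
# with per-stage seeds and line-delimited JSON logging.

#' Build a run configuration
#'
#' Fills a configuration list with the standard defaults: all seven subsets,
#' all five forms, 50-km spatial-error cutoff, 0.70 correlation screen,
#' 10,000 background pixels, 10-fold cross-validation and 10 permutation
#' repeats. Either a \code{simulate} block (synthetic scenario) or a
#' \code{paths} block (occurrence CSV, raster manifest JSON, turbine CSV)
#' supplies the data.
#'
#' @param ... fields overriding the defaults (nested lists are merged
#'   shallowly per block).
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(...) {
  over <- list(...)
  cfg <- list(
    version = 1,
    seed = 1,
    output_dir = "sdm_run",
    subsets = subsetKeys(),
    forms = MODEL_FORMS,
    thresholds = list(max_error_km = 50, correlation = 0.70,
                      background_n = 10000, cv_folds = 10,
                      importance_repeats = 10),
    hyperparameters = list(),
    simulate = list(n_rows = 200, n_cols = 200, n_turbines = 500),
    paths = NULL)
  for (nm in names(over)) {
    if (nm %in% c("thresholds", "simulate") && is.list(over[[nm]]) &&
        !is.null(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return a \code{RunConfig} list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$paths)) raw$simulate <- NULL
  do.call(runConfig, raw)
}

#' Validate a run configuration
#'
#' Checks every path, range and enumeration and returns the full list of
#' violations rather than failing at the first.
#'
#' @param config a \code{RunConfig}.
#' @return character vector of violations (empty when valid).
#' @export
validateConfig <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  th <- config$thresholds
  if (is.null(config$seed) || !is.finite(config$seed))
    add("seed must be a finite integer")
  badForm <- setdiff(toupper(config$forms), MODEL_FORMS)
  if (length(badForm)) add(paste0("unknown model form(s): ",
                                  paste(badForm, collapse = ", ")))
  badSub <- setdiff(config$subsets, subsetKeys())
  if (length(badSub)) add(paste0("unknown subset(s): ",
                                 paste(badSub, collapse = ", ")))
  for (nm in c("max_error_km", "correlation", "background_n", "cv_folds",
               "importance_repeats")) {
    if (is.null(th[[nm]]) || !is.finite(th[[nm]]) || th[[nm]] <= 0)
      add(paste0("threshold '", nm, "' must be positive"))
  }
  if (!is.null(th$cv_folds) && is.finite(th$cv_folds) && th$cv_folds < 2)
    add("cv_folds must be at least 2")
  if (is.null(config$simulate) && is.null(config$paths))
    add("either a 'simulate' or a 'paths' block is required")
  if (!is.null(config$paths)) {
    for (nm in c("occurrences", "raster_manifest", "turbines")) {
      p <- config$paths[[nm]]
      if (is.null(p)) add(paste0("paths$", nm, " is required"))
      else if (!file.exists(p)) add(paste0("paths$", nm, " not found: ", p))
    }
  }
  v
}

#' @keywords internal
jsonLog <- function(conPath, stage, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = conPath, append = TRUE, sep = "")
}

# Load predictor inputs from a raster manifest JSON:
# {"monthly_tmean": [...12 files...], "monthly_trange": [...],
#  "static": {"name": "file", ...},
#  "means_in_tenths": false, "ranges_in_tenths": false}
#' @keywords internal
loadRasterManifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  rd <- function(f, nm = NULL) readRasterLayer(file.path(base, f), name = nm)
  monthlyMeans <- lapply(man$monthly_tmean, rd)
  monthlyRanges <- lapply(man$monthly_trange, rd)
  statics <- lapply(names(man$static), function(nm) rd(man$static[[nm]], nm))
  names(statics) <- names(man$static)
  list(monthlyMeans = monthlyMeans, monthlyRanges = monthlyRanges,
       static = statics,
       meansInTenths = isTRUE(man$means_in_tenths),
       rangesInTenths = isTRUE(man$ranges_in_tenths))
}

#' Run the full seasonal ensemble SDM pipeline
#'
#' Executes every requested subset-by-form combination (the default
#' configuration runs the full 7 x 5 = 35 factorial): occurrence prep,
#' seasonal stack construction and correlation screening, per-form
#' cross-validation and final fits, minimum-training-presence binary maps,
#' per-subset ensembles, permutation variable importance, and turbine
#' exposure summaries. All outputs, a line-delimited JSON stage log, and a
#' manifest (package version, seeds, input hashes, per-stage counts) land in
#' \code{config$output_dir}. A failed stage is recorded in the manifest and
#' the error is re-raised after the partial manifest is written.
#'
#' @param config a \code{RunConfig} (see \code{\link{runConfig}},
#'   \code{\link{readRunConfig}}).
#' @return the run manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  viol <- validateConfig(config)
  if (length(viol))
    stop("invalid configuration:\n  - ", paste(viol, collapse = "\n  - "))
  out <- config$output_dir
  for (d in c("", "models", "maps", "metrics", "exposure"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(out, "log.jsonl")
  if (file.exists(logPath)) unlink(logPath)
  master <- as.integer(config$seed)
  th <- config$thresholds
  forms <- toupper(config$forms)
  subsets <- config$subsets
  manifest <- list(package_version = as.character(utils::packageVersion("seasonalSDM")),
                   seed = master, config = unclass(config),
                   stages = list(), failure = NULL)
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  result <- tryCatch({
    # ---- data stage ----------------------------------------------------
    if (!is.null(config$paths)) {
      occPath <- config$paths$occurrences
      turbines <- read.csv(config$paths$turbines)
      ras <- loadRasterManifest(config$paths$raster_manifest)
      grid <- ras$monthlyMeans[[1]]@grid
    } else {
      sim <- config$simulate
      scenario <- defaultScenario(seed = stageSeed(master, "simulate"),
                                  nRows = sim$n_rows, nCols = sim$n_cols)
      rz <- realizeScenario(scenario, nTurbines = sim$n_turbines)
      occPath <- file.path(out, "occurrences.csv")
      write.csv(rz$occurrences, occPath, row.names = FALSE, quote = FALSE)
      turbines <- rz$turbines
      write.csv(turbines, file.path(out, "turbines.csv"), row.names = FALSE,
                quote = FALSE)
      ras <- list(monthlyMeans = rz$monthlyMeans,
                  monthlyRanges = rz$monthlyRanges, static = rz$static,
                  meansInTenths = FALSE, rangesInTenths = FALSE)
      grid <- scenario$grid
    }
    jsonLog(logPath, "data", n_turbines = nrow(turbines),
            grid = paste0(grid@nRows, "x", grid@nCols))
    manifest$stages$data <- list(
      occurrences_md5 = unname(tools::md5sum(occPath)),
      n_turbines = nrow(turbines))

    # ---- occurrence prep ----------------------------------------------
    prep <- prepareOccurrences(occPath, grid, maxErrorKm = th$max_error_km)
    jsonLog(logPath, "prep", filtered = prep$qc$filtered,
            records = as.list(prep$qc$records),
            locations = as.list(prep$qc$locations))
    jsonlite::write_json(prep$qc, file.path(out, "metrics", "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$prep <- prep$qc

    # ---- stacks + screening -------------------------------------------
    seasons <- unique(subsetSeason(subsets))
    stacks <- list()
    screenReport <- NULL
    for (se in seasons) {
      st <- buildSeasonStack(se, ras$monthlyMeans, ras$monthlyRanges,
                             ras$static, meansInTenths = ras$meansInTenths,
                             rangesInTenths = ras$rangesInTenths)
      scr <- correlationScreen(st, threshold = th$correlation,
                               seed = stageSeed(master, paste0("screen:", se)))
      st@layers <- st@layers[scr$retained]
      st@provenance <- st@provenance[scr$retained]
      stacks[[se]] <- st
      if (nrow(scr$report)) {
        scr$report$season <- se
        screenReport <- rbind(screenReport, scr$report)
      }
      jsonLog(logPath, "screen", season = se,
              retained = length(scr$retained), flagged = nrow(scr$report))
    }
    write.csv(screenReport %||%
                data.frame(var1 = character(0), var2 = character(0),
                           pearson = numeric(0), spearman = numeric(0),
                           dropped = character(0), season = character(0)),
              file.path(out, "metrics", "correlation_screen.csv"),
              row.names = FALSE)

    # ---- per-subset fitting -------------------------------------------
    aucTab <- ssTab <- list()
    impAll <- NULL
    expRows <- list()
    nArtifacts <- 0L
    for (sub in subsets) {
      se <- subsetSeason(sub)
      stack <- stacks[[se]]
      bg <- sampleBackground(grid, th$background_n,
                             seed = stageSeed(master, paste0("background:", sub)))
      asm <- assembleTrainingTable(prep$occupied[[sub]], bg, stack)
      tab <- asm$table
      jsonLog(logPath, "table", subset = sub, rows = nrow(tab@data),
              presences = sum(tab@data$label == 1),
              dropped_nodata = asm$nDroppedNodata)

      models <- list()
      binaries <- list()
      for (fm in forms) {
        hp <- config$hyperparameters[[fm]] %||% list()
        cv <- crossValidate(fm, tab, k = th$cv_folds,
                            seed = stageSeed(master, paste0("cv:", sub)),
                            hp = hp)
        fit <- fitModel(fm, tab, hp = hp,
                        seed = stageSeed(master, paste0("fit:", sub, ":", fm)))
        thr <- mtpThreshold(fit, tab@data[tab@data$label == 1,
                                          tab@covariateNames, drop = FALSE])
        surf <- predictSurface(fit, stack)
        binaries[[fm]] <- binarize(surf, thr)
        models[[fm]] <- fit
        artifact <- list(format_version = 1L,
                         package_version = manifest$package_version,
                         subset = sub, form = fm, model = fit,
                         threshold = thr, cv_means = cv@means,
                         cv_folds = cv@folds)
        saveRDS(artifact, file.path(out, "models",
                                    sprintf("%s_%s.rds", sub, fm)))
        nArtifacts <- nArtifacts + 1L
        aucTab[[fm]][[sub]] <- cv@means[["auc"]]
        ssTab[[fm]][[sub]] <- sprintf("%.3f/%.3f", cv@means[["sensitivity"]],
                                      cv@means[["specificity"]])
        jsonLog(logPath, "fit", subset = sub, form = fm,
                cv_auc = round(cv@means[["auc"]], 4),
                threshold = thr)
      }

      ens <- ensembleMap(binaries, subset = sub)
      writeAsciiGrid(ens, file.path(out, "maps",
                                    sprintf("ensemble_%s.asc", sub)))
      jsonLog(logPath, "ensemble", subset = sub,
              n_pixels = sum(!is.na(ens@values)))

      # permutation importance on the presences plus a bounded background
      # subsample (keeps the per-form evaluation cost flat across subsets)
      d <- tab@data
      bgRows <- which(d$label == 0)
      evalRows <- c(which(d$label == 1),
                    if (length(bgRows) > 2000)
                      withSeed(stageSeed(master, paste0("impbg:", sub)),
                               sort(sample(bgRows, 2000))) else bgRows)
      impTab <- importanceTable(models, subsetTrainingTable(tab, evalRows),
                                nRepeats = th$importance_repeats,
                                seed = stageSeed(master, paste0("imp:", sub)))
      impTab$subset <- sub
      impAll <- rbind(impAll, impTab)

      ext <- extractAtPoints(ens, turbines)
      es <- exposureSummary(ext$values, subset = sub,
                            nExcluded = ext$nExcluded)
      expRows[[sub]] <- data.frame(
        subset = sub, n = es@n, n_excluded = es@nExcluded, mean = es@mean,
        min = es@min, max = es@max, skewness = es@skewness)
      write.csv(data.frame(bin_low = es@histBreaks[-length(es@histBreaks)],
                           bin_high = es@histBreaks[-1],
                           count = es@histCounts),
                file.path(out, "exposure",
                          sprintf("histogram_%s.csv", sub)),
                row.names = FALSE)
      jsonLog(logPath, "exposure", subset = sub, n = es@n,
              mean = round(es@mean, 4))
      manifest$stages[[paste0("subset:", sub)]] <- list(
        rows = nrow(tab@data), presences = sum(tab@data$label == 1),
        locations = nrow(prep$occupied[[sub]]@pixels))
    }

    # ---- cross-subset tables ------------------------------------------
    aucDf <- data.frame(form = forms, stringsAsFactors = FALSE)
    ssDf <- data.frame(form = forms, stringsAsFactors = FALSE)
    for (sub in subsets) {
      aucDf[[sub]] <- vapply(forms, function(fm)
        round(aucTab[[fm]][[sub]], 3), numeric(1))
      ssDf[[sub]] <- vapply(forms, function(fm) ssTab[[fm]][[sub]],
                            character(1))
    }
    write.csv(aucDf, file.path(out, "metrics", "auc.csv"), row.names = FALSE)
    write.csv(ssDf, file.path(out, "metrics", "sensitivity_specificity.csv"),
              row.names = FALSE)
    write.csv(impAll, file.path(out, "metrics", "variable_importance.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, expRows),
              file.path(out, "exposure", "exposure_summary.csv"),
              row.names = FALSE)

    manifest$stages$artifacts <- list(models = nArtifacts,
                                      ensembles = length(subsets))
    jsonLog(logPath, "done", models = nArtifacts,
            ensembles = length(subsets))
    manifest
  }, error = function(e) {
    manifest$failure <<- conditionMessage(e)
    jsonLog(logPath, "failure", message = conditionMessage(e))
    finish()
    stop(e)
  })
  finish()
  invisible(result)
}
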