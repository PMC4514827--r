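# Occurrence-record QC, seasonal binning, sex stratification and
# rasterization into the seven modeling subsets.

OCC_COLUMNS <- c("id", "longitude", "latitude", "x_km", "y_km", "date",
                 "sex", "error_km", "locality_precision")

#' The seven modeling subset keys
#'
#' Winter pools the sexes (too few winter records to stratify); spring,
#' summer and autumn are modeled separately for females and males.
#'
#' @return character vector of the seven subset keys.
#' @export
subsetKeys <- function() {
  c("winter_pooled", "spring_females", "spring_males", "summer_females",
    "summer_males", "autumn_females", "autumn_males")
}

#' Season of a subset key
#' @param subset subset key(s).
#' @return season name(s).
#' @export
subsetSeason <- function(subset) sub("_.*$", "", subset)

#' Assign calendar dates to seasons
#'
#' Seasons are month-day bins that ignore the year: winter is December 1 to
#' February 29 (the leap day belongs to winter), spring March 1 to May 31,
#' summer June 1 to July 31, and autumn August 1 to November 30. August 1
#' opens autumn because autumn migration can begin in early August. December
#' dates fall in the winter bin that spans the year boundary.
#'
#' @param date a \code{Date} vector (or something coercible via
#'   \code{as.Date}).
#' @return character vector of season names.
#' @examples
#' assignSeason(as.Date(c("1987-08-01", "1960-02-29", "1975-05-31")))
#' @export
assignSeason <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  out <- rep(NA_character_, length(m))
  out[m %in% c(12L, 1L, 2L)] <- "winter"
  out[m %in% 3:5] <- "spring"
  out[m %in% 6:7] <- "summer"
  out[m %in% 8:11] <- "autumn"
  out
}

# Word/case normalization for the sex field.
#' @keywords internal
normalizeSex <- function(x) {
  key <- tolower(trimws(x))
  key[key == ""] <- "u"
  map <- c(f = "F", female = "F", m = "M", male = "M",
           u = "U", unk = "U", unknown = "U")
  unname(map[key])
}

# Validate ISO dates strictly (rejects e.g. 1999-02-30, which some date
# parsers silently roll over).
#' @keywords internal
parseStrictDate <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  ok <- !is.na(d) & format(d, "%Y-%m-%d") == x
  d[!ok] <- NA
  d
}

#' Parse an occurrence CSV
#'
#' Reads a CSV with the exact header \code{id, longitude, latitude, x_km,
#' y_km, date, sex, error_km, locality_precision}. Malformed rows (invalid
#' date, unrecognized sex or locality precision, negative or missing spatial
#' error, missing coordinates) are collected into a rejects report rather
#' than silently dropped. When planar coordinates are absent but lon/lat are
#' present, planar km coordinates are derived by a local equirectangular
#' projection about the data's mean lon/lat (adequate for the regional scales
#' this pipeline is run at; the native analysis frame is planar equal-area).
#'
#' @param csvPath path to the CSV file.
#' @return list with \code{records} (clean rows, \code{date} as \code{Date},
#'   sex normalized to F/M/U) and \code{rejects} (data.frame of row numbers
#'   and reasons).
#' @export
parseOccurrences <- function(csvPath) {
  if (!file.exists(csvPath)) stop("occurrence file not found: ", csvPath)
  raw <- read.csv(csvPath, colClasses = "character", check.names = FALSE)
  miss <- setdiff(OCC_COLUMNS, names(raw))
  if (length(miss))
    stop("occurrence CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(raw)
  num <- function(x) suppressWarnings(as.numeric(x))
  lon <- num(raw$longitude); lat <- num(raw$latitude)
  x <- num(raw$x_km); y <- num(raw$y_km)
  noPlanar <- is.na(x) | is.na(y)
  if (any(noPlanar) && any(!is.na(lon) & !is.na(lat))) {
    lon0 <- mean(lon, na.rm = TRUE); lat0 <- mean(lat, na.rm = TRUE)
    kmPerDeg <- 111.32
    x[noPlanar] <- (lon[noPlanar] - lon0) * kmPerDeg * cos(lat0 * pi / 180)
    y[noPlanar] <- (lat[noPlanar] - lat0) * kmPerDeg
  }
  date <- parseStrictDate(raw$date)
  sex <- normalizeSex(raw$sex)
  err <- num(raw$error_km)
  prec <- tolower(trimws(raw$locality_precision))

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  flag(is.na(date), "invalid or missing date")
  flag(is.na(sex), paste0("unrecognized sex value"))
  flag(!prec %in% c("point", "county", "state"), "unrecognized locality_precision")
  flag(is.na(err) | err < 0, "invalid error_km")
  flag(is.na(x) | is.na(y), "missing coordinates")

  keep <- is.na(reason)
  records <- data.frame(
    id = raw$id[keep], longitude = lon[keep], latitude = lat[keep],
    x_km = x[keep], y_km = y[keep], date = date[keep], sex = sex[keep],
    error_km = err[keep], locality_precision = prec[keep],
    stringsAsFactors = FALSE)
  rejects <- data.frame(line = which(!keep) + 1L,  # +1 for the header line
                        id = raw$id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(records = records, rejects = rejects)
}

#' Quality-filter occurrence records
#'
#' Keeps records georeferenced to a point locality with an estimated spatial
#' error of at most \code{maxErrorKm}; records located only to state,
#' province, or county, or with error strictly greater than the cutoff, are
#' dropped. A record at exactly the cutoff is kept (the drop rule is a strict
#' "> 50 km").
#'
#' @param records data.frame as returned by \code{\link{parseOccurrences}}.
#' @param maxErrorKm spatial-error cutoff in km (default 50).
#' @return list with \code{kept} (data.frame) and \code{dropped} (data.frame
#'   with a \code{reason} column recording each record's first failing rule).
#' @export
filterRecords <- function(records, maxErrorKm = 50) {
  if (nrow(records) == 0L)
    return(list(kept = records,
                dropped = cbind(records, reason = character(0))))
  reason <- rep(NA_character_, nrow(records))
  coarse <- records$locality_precision != "point"
  reason[coarse] <- "locality identified only to state/province/county"
  tooFar <- is.na(reason) & records$error_km > maxErrorKm
  reason[tooFar] <- sprintf("georeferencing error > %g km", maxErrorKm)
  keep <- is.na(reason)
  dropped <- records[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], dropped = dropped)
}

#' Split filtered records into the seven modeling subsets
#'
#' Each record is binned to its season (\code{\link{assignSeason}}); winter
#' records of all sexes form the pooled winter subset, while spring, summer
#' and autumn records split by sex. Records of unknown sex outside winter
#' belong to no subset and are counted in the exclusion report.
#'
#' @param records filtered occurrence data.frame.
#' @return list with \code{subsets} (named list of data.frames, one per key
#'   in \code{\link{subsetKeys}}) and \code{excludedUnknownSex} (count).
#' @export
makeSubsets <- function(records) {
  season <- assignSeason(records$date)
  key <- rep(NA_character_, nrow(records))
  key[season == "winter"] <- "winter_pooled"
  nonwinter <- season != "winter"
  key[nonwinter & records$sex == "F"] <- paste0(season[nonwinter & records$sex == "F"], "_females")
  key[nonwinter & records$sex == "M"] <- paste0(season[nonwinter & records$sex == "M"], "_males")
  subsets <- lapply(subsetKeys(), function(k)
    records[!is.na(key) & key == k, , drop = FALSE])
  names(subsets) <- subsetKeys()
  list(subsets = subsets, excludedUnknownSex = sum(is.na(key)))
}

#' Rasterize a subset's records to its occupied-pixel set
#'
#' Maps each record's planar coordinates to its 1-km pixel by the half-open
#' (lower-left inclusive) convention and collects the distinct pixels. The
#' pixel, not the record, is the modeling unit: several records can share one
#' occupied pixel ("location").
#'
#' @param records data.frame of one subset's records.
#' @param grid a \linkS4class{GridSpec}.
#' @param subset subset key label for the result.
#' @return an \linkS4class{OccupiedPixelSet}.
#' @export
rasterizeOccurrences <- function(records, grid, subset = "subset") {
  px <- pointToPixel(grid, records$x_km, records$y_km)
  out <- which(is.na(px$row))
  if (length(out))
    stop("record(s) outside the grid footprint: ",
         paste(head(records$id[out], 10), collapse = ", "),
         if (length(out) > 10) " ..." else "")
  uniq <- unique(as.matrix(px))
  colnames(uniq) <- c("row", "col")
  new("OccupiedPixelSet", subset = subset, pixels = uniq,
      nRecords = nrow(records))
}

#' Run the full occurrence-prep chain
#'
#' Convenience wrapper: parse, filter, split into subsets and rasterize, with
#' a QC report of counts at every step.
#'
#' @param csvPath occurrence CSV path.
#' @param grid a \linkS4class{GridSpec}.
#' @param maxErrorKm spatial-error cutoff (km).
#' @return list with \code{subsets} (records per subset), \code{occupied}
#'   (named list of \linkS4class{OccupiedPixelSet}s) and \code{qc} (list of
#'   counts: parsed, rejected, kept, dropped by reason, per-subset records
#'   and locations, unknown-sex exclusions).
#' @export
prepareOccurrences <- function(csvPath, grid, maxErrorKm = 50) {
  parsed <- parseOccurrences(csvPath)
  filt <- filterRecords(parsed$records, maxErrorKm = maxErrorKm)
  split <- makeSubsets(filt$kept)
  occ <- lapply(subsetKeys(), function(k)
    rasterizeOccurrences(split$subsets[[k]], grid, subset = k))
  names(occ) <- subsetKeys()
  qc <- list(
    parsed = nrow(parsed$records) + nrow(parsed$rejects),
    rejectedRows = nrow(parsed$rejects),
    filtered = nrow(filt$kept),
    dropped = as.list(table(filt$dropped$reason)),
    excludedUnknownSex = split$excludedUnknownSex,
    records = vapply(split$subsets, nrow, integer(1)),
    locations = vapply(occ, function(o) nrow(o@pixels), integer(1)))
  list(subsets = split$subsets, occupied = occ, qc = qc,
       rejects = parsed$rejects, dropped = filt$dropped)
}
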