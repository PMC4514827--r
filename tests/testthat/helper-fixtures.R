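# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (double loops, brute force) so they stay
# independent of the implementation paths they check.

# Brute-force AUC: average pairwise win probability with ties = 1/2.
bruteForceAUC <- function(pres, bg) {
  tot <- 0
  for (p in pres) for (b in bg)
    tot <- tot + if (p > b) 1 else if (p == b) 0.5 else 0
  tot / (length(pres) * length(bg))
}

# Trapezoidal area under the empirical ROC curve.
trapezoidAUC <- function(pres, bg) {
  thr <- sort(unique(c(pres, bg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pres >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(bg >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Lag-1 (rook neighbourhood) Moran's I by direct double loop.
moranIOracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  mu <- mean(m)
  num <- 0; wsum <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        num <- num + (m[r, c] - mu) * (m[r2, c2] - mu)
        wsum <- wsum + 1
      }
    }
  }
  den <- sum((m - mu)^2)
  (nr * nc / wsum) * (num / den)
}

# A small training table with a clean single-driver logistic signal.
makeTinyTable <- function(seed = 1, n1 = 60, n0 = 200, beta = 2,
                          nNoise = 1, subset = "test") {
  set.seed(seed)
  n <- n1 + n0
  x <- rnorm(n)
  lab <- c(rep(1, n1), rep(0, n0))
  # presences drawn from the upper tail of the driver
  x[lab == 1] <- x[lab == 1] + beta
  d <- data.frame(row = seq_len(n), col = 1L, label = lab, driver = x)
  covs <- "driver"
  for (i in seq_len(nNoise)) {
    nm <- paste0("noise", i)
    d[[nm]] <- rnorm(n)
    covs <- c(covs, nm)
  }
  new("TrainingTable", subset = subset, data = d, covariateNames = covs)
}

# A small aligned stack of named constant-free layers.
makeTinyStack <- function(grid, values, season = "summer") {
  layers <- lapply(names(values), function(nm)
    rasterLayer(grid, values[[nm]], name = nm))
  names(layers) <- names(values)
  new("PredictorStack", season = season, layers = layers,
      provenance = setNames(rep("test", length(layers)), names(layers)))
}

# Occurrence data.frame in the standard column layout.
makeRecords <- function(x, y, date = "1980-06-15", sex = "M",
                        error_km = 1, locality_precision = "point") {
  n <- length(x)
  data.frame(id = sprintf("r%03d", seq_len(n)),
             longitude = -100 + x / 100, latitude = 40 + y / 100,
             x_km = x, y_km = y,
             date = as.Date(rep_len(date, n)),
             sex = rep_len(sex, n), error_km = rep_len(error_km, n),
             locality_precision = rep_len(locality_precision, n),
             stringsAsFactors = FALSE)
}
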