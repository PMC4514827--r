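test_that("covariate fields honor degenerate, clipping and moment contracts", {
  g <- gridSpec(40, 40)
  # zero variance -> constant layer at the mean
  const <- generateCovariateField(g, covariateSpec("c", 10, 0), seed = 1)
  expect_true(all(const@values == 10))
  # negative sd rejected
  expect_error(covariateSpec("bad", 0, -1), "sd")
  # bounds respected after clipping
  tc <- generateCovariateField(
    g, covariateSpec("tree_cover", 30, 40, autocorrKm = 5,
                     bounds = c(0, 100)), seed = 2)
  expect_true(all(tc@values >= 0 & tc@values <= 100))
  # empirical mean on target (rescaling is exact before clipping)
  f <- generateCovariateField(g, covariateSpec("f", 5, 2, autocorrKm = 3),
                              seed = 3)
  expect_equal(mean(f@values), 5, tolerance = 1e-8)
  expect_equal(sd(f@values), 2, tolerance = 1e-8)
})

test_that("autocorrelated fields are smoother than white noise (Moran's I oracle)", {
  g <- gridSpec(50, 50)
  smooth <- generateCovariateField(
    g, covariateSpec("s", 0, 1, autocorrKm = 10), seed = 7)
  white <- generateCovariateField(
    g, covariateSpec("w", 0, 1, autocorrKm = 0), seed = 7)
  iS <- moranIOracle(smooth@values)
  iW <- moranIOracle(white@values)
  expect_gt(iS, iW)
  expect_gt(iS, 0.5)          # strongly autocorrelated
  expect_lt(abs(iW), 0.05)    # white noise near zero
})

test_that("true suitability follows the logistic model exactly", {
  g <- gridSpec(4, 4)
  stack <- makeTinyStack(g, list(a = matrix(0, 4, 4)))
  scFlat <- list(coefficients = list(a = list(center = 0, scale = 1,
                                              beta = 0, beta2 = 0)),
                 intercept = 0)
  expect_true(all(trueSuitability(stack, scFlat)@values == 0.5))
  # single covariate, coef 1, value 2 -> 1/(1+exp(-2)) computed independently
  v <- matrix(0, 4, 4); v[2, 2] <- 2
  st2 <- makeTinyStack(g, list(a = v))
  sc1 <- list(coefficients = list(a = list(center = 0, scale = 1,
                                           beta = 1, beta2 = 0)),
              intercept = 0)
  s <- trueSuitability(st2, sc1)
  expect_equal(s@values[2, 2], 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(s@values[2, 2], 0.8808, tolerance = 1e-4)
  # deeply negative intercept drives suitability toward 0, monotonically
  lows <- vapply(c(-2, -6, -12), function(a) {
    sc <- sc1; sc$intercept <- a
    max(trueSuitability(st2, sc)@values)
  }, numeric(1))
  expect_true(all(diff(lows) < 0))
  expect_lt(lows[3], 1e-4)
  # missing covariate named in the error
  scBad <- list(coefficients = list(zz = list(center = 0, scale = 1,
                                              beta = 1)), intercept = 0)
  expect_error(trueSuitability(st2, scBad), "zz")
})

test_that("occurrence sampling respects suitability, seasons and the error model", {
  g <- gridSpec(3, 3)
  sc <- syntheticScenario(
    g, list(covariateSpec("temp_annual", 8, 8),
            covariateSpec("temp_amplitude", 12, 3),
            covariateSpec("temp_range", 25, 8)),
    coefficients = list(), intercept = 0,
    nPresences = c(winter_pooled = 50L, summer_males = 40L), seed = 5)

  # suitability concentrated on one pixel -> every record lands there
  v <- matrix(0, 3, 3); v[2, 3] <- 1
  suit <- rasterLayer(g, v)
  recs <- sampleOccurrences(suit, sc, "winter_pooled", seed = 11)
  px <- pointToPixel(g, recs$x_km, recs$y_km)
  expect_true(all(px$row == 2 & px$col == 3))
  expect_equal(nrow(recs), 50L)

  # winter dates fall in the December 1 - February 29 bin
  md <- format(as.Date(recs$date), "%m-%d")
  mon <- as.integer(substr(md, 1, 2))
  expect_true(all(mon %in% c(12L, 1L, 2L)))
  expect_true(all(assignSeason(as.Date(recs$date)) == "winter"))

  # all-zero suitability rejected
  expect_error(sampleOccurrences(rasterLayer(g, 0), sc, "winter_pooled", 1),
               "zero")
  # generated records pass the QC filters (error model bounded at 45 km)
  expect_true(all(recs$error_km <= 45))
  expect_true(all(filterRecords(recs)$kept$id == recs$id))
})

test_that("pixel draw frequencies follow suitability (binomial and exact checks)", {
  g2 <- gridSpec(1, 2)
  sc2 <- syntheticScenario(
    g2, list(covariateSpec("temp_annual", 8, 8),
             covariateSpec("temp_amplitude", 12, 3),
             covariateSpec("temp_range", 25, 8)),
    coefficients = list(), intercept = 0,
    nPresences = c(summer_males = 1000L), seed = 5)
  suit <- rasterLayer(g2, matrix(c(0.8, 0.2), 1, 2))
  recs <- sampleOccurrences(suit, sc2, "summer_males", seed = 21)
  share <- mean(pointToPixel(g2, recs$x_km, recs$y_km)$col == 1)
  se <- sqrt(0.8 * 0.2 / 1000)
  expect_lt(abs(share - 0.8), 3 * se)

  # exact-distribution check on a small grid (chi-square GOF)
  g3 <- gridSpec(3, 3)
  w <- matrix((1:9) / 45, 3, 3)
  sc3 <- sc2; sc3$nPresences <- c(summer_males = 5000L)
  r3 <- sampleOccurrences(rasterLayer(g3, w), sc3, "summer_males", seed = 9)
  px <- pointToPixel(g3, r3$x_km, r3$y_km)
  counts <- table(factor(paste(px$row, px$col),
                         levels = paste(rep(1:3, 3), rep(1:3, each = 3))))
  expected <- 5000 * as.vector(w) / sum(w)
  chi <- sum((as.vector(counts) - expected)^2 / expected)
  expect_lt(chi, qchisq(0.999, df = 8))
})

test_that("location-targeting mode fixes the distinct-pixel count exactly", {
  g <- gridSpec(20, 20)
  sc <- syntheticScenario(
    g, list(covariateSpec("temp_annual", 8, 8),
            covariateSpec("temp_amplitude", 12, 3),
            covariateSpec("temp_range", 25, 8)),
    coefficients = list(), intercept = 0,
    nPresences = c(autumn_males = 120L),
    nLocations = c(autumn_males = 37L), seed = 5)
  suit <- rasterLayer(g, matrix(runif(400, 0.1, 1), 20, 20))
  recs <- sampleOccurrences(suit, sc, "autumn_males", seed = 3)
  px <- pointToPixel(g, recs$x_km, recs$y_km)
  expect_equal(nrow(recs), 120L)
  expect_equal(nrow(unique(px)), 37L)
})

test_that("turbine generation covers the footprint and follows a bias layer", {
  g <- gridSpec(10, 10)
  tb <- generateTurbines(g, 10, seed = 2)
  expect_equal(nrow(tb), 10L)
  expect_true(all(tb$x_km >= 0 & tb$x_km < 10 & tb$y_km >= 0 & tb$y_km < 10))
  expect_error(generateTurbines(g, 0), ">= 1")
  # bias concentrated on one pixel
  b <- matrix(0, 10, 10); b[4, 7] <- 1
  tb2 <- generateTurbines(g, 25, biasLayer = rasterLayer(g, b), seed = 3)
  px <- pointToPixel(g, tb2$x_km, tb2$y_km)
  expect_true(all(px$row == 4 & px$col == 7))
  # uniform draw: per-quadrant counts consistent with uniform (chi-square
  # statistic computed by hand against the 0.01 critical value)
  g4 <- gridSpec(100, 100)
  tb3 <- generateTurbines(g4, 5000, seed = 4)
  qx <- (tb3$x_km >= 50) + 2 * (tb3$y_km >= 50)
  counts <- tabulate(qx + 1, nbins = 4)
  chi <- sum((counts - 1250)^2 / 1250)
  expect_lt(chi, qchisq(0.99, df = 3))
})

test_that("fixture bundles are deterministic and round-trip cleanly", {
  sc <- defaultScenario(seed = 17, nRows = 25, nCols = 25)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  m1 <- writeFixtureBundle(sc, d1, nTurbines = 30)
  m2 <- writeFixtureBundle(sc, d2, nTurbines = 30)
  # byte-identical CSVs under the same scenario + seed
  expect_identical(unname(tools::md5sum(file.path(d1, "occurrences.csv"))),
                   unname(tools::md5sum(file.path(d2, "occurrences.csv"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "turbines.csv"))),
                   unname(tools::md5sum(file.path(d2, "turbines.csv"))))
  # manifest lists every covariate spec
  expect_setequal(names(m1$covariates), names(sc$covariateSpecs))
  # raster round-trip equals the in-memory layer within float tolerance
  rz <- realizeScenario(sc, nTurbines = 30)
  back <- readAsciiGrid(file.path(d1, "tmean_03.asc"))
  expect_equal(back@values, rz$monthlyMeans[[3]]@values, tolerance = 1e-6)
})

test_that("the default scenario draws the seven subsets at the configured counts", {
  sc <- defaultScenario(seed = 2, nRows = 60, nCols = 60)
  rz <- realizeScenario(sc, nTurbines = 10)
  tab <- table(sub("-[0-9]+$", "", rz$occurrences$id))
  expect_equal(as.integer(tab[names(sc$nPresences)]),
               unname(as.integer(sc$nPresences)))
  # records exceed locations, as in collections data
  px <- pointToPixel(sc$grid, rz$occurrences$x_km, rz$occurrences$y_km)
  expect_gt(nrow(rz$occurrences), nrow(unique(px)))
})
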