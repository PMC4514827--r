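monthlyLayers <- function(grid, values) {
  lapply(1:12, function(m)
    rasterLayer(grid, if (length(values) == 12) values[m] else values,
                name = sprintf("m%02d", m)))
}

test_that("seasonal temperature means average the right months and propagate nodata", {
  g <- gridSpec(3, 3)
  # all months constant 10 -> 10 everywhere
  mm <- monthlyLayers(g, rep(10, 12))
  expect_true(all(seasonalMeanTemperature(mm, "winter")@values == 10))
  # summer = Jun, Jul only
  vals <- rep(0, 12); vals[6] <- 20; vals[7] <- 30
  mm2 <- monthlyLayers(g, vals)
  expect_true(all(seasonalMeanTemperature(mm2, "summer")@values == 25))
  # autumn = Aug..Nov hand mean
  vals3 <- rep(0, 12); vals3[8:11] <- c(20, 15, 10, 5)
  expect_true(all(seasonalMeanTemperature(monthlyLayers(g, vals3),
                                          "autumn")@values == 12.5))
  # winter months are Dec, Jan, Feb
  vals4 <- rep(0, 12); vals4[c(12, 1, 2)] <- c(30, 10, 20)
  expect_true(all(seasonalMeanTemperature(monthlyLayers(g, vals4),
                                          "winter")@values == 20))
  # nodata in one month -> nodata at that pixel
  mm3 <- monthlyLayers(g, rep(10, 12))
  v <- mm3[[6]]@values; v[2, 2] <- NA; mm3[[6]]@values <- v
  out <- seasonalMeanTemperature(mm3, "summer")
  expect_true(is.na(out@values[2, 2]))
  expect_equal(out@values[1, 1], 10)
  # misaligned grids rejected
  mmBad <- mm; mmBad[[3]] <- rasterLayer(gridSpec(4, 4), 1)
  expect_error(seasonalMeanTemperature(mmBad, "spring"), "align")
  # linearity: scaling all monthly inputs scales the seasonal mean
  mm4 <- monthlyLayers(g, seq(1, 23, by = 2))
  mm4x <- lapply(mm4, function(l) rasterLayer(g, l@values * 3))
  expect_equal(seasonalMeanTemperature(mm4x, "autumn")@values,
               3 * seasonalMeanTemperature(mm4, "autumn")@values)
})

test_that("adjacent-season temperature uses the right season and direction", {
  g <- gridSpec(2, 2)
  vals <- 1:12  # month m has constant value m
  mm <- monthlyLayers(g, vals)
  # winter's prior season is autumn: mean(8,9,10,11)
  expect_true(all(adjacentSeasonTemperature(mm, "winter", "prior")@values ==
                    mean(8:11)))
  # autumn's next season is winter: mean(12, 1, 2)
  expect_true(all(adjacentSeasonTemperature(mm, "autumn", "next")@values ==
                    mean(c(12, 1, 2))))
  # spring's prior is winter
  expect_true(all(adjacentSeasonTemperature(mm, "spring", "prior")@values ==
                    mean(c(12, 1, 2))))
  # disallowed pairs rejected
  expect_error(adjacentSeasonTemperature(mm, "spring", "next"), "not defined")
  expect_error(adjacentSeasonTemperature(mm, "autumn", "prior"), "not defined")
})

test_that("seasonal range rescales degC*10 inputs on ingest", {
  g <- gridSpec(2, 2)
  mr <- monthlyLayers(g, rep(200, 12))
  expect_true(all(seasonalTemperatureRange(mr, "winter",
                                           inTenths = TRUE)@values == 20))
  vals <- rep(0, 12); vals[c(12, 1, 2)] <- c(10, 20, 30)
  expect_true(all(seasonalTemperatureRange(monthlyLayers(g, vals), "winter",
                                           inTenths = FALSE)@values == 20))
})

test_that("correlation screen drops one member of every over-threshold pair", {
  g <- gridSpec(40, 40)
  set.seed(8)
  a <- matrix(rnorm(1600), 40, 40)
  b <- matrix(rnorm(1600), 40, 40)
  layers <- list(a = rasterLayer(g, a), a_copy = rasterLayer(g, a),
                 b = rasterLayer(g, b))
  scr <- correlationScreen(layers, seed = 1)
  expect_equal(length(scr$retained), 2L)
  expect_equal(nrow(scr$report), 1L)
  expect_equal(scr$report$pearson, 1, tolerance = 1e-12)
  # independent noise layers both retained
  expect_true(all(c("b") %in% scr$retained))
  expect_lt(abs(cor(as.vector(a), as.vector(b))), 0.1)
})

test_that("the screen catches monotone nonlinear association via Spearman", {
  g <- gridSpec(50, 50)
  set.seed(9)
  z <- matrix(rnorm(2500), 50, 50)
  x <- z^3        # heavy-tailed
  y <- z^9        # monotone transform of x with modest Pearson r
  layers <- list(x = rasterLayer(g, x), y = rasterLayer(g, y))
  # oracle: correlations by direct formula on the full grid
  xv <- as.vector(x); yv <- as.vector(y)
  pearsonOracle <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
  rx <- rank(xv); ry <- rank(yv)
  spearmanOracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_lt(abs(pearsonOracle), 0.70)
  expect_gt(spearmanOracle, 0.99)
  scr <- correlationScreen(layers, seed = 2)
  expect_equal(length(scr$retained), 1L)
  expect_equal(scr$report$pearson, pearsonOracle, tolerance = 1e-10)
  expect_equal(scr$report$spearman, spearmanOracle, tolerance = 1e-10)
})

test_that("screening is order-stable and respects the drop-priority list", {
  g <- gridSpec(30, 30)
  set.seed(10)
  base <- matrix(rnorm(900), 30, 30)
  layers <- list(
    temp = rasterLayer(g, base + rnorm(900, sd = 0.1)),
    elevation = rasterLayer(g, -base + rnorm(900, sd = 0.1)),
    noise = rasterLayer(g, matrix(rnorm(900), 30, 30)))
  scr <- correlationScreen(layers, seed = 3)
  # the named priority variable is the one dropped
  expect_false("elevation" %in% scr$retained)
  expect_true(all(c("temp", "noise") %in% scr$retained))
  perm <- correlationScreen(layers[c(3, 1, 2)], seed = 3)
  expect_setequal(scr$retained, perm$retained)
  # constant layer flagged but retained
  layers$flat <- rasterLayer(g, 5)
  scr2 <- correlationScreen(layers, seed = 3)
  expect_true("flat" %in% scr2$retained)
  expect_true("flat" %in% scr2$constant)
})

test_that("background sampling is uniform, exact and reproducible", {
  g <- gridSpec(20, 20)
  all <- sampleBackground(g, 400, seed = 1)
  expect_equal(nrow(all), 400L)
  expect_equal(nrow(unique(all)), 400L)  # every pixel exactly once
  s1 <- sampleBackground(g, 50, seed = 9)
  s2 <- sampleBackground(g, 50, seed = 9)
  expect_identical(s1, s2)
  expect_error(sampleBackground(g, 401, seed = 1), "available")
  # per-row counts consistent with uniform (chi-square by hand)
  g2 <- gridSpec(100, 100)
  s <- sampleBackground(g2, 5000, seed = 4)
  rowCounts <- tabulate(s[, 1], nbins = 100)
  chi <- sum((rowCounts - 50)^2 / 50)
  expect_lt(chi, qchisq(0.99, df = 99))
  # masked pixels are never drawn
  mask <- matrix(1, 20, 20); mask[1:10, ] <- NA
  sM <- sampleBackground(g, 150, seed = 2,
                         excludeMask = rasterLayer(g, mask))
  expect_true(all(sM[, 1] > 10))
})

test_that("training tables resolve presence/background overlap and audit nodata", {
  g <- gridSpec(10, 10)
  v <- matrix(seq_len(100), 10, 10)
  stack <- makeTinyStack(g, list(a = v, b = v * 2))
  occPix <- cbind(row = 1:5, col = rep(1L, 5))
  occ <- new("OccupiedPixelSet", subset = "t", pixels = occPix,
             nRecords = 9L)
  bg <- cbind(row = c(1L, 2L, 6L, 7L, 8L, 9L, 10L, 1L, 2L, 3L),
              col = c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L))
  out <- assembleTrainingTable(occ, bg, stack)
  # 5 occupied + 10 background with 2 overlapping -> 13 rows, 5 presences
  expect_equal(nrow(out$table@data), 13L)
  expect_equal(sum(out$table@data$label), 5)
  # label sum equals usable occupied pixels (invariant)
  expect_equal(sum(out$table@data$label),
               nrow(unique(occPix)))
  # nodata covariate drops the row with an audit count
  v2 <- v; v2[6, 2] <- NA
  stack2 <- makeTinyStack(g, list(a = v2, b = v * 2))
  out2 <- assembleTrainingTable(occ, bg, stack2)
  expect_equal(out2$nDroppedNodata, 1L)
  expect_equal(nrow(out2$table@data), 12L)
  expect_error(assembleTrainingTable(
    new("OccupiedPixelSet", subset = "t",
        pixels = occPix[0, , drop = FALSE], nRecords = 0L), bg, stack),
    "empty presence")
})
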