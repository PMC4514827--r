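test_that("GLM matches maximum-likelihood logistic regression and recovers truth", {
  # null signal: intercept ~ logit(prevalence), slopes ~ 0
  set.seed(1)
  n <- 800
  d <- data.frame(row = 1:n, col = 1L, label = rbinom(n, 1, 0.25),
                  x = rnorm(n))
  tab <- new("TrainingTable", subset = "t", data = d, covariateNames = "x")
  m <- fitModel("GLM", tab)
  expect_equal(unname(m@fit$coef[1]), qlogis(mean(d$label)), tolerance = 0.25)
  # dual route: same ML problem solved by stats::glm
  ref <- glm(label ~ x + I(x^2), data = d, family = binomial())
  expect_equal(unname(m@fit$coef), unname(coef(ref)), tolerance = 1e-6)
  # label-independent covariates give training AUC near 1/2
  s <- predictSuitability(m, d)
  expect_lt(abs(computeAUC(s[d$label == 1], s[d$label == 0]) - 0.5), 0.08)

  # parameter recovery within 3 SEs on generative logistic data, n = 5000
  set.seed(2)
  x <- rnorm(5000)
  eta <- -1 + 1.5 * x - 0.5 * x^2
  y <- rbinom(5000, 1, plogis(eta))
  d2 <- data.frame(row = 1:5000, col = 1L, label = y, x = x)
  tab2 <- new("TrainingTable", subset = "t", data = d2, covariateNames = "x")
  m2 <- fitModel("GLM", tab2)
  ref2 <- glm(label ~ x + I(x^2), data = d2, family = binomial())
  se <- sqrt(diag(vcov(ref2)))
  expect_true(all(abs(m2@fit$coef - c(-1, 1.5, -0.5)) < 3 * se))
})

test_that("MARS recovers hinge structure and prunes pure noise", {
  # single-hinge truth: a fitted knot lies near the true knot
  set.seed(3)
  n <- 2000
  x <- runif(n, -2, 2)
  y <- rbinom(n, 1, plogis(-1 + 3 * pmax(0, x - 0.4)))
  d <- data.frame(row = 1:n, col = 1L, label = y, x = x)
  tab <- new("TrainingTable", subset = "t", data = d, covariateNames = "x")
  m <- fitModel("MARS", tab)
  b <- marsBasis(m)
  expect_gt(nrow(b), 0)
  band <- quantile(x, c(0.45, 0.65))  # central band around the knot's quantile
  expect_true(any(b$knot >= band[1] & b$knot <= band[2]))

  # pure noise: pruning returns intercept-only in most seeds
  interceptOnly <- vapply(1:10, function(s) {
    set.seed(100 + s)
    dn <- data.frame(row = 1:300, col = 1L, label = rbinom(300, 1, 0.3),
                     x1 = rnorm(300), x2 = rnorm(300))
    tn <- new("TrainingTable", subset = "t", data = dn,
              covariateNames = c("x1", "x2"))
    nrow(marsBasis(fitModel("MARS", tn))) == 0
  }, logical(1))
  expect_gte(sum(interceptOnly), 8)

  # piecewise-linear truth: MARS training deviance <= linear-only logistic
  dev <- function(p, y) -2 * sum(y * log(pmax(p, 1e-12)) +
                                   (1 - y) * log(pmax(1 - p, 1e-12)))
  pm <- predictSuitability(m, d)
  lin <- glm(label ~ x, data = d, family = binomial())
  expect_lte(dev(pm, y), dev(fitted(lin), y))

  # constant covariate is never selected
  d$flat <- 5
  tabF <- new("TrainingTable", subset = "t", data = d,
              covariateNames = c("x", "flat"))
  expect_false("flat" %in% marsBasis(fitModel("MARS", tabF))$var)
})

test_that("BRT reproduces leaf log-odds, decreases deviance, captures interactions", {
  # one unshrunk stump on a binary covariate = two-leaf empirical log-odds
  set.seed(4)
  x <- rep(c(0, 1), each = 150)
  y <- c(rbinom(150, 1, 0.2), rbinom(150, 1, 0.75))
  d <- data.frame(row = seq_along(x), col = 1L, label = y, v = x)
  tab <- new("TrainingTable", subset = "t", data = d, covariateNames = "v")
  m <- fitModel("BRT", tab, hp = list(nTreesMax = 1, depth = 1,
                                      shrinkage = 1, bagFraction = 1,
                                      valFraction = 0, minObs = 5))
  p <- predictSuitability(m, data.frame(v = c(0, 1)))
  expect_equal(p, c(mean(y[x == 0]), mean(y[x == 1])), tolerance = 1e-8)

  # shrinkage <= 0 rejected
  expect_error(fitModel("BRT", tab, hp = list(shrinkage = 0)), "shrinkage")

  # training deviance is non-increasing stage by stage (full bag, no stop)
  tt <- makeTinyTable(seed = 5, n1 = 80, n0 = 200)
  m2 <- fitModel("BRT", tt, hp = list(nTreesMax = 150, bagFraction = 1,
                                      valFraction = 0), seed = 6)
  tr <- brtDevianceTrace(m2)$train
  expect_true(all(diff(tr) <= 1e-10))

  # XOR-structured truth: trees beat the additive GLM out of sample
  set.seed(7)
  n <- 1200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(3 * sign(x1 * x2)))
  d3 <- data.frame(row = 1:n, col = 1L, label = y, x1 = x1, x2 = x2)
  trn <- 1:800; tst <- 801:n
  tabTr <- new("TrainingTable", subset = "t", data = d3[trn, ],
               covariateNames = c("x1", "x2"))
  mB <- fitModel("BRT", tabTr, seed = 8)
  mG <- fitModel("GLM", tabTr, seed = 8)
  sB <- predictSuitability(mB, d3[tst, ])
  sG <- predictSuitability(mG, d3[tst, ])
  isP <- d3$label[tst] == 1
  expect_gt(computeAUC(sB[isP], sB[!isP]), computeAUC(sG[isP], sG[!isP]))
})

test_that("RF votes give granular [0,1] suitabilities and honest OOB behavior", {
  tt <- makeTinyTable(seed = 9, n1 = 60, n0 = 150)
  m <- fitModel("RF", tt, hp = list(nTrees = 200), seed = 10)
  s <- predictSuitability(m, tt@data)
  expect_true(all(s >= 0 & s <= 1))
  # granularity 1/n_trees: vote fractions are multiples of 1/200
  expect_true(all(abs(s * 200 - round(s * 200)) < 1e-9))
  expect_error(fitModel("RF", tt, hp = list(nTrees = 0)), "tree")

  # perfectly separating covariate: out-of-bag votes align with labels
  set.seed(11)
  dSep <- data.frame(row = 1:200, col = 1L,
                     label = rep(c(0, 1), each = 100),
                     x = c(rnorm(100, -3), rnorm(100, 3)))
  tSep <- new("TrainingTable", subset = "t", data = dSep,
              covariateNames = "x")
  mS <- fitModel("RF", tSep, hp = list(nTrees = 200, keepInbag = TRUE),
                 seed = 12)
  oob <- rfOOBVotes(mS, tSep)
  expect_lt(mean(abs(oob - dSep$label), na.rm = TRUE), 0.05)

  # permuted labels: OOB AUC within Monte-Carlo error of 1/2
  set.seed(13)
  dP <- dSep
  dP$label <- sample(dP$label)
  tP <- new("TrainingTable", subset = "t", data = dP, covariateNames = "x")
  mP <- fitModel("RF", tP, hp = list(nTrees = 300, keepInbag = TRUE),
                 seed = 14)
  oobP <- rfOOBVotes(mP, tP)
  ok <- !is.na(oobP)
  aucP <- computeAUC(oobP[ok & dP$label == 1], oobP[ok & dP$label == 0])
  expect_lt(abs(aucP - 0.5), 0.12)
})

test_that("Maxent behaves as a regularized exponential-tilt density estimator", {
  # heavy regularization shrinks all features away -> uniform suitability
  tt <- makeTinyTable(seed = 15, n1 = 80, n0 = 300)
  mInf <- fitModel("MAXENT", tt, hp = list(penaltyMultiplier = 1e7))
  sInf <- predictSuitability(mInf, tt@data)
  expect_lt(diff(range(sInf)), 1e-6)
  expect_error(fitModel("MAXENT", tt, hp = list(penaltyMultiplier = -1)),
               "penaltyMultiplier")

  # discretized 1-D exponential tilt: fitted density ratio matches the
  # analytic tilt within 2%
  set.seed(16)
  grid <- seq(-2, 2, by = 0.25)
  bg <- sample(grid, 20000, replace = TRUE)
  wTilt <- exp(0.9 * grid)
  pres <- sample(grid, 4000, replace = TRUE, prob = wTilt)
  d <- data.frame(row = seq_len(24000), col = 1L,
                  label = rep(c(1, 0), c(4000, 20000)), x = c(pres, bg))
  tab <- new("TrainingTable", subset = "t", data = d, covariateNames = "x")
  # heavy background weighting approximates the infinite-weight limit
  mT <- fitModel("MAXENT", tab, hp = list(features = "l",
                                          penaltyMultiplier = 0,
                                          bgWeight = 2000))
  r <- maxentRaw(mT, data.frame(x = c(0, 1)))
  # oracle: the closed-form exponential tilt of the realized sample — the
  # beta solving the moment condition E_{q_beta}[x] = presence mean, with
  # q_beta proportional to the empirical background distribution times
  # exp(beta x); solved independently by uniroot
  bgTab <- table(bg) / length(bg)
  v <- as.numeric(names(bgTab)); pv <- as.numeric(bgTab)
  moment <- function(beta) sum(pv * exp(beta * v) * v) /
    sum(pv * exp(beta * v)) - mean(pres)
  betaStar <- uniroot(moment, c(0, 3), tol = 1e-10)$root
  expect_equal(betaStar, 0.9, tolerance = 0.1)   # sanity on the construction
  expect_equal(r[2] / r[1], exp(betaStar), tolerance = 0.02)

  # suitability rankings are invariant to affine covariate rescaling
  m1 <- fitModel("MAXENT", tt)
  s1 <- predictSuitability(m1, tt@data)
  tt2 <- tt
  tt2@data$driver <- 100 + 7 * tt2@data$driver
  m2 <- fitModel("MAXENT", tt2)
  s2 <- predictSuitability(m2, tt2@data)
  expect_equal(order(s1), order(s2))
})

test_that("cross-validation is stratified, deterministic and calibrated", {
  # perfectly separable data: mean AUC = 1 for every form
  set.seed(17)
  dSep <- data.frame(row = 1:260, col = 1L,
                     label = rep(c(1, 0), c(60, 200)),
                     x = c(runif(60, 2, 3), runif(200, -3, -2)))
  tSep <- new("TrainingTable", subset = "t", data = dSep,
              covariateNames = "x")
  for (fm in c("GLM", "MARS", "BRT", "RF", "MAXENT")) {
    cv <- crossValidate(fm, tSep, k = 10, seed = 18,
                        hp = if (fm == "RF") list(nTrees = 100) else list())
    expect_equal(cv@means[["auc"]], 1.0,
                 tolerance = 1e-9, label = paste(fm, "separable AUC"))
    expect_equal(nrow(cv@folds), 10L)
  }
  # label permutation: AUC within the Monte-Carlo band of 1/2
  dPerm <- dSep
  set.seed(19); dPerm$label <- sample(dPerm$label)
  tPerm <- new("TrainingTable", subset = "t", data = dPerm,
               covariateNames = "x")
  cvP <- crossValidate("GLM", tPerm, k = 10, seed = 20)
  expect_lt(abs(cvP@means[["auc"]] - 0.5), 0.12)
  # determinism: same seed, same folds and metrics
  cv1 <- crossValidate("BRT", tSep, k = 5, seed = 21)
  cv2 <- crossValidate("BRT", tSep, k = 5, seed = 21)
  expect_identical(cv1@folds, cv2@folds)
  # too few presences is rejected with advice
  tiny <- subsetTrainingTableForTest <- new(
    "TrainingTable", subset = "t",
    data = dSep[c(1:5, 61:200), ], covariateNames = "x")
  expect_error(crossValidate("GLM", tiny, k = 10), "reduce k")
})

test_that("surface prediction is consistent with vector prediction", {
  g <- gridSpec(15, 15)
  set.seed(22)
  ramp <- matrix(rep(seq(-2, 2, length.out = 15), each = 15), 15, 15)
  noise <- matrix(rnorm(225), 15, 15)
  stack <- makeTinyStack(g, list(driver = ramp, noise1 = noise))
  tt <- makeTinyTable(seed = 23, n1 = 60, n0 = 150)
  m <- fitModel("GLM", tt)
  surf <- predictSurface(m, stack)
  # surface at a pixel equals prediction on that pixel's covariate vector
  v <- predictSuitability(m, data.frame(driver = ramp[4, 9],
                                        noise1 = noise[4, 9]))
  expect_equal(surf@values[4, 9], v)
  # constant stack -> constant surface
  cst <- makeTinyStack(g, list(driver = matrix(1, 15, 15),
                               noise1 = matrix(0, 15, 15)))
  expect_lt(diff(range(predictSurface(m, cst)@values)), 1e-12)
  # nodata propagates
  ramp2 <- ramp; ramp2[3, 3] <- NA
  st2 <- makeTinyStack(g, list(driver = ramp2, noise1 = noise))
  expect_true(is.na(predictSurface(m, st2)@values[3, 3]))
  # covariate mismatch rejected, listing the missing name
  stBad <- makeTinyStack(g, list(driver = ramp))
  expect_error(predictSurface(m, stBad), "noise1")
  # monotone model (linear features only) + monotone ramp -> monotone surface
  mono <- fitModel("MAXENT", makeTinyTable(seed = 24, n1 = 100, n0 = 200,
                                           beta = 2, nNoise = 1),
                   hp = list(features = "l"))
  flat <- makeTinyStack(g, list(driver = ramp,
                                noise1 = matrix(0, 15, 15)))
  sv <- predictSurface(mono, flat)@values[1, ]
  expect_true(all(diff(sv) >= -1e-12))
})
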