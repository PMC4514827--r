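# The five presence-background model forms behind one fit/predict contract:
# logistic GLM (linear + quadratic terms), MARS (native forward/backward
# hinge regression), BRT (native compiled gradient boosting), RF (ranger,
# vote-fraction suitability) and a native Maxent-style penalized exponential
# model fit as an infinitely-weighted logistic regression.

MODEL_FORMS <- c("GLM", "MARS", "BRT", "RF", "MAXENT")

#' Default hyperparameters of the five model forms
#'
#' Community-standard presence-background defaults: GLM with linear and
#' quadratic terms (no stepwise selection); MARS additive (degree 1) with up
#' to 21 basis terms and GCV penalty 2; BRT with tree depth 3, shrinkage
#' 0.01, bag fraction 0.75 and up to 5,000 trees chosen by internal
#' validation; RF with 1,000 trees and floor(sqrt(p)) split candidates;
#' Maxent with linear, quadratic and hinge features at penalty multiplier 1.
#' All values are overridable per call or through the run configuration.
#'
#' @return named list of hyperparameter lists, one per form.
#' @export
defaultHyperparameters <- function() {
  list(
    GLM = list(),
    MARS = list(maxTerms = 21, penalty = 2, nKnots = 15),
    BRT = list(nTreesMax = 5000, depth = 3, shrinkage = 0.01,
               bagFraction = 0.75, minObs = 10, valFraction = 0.2,
               patience = 50),
    RF = list(nTrees = 1000, minNode = 1, keepInbag = FALSE),
    MAXENT = list(features = "lqh", nHingeKnots = 10, penaltyMultiplier = 1,
                  bgWeight = 100))
}

#' @keywords internal
mergeHp <- function(form, hp) {
  out <- defaultHyperparameters()[[form]]
  out[names(hp)] <- hp
  out
}

#' @keywords internal
tableData <- function(table) {
  if (is(table, "TrainingTable"))
    list(X = as.matrix(table@data[table@covariateNames]),
         y = table@data$label, names = table@covariateNames)
  else stop("expected a TrainingTable")
}

# Covariate matrix from arbitrary newdata, in training column order.
#' @keywords internal
covariateMatrix <- function(model, newdata) {
  nd <- if (is.matrix(newdata)) newdata else as.matrix(as.data.frame(newdata))
  miss <- setdiff(model@covariateNames, colnames(nd))
  if (length(miss))
    stop("newdata is missing covariate(s): ", paste(miss, collapse = ", "))
  nd[, model@covariateNames, drop = FALSE]
}

# Binomial fit with a ridge fallback when maximum likelihood is degenerate
# (complete separation drives coefficients to infinity).
#' @keywords internal
safeLogistic <- function(D, y) {
  fit <- suppressWarnings(stats::glm.fit(D, y, family = binomial()))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  bad <- !isTRUE(fit$converged) || max(abs(co)) > 30
  if (bad) {
    rf <- glmnet::glmnet(D[, -1, drop = FALSE], y, family = "binomial",
                         alpha = 0, lambda = 1e-3, standardize = FALSE)
    co <- c(as.numeric(rf$a0), as.numeric(rf$beta))
    if (!all(is.finite(co)))
      stop("logistic fit failed to converge even with ridge fallback")
  }
  list(coef = co, ridge = bad)
}

# ---- GLM ----------------------------------------------------------------

#' @keywords internal
fitGLM <- function(table, hp = list(), seed = 1) {
  td <- tableData(table)
  D <- cbind(1, td$X, td$X^2)
  colnames(D) <- c("(Intercept)", td$names, paste0(td$names, "_sq"))
  fit <- safeLogistic(D, td$y)
  new("GLMModel", form = "GLM", covariateNames = td$names,
      fit = list(coef = fit$coef, columns = colnames(D)),
      meta = list(seed = seed, hp = mergeHp("GLM", hp),
                  ridgeFallback = fit$ridge))
}

setMethod("predictSuitability", "GLMModel", function(model, newdata) {
  X <- covariateMatrix(model, newdata)
  D <- cbind(1, X, X^2)
  as.numeric(plogis(D %*% model@fit$coef))
})

# ---- MARS ---------------------------------------------------------------

#' @keywords internal
hingeBasisColumn <- function(x, knot, dir) {
  if (dir > 0) pmax(0, x - knot) else pmax(0, knot - x)
}

#' @keywords internal
marsDesign <- function(X, basis) {
  B <- matrix(1, nrow(X), 1 + length(basis))
  for (i in seq_along(basis)) {
    b <- basis[[i]]
    B[, i + 1] <- hingeBasisColumn(X[, b$var], b$knot, b$dir)
  }
  B
}

# Forward pass: greedily add reflected hinge pairs by exact least-squares
# RSS reduction (computed against the orthogonalized current basis);
# backward pass: prune single terms by generalized cross-validation.
#' @keywords internal
fitMARS <- function(table, hp = list(), seed = 1) {
  hp <- mergeHp("MARS", hp)
  td <- tableData(table)
  X <- td$X; y <- td$y; n <- nrow(X)
  knots <- lapply(seq_len(ncol(X)), function(j) {
    q <- unique(quantile(X[, j], probs = seq(0.05, 0.95,
                                             length.out = hp$nKnots)))
    q[q > min(X[, j]) & q < max(X[, j])]
  })
  cand <- do.call(rbind, lapply(seq_len(ncol(X)), function(j)
    if (length(knots[[j]])) data.frame(var = j, knot = knots[[j]]) else NULL))
  basis <- list()
  B <- matrix(1, n, 1)
  rss0 <- sum((y - mean(y))^2)

  if (!is.null(cand) && nrow(cand) > 0) {
    C1 <- vapply(seq_len(nrow(cand)), function(k)
      pmax(0, X[, cand$var[k]] - cand$knot[k]), numeric(n))
    C2 <- vapply(seq_len(nrow(cand)), function(k)
      pmax(0, cand$knot[k] - X[, cand$var[k]]), numeric(n))
    while (ncol(B) + 2 <= hp$maxTerms) {
      qrB <- qr(B)
      Q <- qr.Q(qrB)
      r <- y - Q %*% crossprod(Q, y)
      P1 <- C1 - Q %*% crossprod(Q, C1)
      P2 <- C2 - Q %*% crossprod(Q, C2)
      d1 <- colSums(P1^2); d2 <- colSums(P2^2); c12 <- colSums(P1 * P2)
      g1 <- as.numeric(crossprod(P1, r)); g2 <- as.numeric(crossprod(P2, r))
      det <- d1 * d2 - c12^2
      scale2 <- pmax(d1 * d2, 1e-300)
      red <- ifelse(det > 1e-10 * scale2,
                    (d2 * g1^2 - 2 * c12 * g1 * g2 + d1 * g2^2) / det,
                    pmax(ifelse(d1 > 1e-12, g1^2 / d1, 0),
                         ifelse(d2 > 1e-12, g2^2 / d2, 0)))
      best <- which.max(red)
      if (!length(best) || red[best] <= 1e-8 * rss0) break
      basis <- c(basis,
                 list(list(var = cand$var[best], knot = cand$knot[best], dir = 1),
                      list(var = cand$var[best], knot = cand$knot[best], dir = -1)))
      B <- cbind(B, C1[, best], C2[, best])
      keepCol <- colSums(abs(B)) > 1e-12
      B <- B[, keepCol, drop = FALSE]
      basis <- basis[keepCol[-1]]
    }
  }

  # backward pruning by GCV; effective parameters M + penalty*(M-1)/2
  gcv <- function(rss, M) {
    Ceff <- M + hp$penalty * (M - 1) / 2
    if (Ceff >= n) return(Inf)
    (rss / n) / (1 - Ceff / n)^2
  }
  sel <- seq_along(basis)
  fitRss <- function(cols) {
    Bi <- marsDesign(X, basis[cols])
    f <- lm.fit(Bi, y)
    sum(f$residuals^2)
  }
  bestSel <- sel
  bestGcv <- gcv(fitRss(sel), length(sel) + 1)
  cur <- sel
  while (length(cur) > 0) {
    trial <- vapply(seq_along(cur), function(i)
      gcv(fitRss(cur[-i]), length(cur)), numeric(1))
    i <- which.min(trial)
    cur <- cur[-i]
    if (trial[i] < bestGcv) { bestGcv <- trial[i]; bestSel <- cur }
  }
  basis <- basis[bestSel]

  Bfin <- marsDesign(X, basis)
  fit <- safeLogistic(Bfin, y)
  new("MARSModel", form = "MARS", covariateNames = td$names,
      fit = list(basis = lapply(basis, function(b)
        list(var = td$names[b$var], knot = b$knot, dir = b$dir)),
        coef = fit$coef),
      meta = list(seed = seed, hp = hp, ridgeFallback = fit$ridge))
}

setMethod("predictSuitability", "MARSModel", function(model, newdata) {
  X <- covariateMatrix(model, newdata)
  basis <- model@fit$basis
  B <- matrix(1, nrow(X), 1 + length(basis))
  for (i in seq_along(basis)) {
    b <- basis[[i]]
    B[, i + 1] <- hingeBasisColumn(X[, b$var], b$knot, b$dir)
  }
  as.numeric(plogis(B %*% model@fit$coef))
})

#' Basis functions of a fitted MARS model
#' @param model a \linkS4class{MARSModel}.
#' @return data.frame with columns \code{var}, \code{knot}, \code{dir},
#'   \code{coef} (empty for an intercept-only model).
#' @export
marsBasis <- function(model) {
  stopifnot(is(model, "MARSModel"))
  b <- model@fit$basis
  if (!length(b))
    return(data.frame(var = character(0), knot = numeric(0),
                      dir = integer(0), coef = numeric(0)))
  data.frame(var = vapply(b, `[[`, character(1), "var"),
             knot = vapply(b, `[[`, numeric(1), "knot"),
             dir = vapply(b, `[[`, numeric(1), "dir"),
             coef = model@fit$coef[-1])
}

# ---- BRT ----------------------------------------------------------------

#' @keywords internal
fitBRT <- function(table, hp = list(), seed = 1) {
  hp <- mergeHp("BRT", hp)
  if (hp$shrinkage <= 0) stop("BRT shrinkage must be > 0")
  td <- tableData(table)
  n <- nrow(td$X)
  res <- withSeed(seed, {
    if (hp$valFraction > 0) {
      # stratified internal-validation split so both classes are tracked
      pres <- which(td$y == 1); bg <- which(td$y == 0)
      vp <- sample(pres, max(1, round(hp$valFraction * length(pres))))
      vb <- sample(bg, max(1, round(hp$valFraction * length(bg))))
      val <- c(vp, vb)
      train <- setdiff(seq_len(n), val)
    } else {
      train <- seq_len(n); val <- integer(0)
    }
    .brt_fit_cpp(td$X, as.numeric(td$y), train - 1L, val - 1L,
                 as.integer(hp$nTreesMax), as.integer(hp$depth),
                 hp$shrinkage, hp$bagFraction, as.integer(hp$minObs),
                 as.integer(hp$patience))
  })
  new("BRTModel", form = "BRT", covariateNames = td$names, fit = res,
      meta = list(seed = seed, hp = hp, nTrees = res$nTrees))
}

setMethod("predictSuitability", "BRTModel", function(model, newdata) {
  X <- covariateMatrix(model, newdata)
  as.numeric(plogis(.brt_predict_cpp(model@fit$trees, model@fit$f0,
                                     model@fit$shrinkage, X)))
})

#' Training and internal-validation deviance traces of a BRT fit
#' @param model a \linkS4class{BRTModel}.
#' @return data.frame with columns \code{tree}, \code{train}, \code{val}
#'   (NA when no internal validation split was used).
#' @export
brtDevianceTrace <- function(model) {
  stopifnot(is(model, "BRTModel"))
  tr <- model@fit$trainDeviance
  va <- model@fit$valDeviance
  data.frame(tree = seq_along(tr), train = tr,
             val = if (length(va)) va else NA_real_)
}

# ---- RF -----------------------------------------------------------------

#' @keywords internal
fitRF <- function(table, hp = list(), seed = 1) {
  hp <- mergeHp("RF", hp)
  if (hp$nTrees < 1) stop("RF needs at least one tree")
  td <- tableData(table)
  if (is.null(hp$mtry)) hp$mtry <- max(1, floor(sqrt(ncol(td$X))))
  d <- data.frame(.label = factor(td$y, levels = c(0, 1)), td$X)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = d,
    num.trees = hp$nTrees, mtry = hp$mtry, min.node.size = hp$minNode,
    keep.inbag = isTRUE(hp$keepInbag), num.threads = 1,
    seed = as.integer(seed), verbose = FALSE)
  new("RFModel", form = "RF", covariateNames = td$names, fit = fit,
      meta = list(seed = seed, hp = hp))
}

# Suitability = fraction of trees voting presence; per-tree predictions are
# chunked to bound memory.
setMethod("predictSuitability", "RFModel", function(model, newdata) {
  X <- covariateMatrix(model, newdata)
  ntree <- model@fit$num.trees
  presLevel <- match("1", model@fit$forest$levels)
  n <- nrow(X)
  chunk <- max(1L, as.integer(ceiling(2e7 / ntree)))
  out <- numeric(n)
  d <- as.data.frame(X)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    pr <- predict(model@fit, data = d[s:e, , drop = FALSE],
                  predict.all = TRUE, num.threads = 1)$predictions
    out[s:e] <- rowMeans(pr == presLevel)
  }
  out
})

#' Out-of-bag vote-fraction suitabilities of an RF fit
#'
#' Requires the model to have been fitted with \code{keepInbag = TRUE}.
#'
#' @param model an \linkS4class{RFModel}.
#' @param table the training \linkS4class{TrainingTable}.
#' @return numeric vector of out-of-bag presence vote fractions (NA for rows
#'   never out of bag).
#' @export
rfOOBVotes <- function(model, table) {
  stopifnot(is(model, "RFModel"))
  inbag <- model@fit$inbag.counts
  if (is.null(inbag))
    stop("model was fitted without keepInbag = TRUE")
  td <- tableData(table)
  pr <- predict(model@fit, data = as.data.frame(td$X),
                predict.all = TRUE, num.threads = 1)$predictions
  presLevel <- match("1", model@fit$forest$levels)
  inb <- do.call(cbind, inbag)   # n x ntree
  oob <- inb == 0
  votes <- rowSums((pr == presLevel) * oob)
  nOob <- rowSums(oob)
  ifelse(nOob > 0, votes / nOob, NA_real_)
}

# ---- Maxent -------------------------------------------------------------

# Feature expansion on internally standardized covariates: linear z,
# quadratic z^2, and unscaled reflected hinges at symmetric quantile knots.
# The symmetric construction makes suitability rankings exactly invariant to
# affine rescaling of any covariate.
#' @keywords internal
maxentFeatureDef <- function(X, features, nHingeKnots) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0] <- 1
  hinges <- NULL
  if (grepl("h", features)) {
    hinges <- lapply(seq_len(ncol(X)), function(j) {
      z <- (X[, j] - center[j]) / scale[j]
      q <- unique(quantile(z, probs = seq(0.05, 0.95,
                                          length.out = nHingeKnots)))
      q[q > min(z) & q < max(z)]
    })
  }
  list(center = center, scale = scale, features = features, hinges = hinges,
       names = colnames(X))
}

#' @keywords internal
maxentFeatures <- function(def, X) {
  Z <- sweep(sweep(X, 2, def$center), 2, def$scale, "/")
  cols <- list()
  nm <- character(0)
  if (grepl("l", def$features)) { cols <- c(cols, list(Z)); nm <- c(nm, paste0("l_", def$names)) }
  if (grepl("q", def$features)) { cols <- c(cols, list(Z^2)); nm <- c(nm, paste0("q_", def$names)) }
  if (grepl("h", def$features) && !is.null(def$hinges)) {
    for (j in seq_along(def$hinges)) {
      for (k in def$hinges[[j]]) {
        cols <- c(cols, list(cbind(pmax(0, Z[, j] - k), pmax(0, k - Z[, j]))))
        nm <- c(nm, paste0("hf_", def$names[j], "_", signif(k, 4)),
                paste0("hr_", def$names[j], "_", signif(k, 4)))
      }
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- nm
  out
}

# Per-feature-class regularization multipliers in the Maxent tradition:
# hinge features are penalized harder than linear/quadratic ones.
#' @keywords internal
maxentRegVector <- function(featureNames) {
  cls <- substr(featureNames, 1, 1)
  ifelse(cls == "l", 0.05, ifelse(cls == "q", 0.1, 0.5))
}

#' @keywords internal
fitMaxent <- function(table, hp = list(), seed = 1) {
  hp <- mergeHp("MAXENT", hp)
  if (hp$penaltyMultiplier < 0) stop("penaltyMultiplier must be >= 0")
  td <- tableData(table)
  def <- maxentFeatureDef(td$X, hp$features, hp$nHingeKnots)
  Fx <- maxentFeatures(def, td$X)
  nFeat <- ncol(Fx)
  if (nFeat < 2) Fx <- cbind(Fx, .pad = 0)   # glmnet needs >= 2 columns
  y <- td$y
  w <- ifelse(y == 1, 1, hp$bgWeight)
  np <- sum(y == 1)
  if (hp$penaltyMultiplier == 0) {
    fit <- glmnet::glmnet(Fx, y, family = "binomial", weights = w,
                          standardize = FALSE, thresh = 1e-8,
                          lambda = c(0.01, 0.001, 0))
  } else {
    # fit glmnet's own regularization path, then read the solution at the
    # Maxent-style target: mean feature regularization times the presence
    # weight share, scaled by the penalty multiplier
    reg <- maxentRegVector(colnames(Fx))
    target <- hp$penaltyMultiplier * mean(reg) * np / sum(w)
    fit <- glmnet::glmnet(Fx, y, family = "binomial", weights = w,
                          standardize = FALSE, penalty.factor = reg,
                          nlambda = 100, lambda.min.ratio = 1e-5)
    iLam <- which.min(abs(log(fit$lambda) - log(target)))
    beta <- as.numeric(fit$beta[, iLam])[seq_len(nFeat)]
  }
  if (hp$penaltyMultiplier == 0)
    beta <- as.numeric(fit$beta[, ncol(fit$beta)])[seq_len(nFeat)]
  etaBg <- as.numeric(Fx[y == 0, seq_len(nFeat), drop = FALSE] %*% beta)
  m <- max(etaBg)
  logZ <- m + log(sum(exp(etaBg - m)))
  pBg <- exp(etaBg - logZ)
  entropy <- -sum(pBg * log(pmax(pBg, 1e-300)))
  new("MaxentModel", form = "MAXENT", covariateNames = td$names,
      fit = list(def = def, beta = beta, alpha = -logZ, entropy = entropy),
      meta = list(seed = seed, hp = hp))
}

setMethod("predictSuitability", "MaxentModel", function(model, newdata) {
  X <- covariateMatrix(model, newdata)
  Fx <- maxentFeatures(model@fit$def, X)
  eta <- as.numeric(Fx %*% model@fit$beta)
  as.numeric(plogis(eta + model@fit$alpha + model@fit$entropy))
})

#' Raw (exponential-model) density ratio of a Maxent fit
#'
#' \eqn{e^{\eta(x)}/Z} with \eqn{Z} the training-background normalizer; the
#' relative values estimate the presence/background density ratio up to a
#' constant.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param newdata covariate matrix/data.frame.
#' @return numeric vector of raw relative densities.
#' @export
maxentRaw <- function(model, newdata) {
  X <- covariateMatrix(model, newdata)
  Fx <- maxentFeatures(model@fit$def, X)
  exp(as.numeric(Fx %*% model@fit$beta) + model@fit$alpha)
}

# ---- registry, CV, surfaces --------------------------------------------

#' Fit one of the five model forms
#'
#' Uniform entry point: \code{fitModel("RF", table)} etc. Hyperparameters
#' not supplied fall back to \code{\link{defaultHyperparameters}}.
#'
#' @param form one of \code{"GLM"}, \code{"MARS"}, \code{"BRT"}, \code{"RF"},
#'   \code{"MAXENT"}.
#' @param table a \linkS4class{TrainingTable}.
#' @param hp named list of hyperparameter overrides.
#' @param seed integer seed for the form's stochastic components.
#' @return a fitted \linkS4class{SDMModel}.
#' @export
fitModel <- function(form, table, hp = list(), seed = 1) {
  form <- toupper(form)
  if (!form %in% MODEL_FORMS)
    stop("unknown model form '", form, "' (choose from ",
         paste(MODEL_FORMS, collapse = ", "), ")")
  switch(form,
         GLM = fitGLM(table, hp, seed), MARS = fitMARS(table, hp, seed),
         BRT = fitBRT(table, hp, seed), RF = fitRF(table, hp, seed),
         MAXENT = fitMaxent(table, hp, seed))
}

#' @keywords internal
subsetTrainingTable <- function(table, rows) {
  new("TrainingTable", subset = table@subset,
      data = table@data[rows, , drop = FALSE],
      covariateNames = table@covariateNames)
}

#' k-fold cross-validation of one model form
#'
#' Folds are stratified on the presence/background label so every held-out
#' fold contains presences (threshold-dependent metrics need them). For each
#' fold the model is fit on the remaining folds, the
#' minimum-training-presence threshold is taken from the training partition,
#' and AUC, sensitivity and specificity are computed on the held-out fold
#' (its background rows are the evaluation background). Reported means are
#' arithmetic means over folds.
#'
#' @param form model form name.
#' @param table a \linkS4class{TrainingTable}.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment and per-fold fits.
#' @param hp hyperparameter overrides for the form.
#' @return a \linkS4class{CVResult}.
#' @export
crossValidate <- function(form, table, k = 10, seed = 1, hp = list()) {
  d <- table@data
  pres <- which(d$label == 1); bg <- which(d$label == 0)
  if (length(pres) < k)
    stop("only ", length(pres), " presence rows but k = ", k,
         "; reduce k or supply more presences")
  if (length(bg) < k)
    stop("only ", length(bg), " background rows but k = ", k)
  fold <- integer(nrow(d))
  withSeed(stageSeed(seed, paste0("folds:", form, ":", table@subset)), {
    fold[pres] <- rep_len(1:k, length(pres))[sample(length(pres))]
    fold[bg] <- rep_len(1:k, length(bg))[sample(length(bg))]
  })
  rows <- lapply(1:k, function(i) {
    trainIdx <- which(fold != i); testIdx <- which(fold == i)
    trainTab <- subsetTrainingTable(table, trainIdx)
    m <- fitModel(form, trainTab, hp = hp,
                  seed = stageSeed(seed, paste0("fit:", form, ":", i)))
    thr <- mtpThreshold(m, trainTab@data[trainTab@data$label == 1,
                                         table@covariateNames, drop = FALSE])
    sc <- predictSuitability(m, d[testIdx, table@covariateNames, drop = FALSE])
    isP <- d$label[testIdx] == 1
    cm <- confusionAtThreshold(sc[isP], sc[!isP], thr)
    data.frame(fold = i, auc = computeAUC(sc[isP], sc[!isP]),
               sensitivity = cm[["sensitivity"]],
               specificity = cm[["specificity"]], threshold = thr)
  })
  folds <- do.call(rbind, rows)
  means <- colMeans(folds[c("auc", "sensitivity", "specificity", "threshold")])
  new("CVResult", form = form, subset = table@subset, folds = folds,
      means = means)
}

#' Predict a suitability surface over a predictor stack
#'
#' @param model a fitted \linkS4class{SDMModel}.
#' @param stack a \linkS4class{PredictorStack} whose layer names cover the
#'   model's training covariates (mismatches are rejected, listing the
#'   differences).
#' @return a \linkS4class{RasterLayer} of suitabilities in [0, 1]; pixels
#'   with nodata in any covariate are nodata.
#' @export
predictSurface <- function(model, stack) {
  have <- names(stack@layers)
  miss <- setdiff(model@covariateNames, have)
  if (length(miss))
    stop("stack lacks covariate(s) the model needs: ",
         paste(miss, collapse = ", "))
  g <- stack@layers[[1]]@grid
  M <- vapply(model@covariateNames, function(nm)
    as.vector(stack@layers[[nm]]@values), numeric(g@nRows * g@nCols))
  ok <- stats::complete.cases(M)
  out <- rep(NA_real_, nrow(M))
  if (any(ok))
    out[ok] <- predictSuitability(model, M[ok, , drop = FALSE])
  rasterLayer(g, matrix(out, g@nRows, g@nCols),
              name = paste0("suitability_", model@form),
              units = "suitability")
}
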