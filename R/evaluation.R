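# Threshold-independent and threshold-dependent model evaluation, and
# permutation delta-AUC variable importance.

#' Rank-based AUC (Mann-Whitney)
#'
#' The probability that a randomly chosen presence receives a higher score
#' than a randomly chosen background pixel, with ties counted one half —
#' equivalently the area under the empirical ROC curve.
#'
#' @param presenceScores,backgroundScores non-empty numeric score vectors.
#' @return AUC in [0, 1].
#' @examples
#' computeAUC(c(0.9, 0.8), c(0.1, 0.2))   # perfect separation: 1
#' @export
computeAUC <- function(presenceScores, backgroundScores) {
  np <- length(presenceScores); nb <- length(backgroundScores)
  if (np == 0 || nb == 0) stop("both score lists must be non-empty")
  r <- rank(c(presenceScores, backgroundScores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Minimum-training-presence threshold
#'
#' The lowest suitability the model predicts for any training presence. With
#' the classification rule "predicted >= threshold => presence", every
#' training presence classifies as present, so training sensitivity is
#' exactly 1 by construction.
#'
#' @param model a fitted \linkS4class{SDMModel}.
#' @param presenceVectors matrix/data.frame of the training presences'
#'   covariates.
#' @return the threshold (a suitability value).
#' @export
mtpThreshold <- function(model, presenceVectors) {
  min(predictSuitability(model, presenceVectors))
}

#' Sensitivity and specificity at a threshold
#'
#' Presences scoring at or above the threshold count as predicted presences
#' (ties at the threshold are presences, which is what makes the
#' minimum-training-presence rule give training sensitivity 1); background
#' scoring strictly below counts as correctly predicted background.
#'
#' @param presenceScores,backgroundScores numeric score vectors.
#' @param threshold classification threshold.
#' @return named numeric vector \code{c(sensitivity=, specificity=)}.
#' @export
confusionAtThreshold <- function(presenceScores, backgroundScores, threshold) {
  if (!length(presenceScores) || !length(backgroundScores))
    stop("both score lists must be non-empty")
  c(sensitivity = mean(presenceScores >= threshold),
    specificity = mean(backgroundScores < threshold))
}

#' Permutation delta-AUC of one covariate
#'
#' The drop in AUC when the covariate's column is randomly shuffled (other
#' columns intact): \eqn{\Delta AUC = AUC_{orig} - mean_r AUC_{perm(r)}}
#' over \code{nRepeats} independent permutations. Large values mean the
#' model leans on the covariate; values near zero (possibly slightly
#' negative, by Monte-Carlo noise) mean it is ignored.
#'
#' @param model a fitted \linkS4class{SDMModel}.
#' @param table a \linkS4class{TrainingTable} (or data.frame with
#'   \code{label} and covariate columns) to evaluate on.
#' @param variable covariate name to permute.
#' @param nRepeats number of independent permutations (default 10).
#' @param seed integer seed.
#' @return the mean delta-AUC (a single number).
#' @export
permutationImportance <- function(model, table, variable, nRepeats = 10,
                                  seed = 1) {
  d <- if (is(table, "TrainingTable")) table@data else table
  if (!variable %in% names(d)) stop("variable not in table: ", variable)
  if (nRepeats < 1) stop("nRepeats must be >= 1")
  pres <- d$label == 1
  base <- predictSuitability(model, d)
  auc0 <- computeAUC(base[pres], base[!pres])
  aucPerm <- withSeed(seed, vapply(seq_len(nRepeats), function(r) {
    dp <- d
    dp[[variable]] <- sample(dp[[variable]])
    s <- predictSuitability(model, dp)
    computeAUC(s[pres], s[!pres])
  }, numeric(1)))
  auc0 - mean(aucPerm)
}

#' Rank covariates by mean permutation delta-AUC across forms
#'
#' @param deltaTable data.frame with a \code{variable} column and one
#'   delta-AUC column per model form (all forms over the same variable set).
#' @return data.frame ordered by descending mean delta-AUC with columns
#'   \code{variable}, the per-form columns, \code{mean_dauc} and \code{rank};
#'   ties in the mean break alphabetically by variable name.
#' @export
rankImportance <- function(deltaTable) {
  if (!"variable" %in% names(deltaTable)) stop("need a 'variable' column")
  forms <- setdiff(names(deltaTable), "variable")
  if (!length(forms)) stop("need at least one per-form delta-AUC column")
  if (anyNA(deltaTable[forms]))
    stop("inconsistent variable sets: missing delta-AUC values")
  m <- rowMeans(deltaTable[forms])
  out <- deltaTable
  out$mean_dauc <- as.numeric(m)
  ord <- order(-out$mean_dauc, out$variable)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full permutation-importance table for a set of fitted models
#'
#' @param models named list of fitted \linkS4class{SDMModel}s (names = form).
#' @param table the evaluation \linkS4class{TrainingTable}.
#' @param nRepeats permutations per variable.
#' @param seed integer seed (streams are per form x variable).
#' @return the ranked importance data.frame from \code{\link{rankImportance}}.
#' @export
importanceTable <- function(models, table, nRepeats = 10, seed = 1) {
  vars <- table@covariateNames
  cols <- lapply(names(models), function(fm)
    vapply(vars, function(v)
      permutationImportance(models[[fm]], table, v, nRepeats = nRepeats,
                            seed = stageSeed(seed, paste0("imp:", fm, ":", v))),
      numeric(1)))
  d <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (i in seq_along(models)) d[[names(models)[i]]] <- cols[[i]]
  rankImportance(d)
}
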