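# Family-stratified cross-validation, accuracy scaling, model comparison
# and predictor-reduction experiments.

#' Family-stratified fold assignment
#'
#' Within every family, lines are split as evenly as possible into
#' \code{nFolds} disjoint folds covering the family (largest-remainder
#' allocation via shuffled cyclic labels), so each fold's complement is a
#' training set of roughly (nFolds-1)/nFolds of every family. Families
#' smaller than \code{nFolds} have their lines spread over distinct folds
#' with a warning.
#'
#' @param families character/factor family label per line.
#' @param nFolds number of folds (>= 2, default 5).
#' @param seed integer seed; equal seeds give identical partitions.
#' @return Integer fold assignment in 1..nFolds, one per line.
#' @export
stratifiedPartition <- function(families, nFolds = 5L, seed = 1L) {
  nFolds <- .assertCount(nFolds, "nFolds", min = 2)
  families <- as.character(families)
  n <- length(families)
  fold <- integer(n)
  .withSeed(.subSeed(seed, "partition"), {
    for (f in unique(families)) {
      idx <- which(families == f)
      if (length(idx) < nFolds)
        warning(sprintf(
          "family %s has %d lines for %d folds; assigning to distinct folds",
          f, length(idx), nFolds))
      labs <- rep_len(sample.int(nFolds), length(idx))
      fold[idx] <- labs[sample.int(length(labs))]
    }
  })
  fold
}

#' Prediction accuracy from prediction ability
#'
#' r_ac = r_ab / sqrt(h2). May exceed 1 for low-heritability traits.
#'
#' @param rAb prediction ability (mean observed-predicted correlation).
#' @param h2 trait heritability in (0, 1].
#' @return The accuracy.
#' @examples
#' predictionAccuracy(0.93, 0.91)
#' @export
predictionAccuracy <- function(rAb, h2) {
  if (any(h2 <= 0)) stop("accuracy undefined for h2 <= 0")
  if (any(h2 > 1)) stop("h2 must lie in (0, 1]")
  rAb / sqrt(h2)
}

# Fit + predict one CV evaluation for the given model spec.
.cvFit <- function(yTrain, XTrain, XTest, model, lambda, priors, seed) {
  if (model == "rr_blup") {
    lam <- if (is.null(lambda)) {
      # no plug-in penalty given: REML on the additive kernel inside the
      # training fold; K = Xc Xc'/m, so lambda = m * res / comp
      Xc <- scale(XTrain, center = TRUE, scale = FALSE)
      fit <- .remlKernels(as.numeric(scale(yTrain)),
                          list(G = tcrossprod(Xc) / ncol(Xc)),
                          starts = c(0.5, 5))
      ncol(Xc) * fit$residual / max(fit$components[["G"]], 1e-8)
    } else lambda
    eff <- fitRrblup(yTrain, XTrain, lam)
  } else {
    eff <- fitBayesb(yTrain, XTrain, priors, seed = seed)
  }
  predictValues(eff, XTest)
}

#' Cross-validated prediction ability and accuracy
#'
#' Runs \code{nRuns / nFolds} independent stratified \code{nFolds}-fold
#' partitions (the default 100 runs = 20 replicates of 5-fold), fitting on
#' training lines only and recording, per evaluation, the Pearson
#' correlation between observed and predicted values in the held-out
#' lines. A run with constant predictions records ability 0 with a
#' warning. Accuracies are abilities divided by sqrt(h2).
#'
#' @param y named numeric response or \linkS4class{TraitBLUEs} (its h2 is
#'   used unless \code{h2} is given).
#' @param X predictor matrix, rows aligned to \code{y} by name.
#' @param families family label per line of \code{X}.
#' @param model "rr_blup" or "bayes_b".
#' @param nRuns total evaluations; must be a multiple of \code{nFolds}.
#' @param nFolds folds per replicate (default 5).
#' @param seed integer seed controlling partitions and sampler streams.
#' @param lambda RR-BLUP plug-in penalty; NULL re-estimates it by REML
#'   inside every training fold.
#' @param priors \linkS4class{BayesBPriors} for BayesB.
#' @param h2 heritability for accuracy scaling (NA disables scaling).
#' @param trait,predictorSet labels stored in the result.
#' @return A \linkS4class{CVResult}.
#' @export
runCrossValidation <- function(y, X, families, model = c("rr_blup", "bayes_b"),
                               nRuns = 100L, nFolds = 5L, seed = 1L,
                               lambda = NULL, priors = bayesbPriors(),
                               h2 = NULL, trait = "trait",
                               predictorSet = "predictors") {
  model <- match.arg(model)
  if (is(y, "TraitBLUEs")) {
    if (is.null(h2)) h2 <- heritability(y)
    trait <- y@trait
    y <- blues(y)
  }
  if (is.null(h2)) h2 <- NA_real_
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    common <- intersect(rownames(X), names(y))
    if (length(common) < nrow(X))
      warning("restricting to ", length(common), " lines present in both")
    families <- families[match(common, rownames(X))]
    X <- X[common, , drop = FALSE]
    y <- y[common]
  }
  nFolds <- .assertCount(nFolds, "nFolds", min = 2)
  nRuns <- .assertCount(nRuns, "nRuns")
  if (nRuns %% nFolds != 0)
    stop("'nRuns' must be a multiple of 'nFolds'")
  nReps <- nRuns %/% nFolds
  ab <- numeric(0)
  for (rep in seq_len(nReps)) {
    fold <- stratifiedPartition(families, nFolds,
                                seed = .subSeed(seed, sprintf("rep%d", rep)))
    for (k in seq_len(nFolds)) {
      test <- fold == k
      pred <- .cvFit(y[!test], X[!test, , drop = FALSE],
                     X[test, , drop = FALSE], model, lambda, priors,
                     seed = .subSeed(seed, sprintf("fit%d_%d", rep, k)))
      if (stats::sd(pred) == 0 || stats::sd(y[test]) == 0) {
        warning("constant predictions in one evaluation; ability set to 0")
        r <- 0
      } else r <- stats::cor(y[test], pred)
      ab <- c(ab, r)
    }
  }
  rAb <- mean(ab)
  acc <- if (is.finite(h2)) ab / sqrt(h2) else ab
  new("CVResult", abilities = ab, rAb = rAb,
      rAc = if (is.finite(h2)) rAb / sqrt(h2) else NA_real_,
      sd = stats::sd(acc), h2 = as.numeric(h2), model = model,
      predictorSet = predictorSet, trait = trait,
      nFolds = nFolds, nRuns = nRuns, seed = as.integer(seed))
}

#' Two-sided t-test between two cross-validation results
#'
#' Compares per-run accuracies (abilities when no h2 is attached) with
#' Welch's two-sample t-test by default; \code{paired = TRUE} uses a paired
#' test and is appropriate when both results were produced with identical
#' partitions (same seed, folds and runs).
#'
#' @param a,b \linkS4class{CVResult} objects with equal run counts.
#' @param alpha significance level (default 0.01).
#' @param paired use a paired t-test.
#' @return list with \code{statistic}, \code{p.value},
#'   \code{significant}.
#' @export
compareModels <- function(a, b, alpha = 0.01, paired = FALSE) {
  stopifnot(is(a, "CVResult"), is(b, "CVResult"))
  if (a@nRuns != b@nRuns) stop("run counts differ")
  va <- if (is.finite(a@h2)) a@abilities / sqrt(a@h2) else a@abilities
  vb <- if (is.finite(b@h2)) b@abilities / sqrt(b@h2) else b@abilities
  if (stats::sd(va) == 0 && stats::sd(vb) == 0)
    stop("zero variance in both samples; t-test undefined")
  tt <- stats::t.test(va, vb, paired = paired)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       significant = tt$p.value < alpha)
}

#' Select a predictor subset from fitted effects
#'
#' mode "best" keeps the \code{round(fraction * m)} predictors with the
#' largest absolute effects; mode "random" draws a uniform sample of the
#' same size without replacement.
#'
#' @param effects a \linkS4class{MarkerEffects} fitted on the full set.
#' @param fraction fraction of predictors to keep, in (0, 1].
#' @param mode "best" or "random".
#' @param seed integer seed (random mode).
#' @return Character vector of selected predictor ids.
#' @export
subsetPredictors <- function(effects, fraction, mode = c("best", "random"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(effects, "MarkerEffects"))
  if (fraction <= 0 || fraction > 1) stop("'fraction' must lie in (0, 1]")
  g <- effects@effects
  m <- length(g)
  size <- round(fraction * m)
  if (size < 1) stop("fraction * m below 1 predictor")
  if (mode == "best") {
    names(g)[order(-abs(g))[seq_len(size)]]
  } else {
    .withSeed(.subSeed(seed, "subset"), sample(names(g), size))
  }
}

#' Predictor-reduction experiment
#'
#' Fits effects once on the full predictor set, then for every (fraction,
#' mode) combination selects a subset and reruns the full cross-validation
#' on the reduced matrix, tabulating ability and accuracy. Selection from
#' full-data effects follows the published procedure even though it leaks
#' test information into the selection step; set
#' \code{selectionWithinFold = TRUE} for a leakage-free variant that
#' re-selects inside every training fold (logged with a note).
#'
#' @inheritParams runCrossValidation
#' @param fractions subset fractions (default 0.5, 0.25, 0.1).
#' @param modes subset modes (default best and random).
#' @param effects optional precomputed full-set \linkS4class{MarkerEffects}.
#' @param selectionModel model used to fit the full-set effects when
#'   \code{effects} is NULL (default the CV model).
#' @param selectionWithinFold re-select inside each training fold.
#' @param verbose log selected subset sizes.
#' @return data.frame with fraction, mode, size, rAb, rAc, sd.
#' @export
reductionExperiment <- function(y, X, families, model = c("rr_blup", "bayes_b"),
                                fractions = c(0.5, 0.25, 0.1),
                                modes = c("best", "random"), nRuns = 100L,
                                nFolds = 5L, seed = 1L, lambda = NULL,
                                priors = bayesbPriors(), h2 = NULL,
                                effects = NULL, selectionModel = NULL,
                                selectionWithinFold = FALSE,
                                verbose = FALSE) {
  model <- match.arg(model)
  if (selectionWithinFold)
    message("note: leakage-free within-fold selection requested; ",
            "subsets are re-selected per training fold")
  if (is(y, "TraitBLUEs")) {
    if (is.null(h2)) h2 <- heritability(y)
    yv <- blues(y)
  } else yv <- y
  if (is.null(effects) && !selectionWithinFold) {
    selModel <- if (is.null(selectionModel)) model else selectionModel
    effects <- if (selModel == "bayes_b")
      fitBayesb(yv, X, priors, seed = .subSeed(seed, "fullfit"))
    else {
      lam <- if (is.null(lambda)) ncol(X) else lambda
      fitRrblup(yv, X, lam)
    }
  }
  rows <- list()
  for (fr in fractions) for (md in modes) {
    if (selectionWithinFold) {
      cv <- .cvWithinFoldSelection(yv, X, families, model, fr, md, nRuns,
                                   nFolds, seed, lambda, priors, h2)
    } else {
      ids <- subsetPredictors(effects, fr, md,
                              seed = .subSeed(seed, paste0("sub", fr, md)))
      if (verbose)
        message(sprintf("reduction: %s %.0f%% -> %d predictors",
                        md, 100 * fr, length(ids)))
      cv <- runCrossValidation(yv, X[, ids, drop = FALSE], families, model,
                               nRuns = nRuns, nFolds = nFolds, seed = seed,
                               lambda = lambda, priors = priors, h2 = h2,
                               predictorSet = sprintf("%s_%g", md, fr))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = fr, mode = md,
      size = round(fr * ncol(X)), rAb = cv@rAb, rAc = cv@rAc, sd = cv@sd)
  }
  do.call(rbind, rows)
}

# leakage-free variant: select inside each training fold
.cvWithinFoldSelection <- function(y, X, families, model, fraction, mode,
                                   nRuns, nFolds, seed, lambda, priors, h2) {
  nReps <- nRuns %/% nFolds
  ab <- numeric(0)
  for (rep in seq_len(nReps)) {
    fold <- stratifiedPartition(families, nFolds,
                                seed = .subSeed(seed, sprintf("rep%d", rep)))
    for (k in seq_len(nFolds)) {
      test <- fold == k
      lamSel <- if (is.null(lambda)) ncol(X) else lambda
      eff <- if (model == "bayes_b")
        fitBayesb(y[!test], X[!test, , drop = FALSE], priors,
                  seed = .subSeed(seed, sprintf("sel%d_%d", rep, k)))
      else fitRrblup(y[!test], X[!test, , drop = FALSE], lamSel)
      ids <- subsetPredictors(eff, fraction, mode,
                              seed = .subSeed(seed, sprintf("ss%d_%d", rep, k)))
      pred <- .cvFit(y[!test], X[!test, ids, drop = FALSE],
                     X[test, ids, drop = FALSE], model, lambda, priors,
                     seed = .subSeed(seed, sprintf("fit%d_%d", rep, k)))
      r <- if (stats::sd(pred) == 0) 0 else stats::cor(y[test], pred)
      ab <- c(ab, r)
    }
  }
  rAb <- mean(ab)
  acc <- if (!is.null(h2) && is.finite(h2)) ab / sqrt(h2) else ab
  new("CVResult", abilities = ab, rAb = rAb,
      rAc = if (!is.null(h2) && is.finite(h2)) rAb / sqrt(h2) else NA_real_,
      sd = stats::sd(acc),
      h2 = if (is.null(h2)) NA_real_ else as.numeric(h2),
      model = model, predictorSet = sprintf("withinfold_%s_%g", mode, fraction),
      trait = "trait", nFolds = as.integer(nFolds),
      nRuns = as.integer(nRuns), seed = as.integer(seed))
}
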