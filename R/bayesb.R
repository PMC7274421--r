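# R front end for the BayesB Gibbs sampler (C++ backend).

#' Construct BayesB prior settings
#'
#' Defaults: slab degrees of freedom 5 with a data-derived scale chosen so
#' the prior slab explains half the phenotypic variance given the mean
#' predictor variance; Beta(1, 9) prior on the exclusion probability pi;
#' chain of 12,000 sweeps, 2,000 burn-in, thinning 5. All settings are
#' configurable and echoed into run manifests.
#'
#' @param piShape beta shape pair for the prior on pi (exclusion
#'   probability).
#' @param df0,scale0 slab prior; \code{scale0 = NA} derives the scale from
#'   the data at fit time.
#' @param dfE,scaleE residual-variance prior; \code{scaleE = NA} likewise.
#' @param nIter,burnIn,thin chain controls.
#' @param fixPi fix pi instead of sampling it (NA = sample).
#' @return A \linkS4class{BayesBPriors}.
#' @export
bayesbPriors <- function(piShape = c(1, 9), df0 = 5, scale0 = NA_real_,
                         dfE = 5, scaleE = NA_real_, nIter = 12000L,
                         burnIn = 2000L, thin = 5L, fixPi = NA_real_) {
  new("BayesBPriors", piShape = as.numeric(piShape), df0 = as.numeric(df0),
      scale0 = as.numeric(scale0), dfE = as.numeric(dfE),
      scaleE = as.numeric(scaleE), nIter = as.integer(nIter),
      burnIn = as.integer(burnIn), thin = as.integer(thin),
      fixPi = as.numeric(fixPi))
}

#' Fit BayesB marker effects by Gibbs sampling
#'
#' Spike-and-slab whole-genome regression: each effect is zero with
#' probability pi or drawn from a normal slab whose variance carries its
#' own scaled inverse chi-squared prior. Per sweep the sampler updates the
#' intercept (flat prior), every effect through its inclusion indicator and
#' conditional normal, each slab variance, pi (beta conditional) and the
#' residual variance (scaled inverse chi-squared conditional). Posterior
#' means over retained sweeps are returned.
#'
#' Dosage matrices coded 0/1/2 are internally recoded to -1/0/1; other
#' predictor matrices are column-centred. Either way the reported intercept
#' is mapped back to the coding of \code{X}, so \code{\link{predictValues}}
#' applies directly to matrices in the original coding.
#'
#' @param y named numeric response or \linkS4class{TraitBLUEs}.
#' @param X predictor matrix, rows aligned to \code{y}.
#' @param priors a \linkS4class{BayesBPriors}.
#' @param seed integer seed (chains with equal seeds are identical).
#' @return A \linkS4class{MarkerEffects} with model = "bayes_b",
#'   per-predictor posterior inclusion probabilities, the posterior mean of
#'   pi and of the residual variance.
#' @export
fitBayesb <- function(y, X, priors = bayesbPriors(), seed = 1L) {
  stopifnot(is(priors, "BayesBPriors"))
  if (is(y, "TraitBLUEs")) y <- blues(y)
  y <- drop(y)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (length(y) != nrow(X))
    stop("rows of X do not match length of y")
  if (is.null(colnames(X))) colnames(X) <- sprintf("P%d", seq_len(ncol(X)))
  isDosage <- all(X %in% c(0, 1, 2))
  if (isDosage) {
    Xb <- X - 1
    coding <- "dosage-1"
    centers <- rep(1, ncol(X))
  } else {
    centers <- colMeans(X)
    Xb <- sweep(X, 2, centers)
    coding <- "centered"
  }
  pi0 <- if (is.finite(priors@fixPi)) priors@fixPi else
    priors@piShape[1] / sum(priors@piShape)
  vy <- stats::var(y)
  sumVar <- sum(.colVars(Xb))
  S0 <- priors@scale0
  if (is.na(S0)) {
    # prior slab explains half the phenotypic variance:
    # (1 - pi0) * sumVar * df0 * S0 / (df0 - 2) = 0.5 * var(y)
    incl <- max(1 - pi0, 1e-3)
    S0 <- 0.5 * vy * max(priors@df0 - 2, 0.5) /
      (priors@df0 * incl * max(sumVar, 1e-12))
  }
  SE <- priors@scaleE
  if (is.na(SE)) SE <- 0.5 * vy * max(priors@dfE - 2, 0.5) / priors@dfE
  res <- .withSeed(if (is.null(seed)) NULL else .subSeed(seed, "bayesb"),
                   .bayesbGibbs(as.numeric(y), Xb, priors@df0, S0,
                                priors@piShape[1], priors@piShape[2],
                                priors@dfE, SE, priors@nIter,
                                priors@burnIn, priors@thin, priors@fixPi))
  g <- stats::setNames(res$g, colnames(X))
  mu <- res$mu - sum(centers * g)  # back to the coding of X
  new("MarkerEffects", mu = mu, effects = g, model = "bayes_b",
      coding = coding,
      inclusionProb = stats::setNames(res$inclusionProb, colnames(X)),
      pi = res$pi, sigma2e = res$sigma2e)
}
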