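# Quality control, imputation and transformation of the predictor layers.

#' SNP quality filters
#'
#' Retains markers that are (i) polymorphic in at least one family, (ii)
#' have a missing-call fraction strictly below \code{maxFailure}, and (iii)
#' a heterozygote fraction (among observed calls) strictly below
#' \code{maxHet}. The operation is idempotent and preserves column order.
#'
#' @param g a \linkS4class{GenotypeMatrix} with raw 0/1/2/NA calls.
#' @param maxFailure maximum tolerated missing fraction (strict "<").
#' @param maxHet maximum tolerated heterozygote fraction (strict "<").
#' @param verbose log retained/removed counts.
#' @return The filtered \linkS4class{GenotypeMatrix}.
#' @export
qcFilterSnps <- function(g, maxFailure = 0.10, maxHet = 0.125,
                         verbose = FALSE) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (maxFailure < 0 || maxFailure > 1 || maxHet < 0 || maxHet > 1)
    stop("thresholds must lie in [0, 1]")
  d <- dosage(g)
  nObs <- colSums(!is.na(d))
  missFrac <- colMeans(is.na(d))
  hetFrac <- ifelse(nObs > 0, colSums(d == 1, na.rm = TRUE) / nObs, 1)
  polyAny <- rep(FALSE, ncol(d))
  for (f in unique(g@family)) {
    sub <- d[g@family == f, , drop = FALSE]
    rng <- apply(sub, 2, function(col) {
      v <- col[!is.na(col)]
      length(unique(v)) > 1
    })
    polyAny <- polyAny | rng
  }
  keep <- polyAny & (missFrac < maxFailure) & (hetFrac < maxHet)
  if (verbose)
    message(sprintf("qcFilterSnps: retained %d of %d markers",
                    sum(keep), ncol(d)))
  mapKeep <- if (nrow(g@map) > 0)
    g@map[g@map$id %in% colnames(d)[keep], , drop = FALSE] else g@map
  GenotypeMatrix(d[, keep, drop = FALSE], g@family, map = mapKeep)
}

#' Mean imputation of missing genotype calls
#'
#' Replaces every missing call by the mean observed dosage of that marker
#' (continuous, not rounded: downstream ridge/Bayesian regressions accept
#' real-valued dosages). Observed cells are untouched; column means are
#' preserved.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @return The imputed \linkS4class{GenotypeMatrix} with no missing cells.
#' @export
imputeMNI <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- dosage(g)
  nObs <- colSums(!is.na(d))
  if (any(nObs == 0))
    stop("marker(s) with no observed calls: ",
         paste(colnames(d)[nObs == 0], collapse = ", "))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx) > 0) d[idx] <- mu[idx[, 2]]
  GenotypeMatrix(d, g@family, map = g@map)
}

#' Recode family-monomorphic markers to the recurrent-parent state
#'
#' The donor allele is defined per family relative to the recurrent parent.
#' At markers where a family shows no segregation (all observed calls
#' identical), that family's lines are indistinguishable from the recurrent
#' parent and are coded 0, even if the raw array call differed.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @return The recoded \linkS4class{GenotypeMatrix}.
#' @export
monomorphicFamilyRecode <- function(g) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- dosage(g)
  for (f in unique(g@family)) {
    rows <- which(g@family == f)
    sub <- d[rows, , drop = FALSE]
    mono <- apply(sub, 2, function(col) {
      v <- col[!is.na(col)]
      length(v) > 0 && length(unique(v)) == 1
    })
    if (any(mono)) d[rows, mono] <- 0
  }
  GenotypeMatrix(d, g@family, map = g@map)
}

#' Filter metabolites by missingness
#'
#' Removes metabolites whose missing fraction strictly exceeds
#' \code{maxMissing} (a feature with exactly the threshold fraction is
#' retained). Idempotent; preserves column order.
#'
#' @param m a \linkS4class{MetaboliteMatrix}.
#' @param maxMissing maximum tolerated missing fraction (default 0.10).
#' @param verbose log retained/removed counts.
#' @return The filtered \linkS4class{MetaboliteMatrix}.
#' @export
filterMetabolites <- function(m, maxMissing = 0.10, verbose = FALSE) {
  stopifnot(is(m, "MetaboliteMatrix"))
  if (maxMissing < 0 || maxMissing >= 1)
    stop("'maxMissing' must lie in [0, 1)")
  x <- intensities(m)
  missFrac <- colMeans(is.na(x))
  keep <- missFrac <= maxMissing
  if (verbose)
    message(sprintf("filterMetabolites: retained %d of %d metabolites",
                    sum(keep), ncol(x)))
  MetaboliteMatrix(x[, keep, drop = FALSE], samplingDate = m@samplingDate)
}

#' Minimum imputation of missing metabolite values
#'
#' Replaces missing intensities by the per-metabolite observed minimum
#' (below-detection-limit convention).
#'
#' @param m a \linkS4class{MetaboliteMatrix}.
#' @return The imputed \linkS4class{MetaboliteMatrix}.
#' @export
imputeMetaboliteMin <- function(m) {
  stopifnot(is(m, "MetaboliteMatrix"))
  x <- intensities(m)
  nObs <- colSums(!is.na(x))
  if (any(nObs == 0))
    stop("metabolite(s) with no observed values: ",
         paste(colnames(x)[nObs == 0], collapse = ", "))
  mins <- apply(x, 2, min, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx) > 0) x[idx] <- mins[idx[, 2]]
  MetaboliteMatrix(x, samplingDate = m@samplingDate)
}

#' Box-Cox power transformation over a lambda grid
#'
#' Chooses lambda from the grid maximising the Box-Cox profile
#' log-likelihood under normality and applies the transform
#' (x^lambda - 1)/lambda (log x at lambda = 0). Inputs that are not
#' strictly positive are first shifted by (1 - min(x)).
#'
#' @param x numeric vector.
#' @param lambdaGrid candidate lambdas (default -3 to 3 by 0.25).
#' @return list with \code{transformed}, \code{lambda}, \code{shift} and
#'   the per-lambda \code{logLik} profile.
#' @export
boxcoxTransform <- function(x, lambdaGrid = seq(-3, 3, by = 0.25)) {
  if (any(!is.finite(x))) stop("input must be finite")
  if (length(x) < 3) stop("need at least 3 values")
  shift <- 0
  if (min(x) <= 0) {
    shift <- 1 - min(x)
    x <- x + shift
  }
  n <- length(x)
  slx <- sum(log(x))
  ll <- vapply(lambdaGrid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(x) else (x^lam - 1) / lam
    s2 <- stats::var(z) * (n - 1) / n
    if (s2 <= 0) return(-Inf)
    -n / 2 * log(s2) + (lam - 1) * slx
  }, numeric(1))
  best <- lambdaGrid[which.max(ll)]
  z <- if (abs(best) < 1e-12) log(x) else (x^best - 1) / best
  list(transformed = z, lambda = best, shift = shift,
       logLik = stats::setNames(ll, lambdaGrid))
}
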