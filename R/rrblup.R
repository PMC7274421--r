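# Ridge-regression BLUP via Henderson's mixed-model equations.

#' Plug-in ridge penalty for RR-BLUP
#'
#' lambda = (sigma2_R / l) / (sigma2_G / m): the residual variance per trial
#' year over the genetic variance per marker, both taken from the
#' phenotypic mixed model.
#'
#' @param sigma2G,sigma2R genotypic and residual variance components.
#' @param m number of predictors.
#' @param l number of trial years.
#' @return The penalty lambda.
#' @examples
#' rrblupLambda(2, 4, 100, 8)  # 25
#' @export
rrblupLambda <- function(sigma2G, sigma2R, m, l) {
  if (sigma2G <= 0) stop("lambda undefined: sigma2_G must be positive")
  if (sigma2R <= 0 || m <= 0 || l <= 0)
    stop("all inputs must be positive")
  (sigma2R / l) / (sigma2G / m)
}

#' Fit RR-BLUP marker effects
#'
#' Solves the mixed-model equations for y = 1 mu + X g + e with a fixed
#' intercept and equally shrunken effects (g penalised by \code{lambda}).
#' Absorbing the intercept gives (Xc' Xc + lambda I) g = Xc' yc on
#' column-centred data; when predictors outnumber observations the
#' equivalent kernel form g = Xc' (Xc Xc' + lambda I)^-1 yc is used. Both
#' routes yield the identical unique solution for lambda > 0, and
#' predictions are invariant to a constant shift of the dosage coding (the
#' intercept absorbs it).
#'
#' @param y named numeric response (or a \linkS4class{TraitBLUEs}).
#' @param X predictor matrix, rows aligned to \code{y}.
#' @param lambda ridge penalty (> 0), e.g. from \code{\link{rrblupLambda}}.
#' @param method "auto" picks the cheaper of the marker-effect ("mme") and
#'   kernel ("kernel") routes; both are exposed for cross-checking.
#' @return A \linkS4class{MarkerEffects} with model = "rr_blup"; mu is on
#'   the coding of \code{X}, so \code{mu + X g} are the fitted values.
#' @export
fitRrblup <- function(y, X, lambda, method = c("auto", "mme", "kernel")) {
  method <- match.arg(method)
  if (is(y, "TraitBLUEs")) y <- blues(y)
  y <- drop(y)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (length(y) != nrow(X))
    stop("rows of X (", nrow(X), ") do not match length of y (",
         length(y), ")")
  if (!is.numeric(lambda) || lambda <= 0) stop("'lambda' must be > 0")
  if (is.null(colnames(X))) colnames(X) <- sprintf("P%d", seq_len(ncol(X)))
  n <- nrow(X); m <- ncol(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  if (method == "auto") method <- if (m <= n) "mme" else "kernel"
  g <- if (method == "mme") {
    A <- crossprod(Xc)
    diag(A) <- diag(A) + lambda
    drop(solve(A, crossprod(Xc, yc)))
  } else {
    K <- tcrossprod(Xc)
    diag(K) <- diag(K) + lambda
    drop(crossprod(Xc, solve(K, yc)))
  }
  names(g) <- colnames(X)
  mu <- ybar - sum(xbar * g)
  new("MarkerEffects", mu = mu, effects = g, model = "rr_blup",
      coding = "as-supplied", inclusionProb = numeric(),
      pi = NA_real_, sigma2e = NA_real_)
}

#' Predict genomic (or metabolic) estimated breeding values
#'
#' Returns mu + X_new g. Columns of \code{X_new} must cover the fitted
#' predictor ids in the same coding the model was fitted on.
#'
#' @param e a \linkS4class{MarkerEffects}.
#' @param Xnew predictor matrix for new lines.
#' @return Named numeric vector of predicted values.
#' @export
predictValues <- function(e, Xnew) {
  stopifnot(is(e, "MarkerEffects"))
  if (!is.matrix(Xnew)) Xnew <- as.matrix(Xnew)
  ids <- names(e@effects)
  if (is.null(colnames(Xnew)))
    if (ncol(Xnew) == length(ids)) colnames(Xnew) <- ids else
      stop("unnamed predictor columns of wrong dimension")
  missing <- setdiff(ids, colnames(Xnew))
  if (length(missing))
    stop("predictor(s) absent from new data: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  drop(e@mu + Xnew[, ids, drop = FALSE] %*% e@effects)
}

#' Combine SNP and metabolite predictor blocks
#'
#' Column-concatenates the two blocks over a shared, identically ordered
#' line set. Metabolite columns are standardised (zero mean, unit variance)
#' so heterogeneous intensity scales do not dominate the common-variance
#' effect prior; SNP dosages are left untouched. Predictor ids are
#' provenance-tagged.
#'
#' @param Xsnp SNP dosage matrix (lines x markers) or
#'   \linkS4class{GenotypeMatrix}.
#' @param Xmet metabolite matrix (lines x metabolites) or
#'   \linkS4class{MetaboliteMatrix}; may have zero columns.
#' @param standardizeMet standardise the metabolite block (default TRUE).
#' @return Combined predictor matrix with ids \code{SNP:*} and \code{MET:*}.
#' @export
combinePredictors <- function(Xsnp, Xmet, standardizeMet = TRUE) {
  if (is(Xsnp, "GenotypeMatrix")) Xsnp <- dosage(Xsnp)
  if (is(Xmet, "MetaboliteMatrix")) Xmet <- intensities(Xmet)
  if (ncol(Xmet) == 0) {
    out <- Xsnp
    colnames(out) <- paste0("SNP:", colnames(Xsnp))
    return(out)
  }
  if (!identical(rownames(Xsnp), rownames(Xmet)))
    stop("line sets (or their order) differ between the two blocks")
  if (anyNA(Xmet)) stop("impute metabolites before combining")
  M <- if (standardizeMet) {
    sds <- apply(Xmet, 2, stats::sd)
    if (any(sds == 0)) stop("constant metabolite column(s)")
    scale(Xmet)
  } else Xmet
  out <- cbind(Xsnp, M)
  colnames(out) <- c(paste0("SNP:", colnames(Xsnp)),
                     paste0("MET:", colnames(Xmet)))
  out
}
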