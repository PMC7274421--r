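# Phenotypic mixed models: variance components, heritabilities, BLUEs, and
# the multi-kernel genomic-heritability model.

#' REML variance components of a multi-year trial
#'
#' Fits value = mean + genotype + year + genotype:year + error with all
#' effects random (REML via \pkg{lme4}) and returns the genotype (V_G),
#' genotype-by-year (V_GY) and residual (V_R) components together with the
#' design constants y (years) and r (replicates) used in heritability
#' ratios. Negative estimates are truncated at zero by the fitter.
#'
#' Balanced complete designs (every line in every year with a constant
#' replicate count and interior estimates) use the exact closed-form REML
#' solution, which coincides with the ANOVA expected-mean-square
#' estimators; any other design falls back to the iterative \pkg{lme4}
#' fit.
#'
#' @param p plot phenotype table (see \code{\link{plotPhenotypeTable}}).
#' @param trait trait name to subset on (default: the only trait present).
#' @return A \linkS4class{VarianceComponents} with model = "phenotypic".
#' @export
estimateVarianceComponents <- function(p, trait = NULL) {
  p <- plotPhenotypeTable(p)
  if (!is.null(trait)) p <- p[p$trait == trait, , drop = FALSE]
  if (nrow(p) == 0) stop("no records for the requested trait")
  if (length(unique(p$year)) < 2)
    stop("V_GY inestimable: need at least 2 years")
  if (length(unique(p$line_id)) < 2)
    stop("V_G inestimable: need at least 2 lines")
  cellCount <- table(p$line_id, p$year)
  if (max(cellCount) < 2)
    stop("V_R inestimable: V_GY and V_R are not separable without ",
         "replicated (line, year) cells")
  nYears <- length(unique(p$year))
  nReps <- max(cellCount)
  comps <- NULL
  if (all(cellCount == nReps)) {
    # balanced complete design: exact closed-form (ANOVA/EMS) solution
    nl <- nrow(cellCount)
    cellMean <- tapply(p$value, list(p$line_id, p$year), mean)
    lineMean <- rowMeans(cellMean)
    yearMean <- colMeans(cellMean)
    grand <- mean(cellMean)
    msG <- nYears * nReps * sum((lineMean - grand)^2) / (nl - 1)
    inter <- sweep(sweep(cellMean, 1, lineMean), 2, yearMean) + grand
    msGY <- nReps * sum(inter^2) / ((nl - 1) * (nYears - 1))
    mse <- if (nReps > 1) {
      cellOf <- cellMean[cbind(as.character(p$line_id),
                               as.character(p$year))]
      sum((p$value - cellOf)^2) / (nl * nYears * (nReps - 1))
    } else 0
    cand <- c(V_G = (msG - msGY) / (nYears * nReps),
              V_GY = (msGY - mse) / nReps, V_R = mse)
    if (all(cand >= 0)) comps <- cand  # interior: equals REML exactly
  }
  if (is.null(comps)) {
    d <- data.frame(value = p$value, line = factor(p$line_id),
                    year = factor(p$year))
    fit <- lme4::lmer(value ~ 1 + (1 | line) + (1 | year) + (1 | line:year),
                      data = d, REML = TRUE,
                      control = lme4::lmerControl(
                        calc.derivs = FALSE,
                        optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    getv <- function(grp) {
      v <- vc$vcov[vc$grp == grp]
      if (length(v) == 0) 0 else v
    }
    comps <- c(V_G = getv("line"), V_GY = getv("line:year"),
               V_R = getv("Residual"))
  }
  new("VarianceComponents", components = pmax(comps, 0),
      nYears = as.numeric(nYears), nReps = as.numeric(nReps),
      model = "phenotypic")
}

#' Broad-sense heritability on an entry-mean basis
#'
#' h2 = V_G / (V_G + V_GY / y + V_R / (y r)).
#'
#' @param v a \linkS4class{VarianceComponents} (phenotypic model), or a
#'   named numeric vector with V_G, V_GY, V_R.
#' @param nYears,nReps override the design constants stored in \code{v}.
#' @return Heritability in [0, 1].
#' @examples
#' broadSenseHeritability(c(V_G = 2, V_GY = 1, V_R = 4), nYears = 5, nReps = 2)
#' @export
broadSenseHeritability <- function(v, nYears = NULL, nReps = NULL) {
  if (is(v, "VarianceComponents")) {
    if (is.null(nYears)) nYears <- v@nYears
    if (is.null(nReps)) nReps <- v@nReps
    v <- v@components
  }
  if (is.null(nYears) || is.null(nReps) || nYears < 1 || nReps < 1)
    stop("need nYears >= 1 and nReps >= 1")
  den <- v[["V_G"]] + v[["V_GY"]] / nYears + v[["V_R"]] / (nYears * nReps)
  if (den <= 0) stop("heritability undefined: all components are zero")
  unname(v[["V_G"]] / den)
}

#' Repeatability from repeated measurements
#'
#' rep = V_G / (V_G + V_R / r).
#'
#' @param vG,vR genotypic and residual variance components.
#' @param r number of repeated measurements.
#' @return Repeatability in [0, 1].
#' @export
repeatability <- function(vG, vR, r) {
  if (r < 1) stop("'r' must be >= 1")
  den <- vG + vR / r
  if (den <= 0) stop("repeatability undefined: zero denominator")
  vG / den
}

#' Per-genotype BLUEs across years
#'
#' Solves the fixed-effects model value = genotype + year + error by sparse
#' least squares and reports, per line, the estimated mean over the trial
#' years (genotype effect plus the average year effect). With a single year
#' and balanced data this reduces to per-line means; year effects absorb
#' additive year shifts so BLUE differences between lines are invariant to
#' them.
#'
#' @param p plot phenotype table.
#' @param trait trait name to subset on.
#' @param h2 optional heritability to attach to the result.
#' @return A \linkS4class{TraitBLUEs}.
#' @export
computeBlues <- function(p, trait = NULL, h2 = NA_real_) {
  p <- plotPhenotypeTable(p)
  if (!is.null(trait)) p <- p[p$trait == trait, , drop = FALSE]
  if (nrow(p) == 0) stop("no records for the requested trait")
  traitName <- if (!is.null(trait)) trait else unique(p$trait)[1]
  d <- data.frame(value = p$value, line = factor(p$line_id),
                  year = factor(p$year))
  allLines <- levels(d$line)
  hasYear <- nlevels(d$year) > 1
  Xs <- if (hasYear)
    Matrix::sparse.model.matrix(~ 0 + line + year, data = d)
  else
    Matrix::sparse.model.matrix(~ 0 + line, data = d)
  XtX <- Matrix::crossprod(Xs)
  beta <- tryCatch(
    as.numeric(Matrix::solve(XtX, Matrix::crossprod(Xs, d$value))),
    error = function(e) stop("BLUE system singular (disconnected design): ",
                             conditionMessage(e)))
  names(beta) <- colnames(Xs)
  lineCoef <- beta[paste0("line", allLines)]
  yearMean <- if (hasYear) {
    yc <- beta[grep("^year", names(beta))]
    mean(c(0, yc))  # baseline year is the reference level
  } else 0
  vals <- stats::setNames(unname(lineCoef) + yearMean, allLines)
  if (anyNA(vals))
    stop("no records for line(s): ",
         paste(allLines[is.na(vals)], collapse = ", "))
  new("TraitBLUEs", values = vals, trait = as.character(traitName),
      h2 = as.numeric(h2))
}

#' Build additive, dominance and epistasis genomic kernels
#'
#' Additive kernel from column-centred dosages X_c as X_c X_c'; dominance
#' kernel from centred heterozygosity indicators; additive-by-additive
#' epistasis kernel as the element-wise square of the additive kernel. Each
#' kernel is scaled to mean diagonal 1 so variance components are on the
#' phenotypic scale.
#'
#' @param g a \linkS4class{GenotypeMatrix} or a dosage matrix.
#' @return Named list of kernels \code{A}, \code{D}, \code{I} (n x n).
#' @export
makeGenomicKernels <- function(g) {
  X <- if (is(g, "GenotypeMatrix")) dosage(g) else g
  if (anyNA(X)) stop("impute missing dosages before building kernels")
  norm1 <- function(K) {
    md <- mean(diag(K))
    if (md <= 0) stop("degenerate kernel (no variation)")
    K / md
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  A <- norm1(tcrossprod(Xc))
  # heterozygosity score: 1 at dosage 1, 0 at the homozygotes, linear between
  W <- 1 - abs(X - 1)
  W[W < 0] <- 0
  Wc <- scale(W, center = TRUE, scale = FALSE)
  D <- tcrossprod(Wc)
  D <- if (mean(diag(D)) > 1e-10) norm1(D) else NULL
  I <- norm1(A * A)
  out <- list(A = A, D = D, I = I)
  out[!vapply(out, is.null, logical(1))]
}

# Generic multi-kernel REML: V = sigma2 * (sum_k theta_k K_k + I_n), total
# variance profiled out, theta optimised on the log scale by Nelder-Mead
# from several starts. Returns per-kernel components and the residual.
.remlKernels <- function(y, kernels, tol = 1e-8, maxit = 500,
                         starts = c(0.5, 0.05, 2)) {
  n <- length(y)
  nk <- length(kernels)
  X <- matrix(1, n, 1)
  evalObj <- function(logTheta) {
    theta <- exp(logTheta)
    H <- diag(n)
    for (k in seq_len(nk)) H <- H + theta[k] * kernels[[k]]
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) return(list(obj = 1e10))
    HiY <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
    HiX <- backsolve(ch, backsolve(ch, X, transpose = TRUE))
    XtHiX <- crossprod(X, HiX)
    XtHiY <- crossprod(X, HiY)
    yPy <- drop(sum(y * HiY) - t(XtHiY) %*% solve(XtHiX, XtHiY))
    if (yPy <= 0) return(list(obj = 1e10))
    obj <- 0.5 * (2 * sum(log(diag(ch))) +
                    as.numeric(determinant(XtHiX)$modulus) +
                    (n - 1) * log(yPy / (n - 1)))
    list(obj = obj, sigma2 = yPy / (n - 1))
  }
  best <- NULL
  for (s0 in starts) {
    fit <- stats::optim(rep(log(s0), nk),
                        function(lt) evalObj(lt)$obj,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = tol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$value >= 1e10 - 1)
    stop("kernel system singular; consider dropping the epistasis kernel")
  fin <- evalObj(best$par)
  theta <- exp(best$par)
  theta[theta < 1e-8] <- 0
  sigma2 <- fin$sigma2
  list(components = stats::setNames(theta * sigma2, names(kernels)),
       residual = sigma2, logLik = -best$value)
}

#' Genomic (SNP-based) heritability of a quantitative feature
#'
#' Fits a three-kernel random-effect model (additive, dominance,
#' additive-by-additive epistasis) by REML and returns
#' h2_SNP = (s2_A + s2_D + s2_I) / (s2_A + s2_D + s2_I + s2_R), which lies
#' in [0, 1] by construction.
#'
#' @param y named numeric feature values (e.g. a metabolite); names must be
#'   a subset of the genotype line ids.
#' @param g a \linkS4class{GenotypeMatrix}, or NULL when \code{kernels} is
#'   given.
#' @param kernels optional precomputed kernel list (from
#'   \code{\link{makeGenomicKernels}}); pass this when scoring many
#'   features on the same genotypes.
#' @param starts variance-ratio starting values for the REML restarts; a
#'   single value speeds up large batch runs.
#' @return list with \code{components} (a \linkS4class{VarianceComponents},
#'   genomic model) and \code{h2Snp}.
#' @export
genomicHeritability <- function(y, g = NULL, kernels = NULL,
                                starts = c(0.5, 0.05, 2)) {
  if (is.null(kernels)) {
    stopifnot(is(g, "GenotypeMatrix"))
    if (!all(names(y) %in% lineIds(g)))
      stop("feature lines must be a subset of the genotype lines")
    kernels <- makeGenomicKernels(
      dosage(g)[names(y), , drop = FALSE])
  } else if (!is.null(names(y)) && !is.null(rownames(kernels[[1]]))) {
    kernels <- lapply(kernels, function(K) K[names(y), names(y)])
  }
  y <- as.numeric(scale(y))  # unit scale for optimizer conditioning
  fit <- .remlKernels(y, kernels, starts = starts)
  comps <- fit$components
  full <- c(sigma2_A = unname(comps["A"]),
            sigma2_D = unname(if ("D" %in% names(comps)) comps["D"] else 0),
            sigma2_I = unname(comps["I"]),
            sigma2_R = fit$residual)
  full[is.na(full)] <- 0
  gen <- sum(full[c("sigma2_A", "sigma2_D", "sigma2_I")])
  h2 <- gen / (gen + full[["sigma2_R"]])
  list(components = new("VarianceComponents", components = full,
                        nYears = 1, nReps = 1, model = "genomic"),
       h2Snp = h2)
}
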