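#' @import methods
NULL

#' Genetic map of markers on linkage groups
#'
#' Positions are genetic (centiMorgan) positions on named chromosomes.
#'
#' @slot chromosomes data.frame with columns \code{id} (character) and
#'   \code{length} (cM, positive).
#' @slot markers data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} (cM); ordered, non-decreasing within chromosome.
#' @exportClass GeneticMap
setClass("GeneticMap",
  slots = c(chromosomes = "data.frame", markers = "data.frame"))

setValidity("GeneticMap", function(object) {
  ch <- object@chromosomes
  mk <- object@markers
  if (!all(c("id", "length") %in% names(ch)))
    return("chromosomes needs columns 'id' and 'length'")
  if (!all(c("id", "chrom", "pos") %in% names(mk)))
    return("markers needs columns 'id', 'chrom' and 'pos'")
  if (any(ch$length <= 0)) return("chromosome lengths must be positive")
  if (anyDuplicated(mk$id)) return("duplicate marker ids")
  if (!all(mk$chrom %in% ch$id))
    return("every marker must lie on a declared chromosome")
  if (any(mk$pos < 0)) return("marker positions must be non-negative")
  for (c_id in unique(mk$chrom)) {
    p <- mk$pos[mk$chrom == c_id]
    if (is.unsorted(p)) return(sprintf(
      "marker positions not non-decreasing on chromosome %s", c_id))
    len <- ch$length[ch$id == c_id]
    if (any(p > len)) return(sprintf(
      "marker beyond the end of chromosome %s", c_id))
  }
  TRUE
})

#' Dosage matrix of a multi-family population
#'
#' Lines x markers dosages counting copies of the donor (non-recurrent)
#' allele: 0 = homozygous recurrent parent, 1 = heterozygous, 2 = homozygous
#' donor. Missing calls are NA; after mean imputation cells may be fractional.
#'
#' @slot dosage numeric matrix, rows = lines (rownames = line ids),
#'   columns = markers (colnames = marker ids).
#' @slot family character vector of family labels, one per line.
#' @slot map data.frame with marker metadata (\code{id}, \code{chrom},
#'   \code{pos}); may have zero rows when no map is attached.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  slots = c(dosage = "matrix", family = "character", map = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("dosage matrix needs line ids as rownames and marker ids as colnames")
  if (anyDuplicated(rownames(d))) return("duplicate line ids")
  if (anyDuplicated(colnames(d))) return("duplicate marker ids")
  if (length(object@family) != nrow(d))
    return("one family label per line required")
  if (anyNA(object@family)) return("family label missing for some line")
  ok <- is.na(d) | (is.finite(d) & d >= 0 & d <= 2)
  if (!all(ok)) return("dosages must lie in [0, 2] or be NA")
  if (nrow(object@map) > 0 &&
      !all(colnames(d) %in% object@map$id))
    return("map does not cover all markers")
  TRUE
})

#' Metabolite intensity matrix
#'
#' @slot intensities numeric matrix, rows = lines, columns = metabolites;
#'   non-negative where observed, NA where missing.
#' @slot samplingDate free-text tag for the sampling campaign.
#' @exportClass MetaboliteMatrix
setClass("MetaboliteMatrix",
  slots = c(intensities = "matrix", samplingDate = "character"))

setValidity("MetaboliteMatrix", function(object) {
  m <- object@intensities
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("intensity matrix needs line ids as rownames and metabolite ids as colnames")
  if (anyDuplicated(rownames(m))) return("duplicate line ids")
  if (anyDuplicated(colnames(m))) return("duplicate metabolite ids")
  if (any(!is.na(m) & !is.finite(m)))
    return("intensities must be finite where present")
  TRUE
})

#' Ground truth of a simulated population
#'
#' Records everything the generator knows so parameter-recovery tests can
#' compare estimates against generating values.
#'
#' @slot qtlIndices integer marker indices of the trait QTL.
#' @slot qtlEffects additive allele-substitution effects, one per QTL.
#' @slot targetH2 broad-sense heritability aimed for, in (0, 1].
#' @slot gxyRatio ratio V_GY / V_G used by the generator.
#' @slot varG,varGY,varR generating variance components on the plot scale.
#' @slot genotypicValues named numeric, true genotypic value per line.
#' @slot metaboliteH2 named numeric, generating genomic heritability per
#'   simulated metabolite (empty until metabolites are simulated).
#' @slot metaboliteQtl list of integer QTL index vectors per metabolite.
#' @exportClass SimTruth
setClass("SimTruth",
  slots = c(qtlIndices = "integer", qtlEffects = "numeric",
            targetH2 = "numeric", gxyRatio = "numeric",
            varG = "numeric", varGY = "numeric", varR = "numeric",
            genotypicValues = "numeric",
            metaboliteH2 = "numeric", metaboliteQtl = "list"))

setValidity("SimTruth", function(object) {
  if (length(object@targetH2) == 1 &&
      (object@targetH2 <= 0 || object@targetH2 > 1))
    return("targetH2 must lie in (0, 1]")
  if (length(object@qtlEffects) != length(object@qtlIndices))
    return("one effect per QTL index required")
  TRUE
})

#' Variance components of a phenotypic or genomic random-effect model
#'
#' @slot components named non-negative numeric; phenotypic model uses
#'   \code{V_G}, \code{V_GY}, \code{V_R}; genomic model uses \code{sigma2_A},
#'   \code{sigma2_D}, \code{sigma2_I}, \code{sigma2_R}.
#' @slot nYears,nReps design constants used in heritability ratios.
#' @slot model "phenotypic" or "genomic".
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  slots = c(components = "numeric", nYears = "numeric", nReps = "numeric",
            model = "character"))

setValidity("VarianceComponents", function(object) {
  if (is.null(names(object@components)))
    return("components must be named")
  if (any(object@components < 0))
    return("variance components must be non-negative")
  TRUE
})

#' Per-genotype best linear unbiased estimates of a trait
#'
#' @slot values named numeric, one BLUE per line (trait units).
#' @slot trait trait name.
#' @slot h2 broad-sense heritability of the trait (NA when not computed).
#' @exportClass TraitBLUEs
setClass("TraitBLUEs",
  slots = c(values = "numeric", trait = "character", h2 = "numeric"))

setValidity("TraitBLUEs", function(object) {
  if (is.null(names(object@values))) return("values must be named by line id")
  if (anyDuplicated(names(object@values))) return("duplicate line ids")
  TRUE
})

#' Fitted whole-genome (or whole-metabolome) regression effects
#'
#' @slot mu intercept on the scale of the canonical predictor coding (the
#'   coding of the matrix handed to \code{\link{predictValues}}).
#' @slot effects named numeric effect per predictor.
#' @slot model "rr_blup" or "bayes_b".
#' @slot coding predictor coding used internally by the fit.
#' @slot inclusionProb posterior inclusion probability per predictor
#'   (BayesB; empty for RR-BLUP).
#' @slot pi posterior mean of the exclusion probability (BayesB).
#' @slot sigma2e posterior mean residual variance (BayesB).
#' @exportClass MarkerEffects
setClass("MarkerEffects",
  slots = c(mu = "numeric", effects = "numeric", model = "character",
            coding = "character", inclusionProb = "numeric",
            pi = "numeric", sigma2e = "numeric"))

setValidity("MarkerEffects", function(object) {
  if (is.null(names(object@effects))) return("effects must be named")
  if (!all(is.finite(object@effects))) return("effects must be finite")
  if (length(object@inclusionProb) &&
      length(object@inclusionProb) != length(object@effects))
    return("inclusionProb must match effects in length")
  TRUE
})

#' Prior settings for the BayesB Gibbs sampler
#'
#' Each effect is exactly zero with probability pi; otherwise its own
#' variance follows a scaled inverse chi-squared prior with \code{df0}
#' degrees of freedom and scale \code{scale0}. pi itself carries a beta
#' prior. The residual variance has a scaled inverse chi-squared prior.
#'
#' @slot piShape beta shape pair (alpha, beta) of the prior on the
#'   exclusion probability pi.
#' @slot df0,scale0 slab prior degrees of freedom and scale; \code{scale0 =
#'   NA} derives the scale so the prior slab explains half the phenotypic
#'   variance given the mean predictor variance.
#' @slot dfE,scaleE residual-variance prior; \code{scaleE = NA} is derived
#'   analogously.
#' @slot nIter,burnIn,thin chain length controls.
#' @slot fixPi fix pi at this value instead of sampling it (NA = sample).
#' @exportClass BayesBPriors
setClass("BayesBPriors",
  slots = c(piShape = "numeric", df0 = "numeric", scale0 = "numeric",
            dfE = "numeric", scaleE = "numeric",
            nIter = "integer", burnIn = "integer", thin = "integer",
            fixPi = "numeric"))

setValidity("BayesBPriors", function(object) {
  if (length(object@piShape) != 2 || any(object@piShape <= 0))
    return("piShape must be two positive beta shapes")
  if (object@df0 <= 0) return("df0 must be positive")
  if (!is.na(object@scale0) && object@scale0 <= 0)
    return("scale0 must be positive (or NA for the data-derived default)")
  if (object@burnIn >= object@nIter) return("burnIn must be below nIter")
  if (object@thin < 1) return("thin must be >= 1")
  if (!is.na(object@fixPi) && (object@fixPi < 0 || object@fixPi > 1))
    return("fixPi must lie in [0, 1]")
  TRUE
})

#' Cross-validation result for one (trait, predictor set, model) cell
#'
#' @slot abilities per-evaluation Pearson correlations between observed and
#'   predicted values in the held-out lines.
#' @slot rAb mean prediction ability.
#' @slot rAc prediction accuracy rAb / sqrt(h2).
#' @slot sd standard deviation of per-evaluation accuracies.
#' @slot h2 heritability used for the accuracy scaling.
#' @slot model,predictorSet,trait labels.
#' @slot nFolds,nRuns,seed replication bookkeeping; results with equal seed,
#'   folds and runs share partitions and may be compared pairwise.
#' @exportClass CVResult
setClass("CVResult",
  slots = c(abilities = "numeric", rAb = "numeric", rAc = "numeric",
            sd = "numeric", h2 = "numeric", model = "character",
            predictorSet = "character", trait = "character",
            nFolds = "integer", nRuns = "integer", seed = "integer"))

setValidity("CVResult", function(object) {
  if (length(object@rAb) == 1 && is.finite(object@rAb) &&
      abs(object@rAb) > 1 + 1e-12)
    return("mean ability must lie in [-1, 1]")
  TRUE
})
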