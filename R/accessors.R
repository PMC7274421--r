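#' Constructors for the core containers
#'
#' Thin validated constructors; most users obtain these objects from the
#' simulator or the readers instead.
#'
#' @param dosage numeric lines x markers matrix with dimnames.
#' @param family character family label per line.
#' @param map optional marker map data.frame (id, chrom, pos).
#' @return A validated object of the corresponding class.
#' @export
GenotypeMatrix <- function(dosage, family, map = NULL) {
  if (is.null(map)) map <- data.frame(id = character(), chrom = character(),
                                      pos = numeric())
  new("GenotypeMatrix", dosage = dosage, family = as.character(family),
      map = map)
}

#' @rdname GenotypeMatrix
#' @param intensities numeric lines x metabolites matrix with dimnames.
#' @param samplingDate free-text tag for the sampling campaign.
#' @export
MetaboliteMatrix <- function(intensities, samplingDate = "sim") {
  new("MetaboliteMatrix", intensities = intensities,
      samplingDate = samplingDate)
}

#' @rdname GenotypeMatrix
#' @param chromosomes data.frame (id, length in cM).
#' @param markers data.frame (id, chrom, pos in cM).
#' @export
GeneticMap <- function(chromosomes, markers) {
  new("GeneticMap", chromosomes = chromosomes, markers = markers)
}

#' Validate a plot-level phenotype table
#'
#' Long-format plot observations with one row per (line, year, replicate,
#' trait). Used as input to variance-component estimation and BLUEs.
#'
#' @param df data.frame with columns \code{line_id}, \code{year},
#'   \code{replicate}, \code{trait}, \code{value}.
#' @return The validated data.frame (invisibly classed for printing).
#' @export
plotPhenotypeTable <- function(df) {
  need <- c("line_id", "year", "replicate", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$value)))
    stop("phenotype values must be finite")
  key <- paste(df$line_id, df$year, df$replicate, df$trait)
  if (anyDuplicated(key))
    stop("duplicate (line, year, replicate, trait) records")
  df
}

#' Accessors for genotype containers
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return \code{dosage}: the numeric matrix; \code{families}: family label
#'   per line; \code{lineIds}/\code{markerIds}: dimnames; \code{markerMap}:
#'   the attached map data.frame.
#' @name dosage
NULL

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @rdname dosage
#' @export
setMethod("families", "GenotypeMatrix", function(x)
  stats::setNames(x@family, rownames(x@dosage)))

#' @rdname dosage
#' @export
setMethod("lineIds", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @rdname dosage
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@dosage))

#' @rdname dosage
#' @export
setMethod("markerMap", "GenotypeMatrix", function(x) x@map)

#' @rdname dosage
#' @export
setMethod("lineIds", "MetaboliteMatrix", function(x) rownames(x@intensities))

#' Accessors for metabolite containers
#'
#' @param x a \linkS4class{MetaboliteMatrix}.
#' @return \code{intensities}: the numeric matrix; \code{metaboliteIds}:
#'   its column names.
#' @name intensities
NULL

#' @rdname intensities
#' @export
setMethod("intensities", "MetaboliteMatrix", function(x) x@intensities)

#' @rdname intensities
#' @export
setMethod("metaboliteIds", "MetaboliteMatrix", function(x)
  colnames(x@intensities))

#' Accessors for fitted effects
#'
#' @param x a \linkS4class{MarkerEffects}.
#' @return \code{intercept}: the intercept on the canonical coding;
#'   \code{effectsVector}: named per-predictor effects;
#'   \code{inclusionProb}: BayesB posterior inclusion probabilities.
#' @name effects-access
NULL

#' @rdname effects-access
#' @export
setMethod("intercept", "MarkerEffects", function(x) x@mu)

#' @rdname effects-access
#' @export
setMethod("effectsVector", "MarkerEffects", function(x) x@effects)

#' @rdname effects-access
#' @export
setMethod("inclusionProb", "MarkerEffects", function(x) x@inclusionProb)

#' Accessors for trait BLUEs
#'
#' @param x a \linkS4class{TraitBLUEs} (or \linkS4class{CVResult} for
#'   \code{heritability}).
#' @return \code{blues}: named numeric per-line estimates;
#'   \code{heritability}: the trait heritability.
#' @name blues-access
NULL

#' @rdname blues-access
#' @export
setMethod("blues", "TraitBLUEs", function(x) x@values)

#' @rdname blues-access
#' @export
setMethod("heritability", "TraitBLUEs", function(x) x@h2)

#' @rdname blues-access
#' @export
setMethod("heritability", "CVResult", function(x) x@h2)

#' Accessors for cross-validation results
#'
#' @param x a \linkS4class{CVResult}.
#' @return \code{abilities}: the per-evaluation correlations;
#'   \code{predictionAbility}: their mean (r_ab).
#' @name cv-access
NULL

#' @rdname cv-access
#' @export
setMethod("abilities", "CVResult", function(x) x@abilities)

#' @rdname cv-access
#' @export
setMethod("predictionAbility", "CVResult", function(x) x@rAb)

#' Accessor for variance components
#'
#' @param x a \linkS4class{VarianceComponents}.
#' @return Named numeric vector of components.
#' @name vc-access
NULL

#' @rdname vc-access
#' @export
setMethod("varianceComponents", "VarianceComponents",
          function(x) x@components)

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d markers on %d chromosomes (%.0f cM total)\n",
              nrow(object@markers), nrow(object@chromosomes),
              sum(object@chromosomes$length)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  cat(sprintf(
    "GenotypeMatrix: %d lines x %d markers, %d families, %.2f%% missing\n",
    nrow(d), ncol(d), length(unique(object@family)),
    100 * mean(is.na(d))))
})

setMethod("show", "MetaboliteMatrix", function(object) {
  m <- object@intensities
  cat(sprintf(
    "MetaboliteMatrix [%s]: %d lines x %d metabolites, %.2f%% missing\n",
    object@samplingDate, nrow(m), ncol(m), 100 * mean(is.na(m))))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents (%s model):\n", object@model))
  print(round(object@components, 6))
})

setMethod("show", "TraitBLUEs", function(object) {
  cat(sprintf("TraitBLUEs for %s: %d lines, h2 = %s\n", object@trait,
              length(object@values),
              ifelse(is.na(object@h2), "NA", sprintf("%.3f", object@h2))))
})

setMethod("show", "MarkerEffects", function(object) {
  cat(sprintf("MarkerEffects (%s): mu = %.4g, %d predictors\n",
              object@model, object@mu, length(object@effects)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult %s / %s / %s: r_ab = %.3f, r_ac = %.3f (SD %.3f), %d runs\n",
    object@trait, object@predictorSet, object@model, object@rAb,
    object@rAc, object@sd, object@nRuns))
})
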