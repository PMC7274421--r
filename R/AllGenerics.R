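#' @rdname dosage
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname dosage
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @rdname dosage
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname dosage
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname dosage
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname intensities
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname effects-access
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @rdname effects-access
#' @export
setGeneric("effectsVector", function(x) standardGeneric("effectsVector"))

#' @rdname effects-access
#' @export
setGeneric("inclusionProb", function(x) standardGeneric("inclusionProb"))

#' @rdname blues-access
#' @export
setGeneric("blues", function(x) standardGeneric("blues"))

#' @rdname blues-access
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname cv-access
#' @export
setGeneric("abilities", function(x) standardGeneric("abilities"))

#' @rdname cv-access
#' @export
setGeneric("predictionAbility", function(x) standardGeneric("predictionAbility"))

#' @rdname vc-access
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
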