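# Correlation and distance analyses comparing the genomic and metabolic
# layers.

#' Pearson correlations between trait BLUEs and metabolite intensities
#'
#' One correlation per (trait, metabolite) pair over pairwise-complete
#' shared lines.
#'
#' @param bluesList named list of \linkS4class{TraitBLUEs} (or named
#'   numeric vectors).
#' @param m a \linkS4class{MetaboliteMatrix}.
#' @return Long data.frame (trait, metabolite, r).
#' @export
traitMetaboliteCorrelations <- function(bluesList, m) {
  stopifnot(is(m, "MetaboliteMatrix"))
  x <- intensities(m)
  rows <- list()
  for (tn in names(bluesList)) {
    b <- bluesList[[tn]]
    if (is(b, "TraitBLUEs")) b <- blues(b)
    shared <- intersect(names(b), rownames(x))
    if (length(shared) < 3)
      stop("fewer than 3 shared lines for trait ", tn)
    r <- suppressWarnings(
      stats::cor(b[shared], x[shared, , drop = FALSE],
                 use = "pairwise.complete.obs"))
    rows[[tn]] <- data.frame(trait = tn, metabolite = colnames(x),
                             r = drop(r), row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Correlation matrix of fitted effect vectors across traits
#'
#' Pearson correlations between per-predictor effect vectors of models
#' fitted on the identical predictor set; high values indicate shared
#' genetic (or metabolic) control of the traits.
#'
#' @param effectsList named list of \linkS4class{MarkerEffects}.
#' @return Symmetric trait x trait correlation matrix.
#' @export
effectCorrelationMatrix <- function(effectsList) {
  stopifnot(length(effectsList) >= 1)
  ids <- names(effectsList[[1]]@effects)
  for (e in effectsList)
    if (!identical(names(e@effects), ids))
      stop("effect vectors fitted on different predictor sets")
  G <- vapply(effectsList, function(e) unname(e@effects),
              numeric(length(ids)))
  stats::cor(G)
}

#' Compare Euclidean distance structure of two predictor layers
#'
#' Computes pairwise Euclidean line-by-line distances for each matrix and
#' the Pearson correlation of the two strictly-lower triangles.
#'
#' @param Xsnp,Xmet matrices over the same, identically ordered line set
#'   (or the corresponding containers).
#' @return list with \code{dSnp}, \code{dMet} (objects of class
#'   \code{dist}) and \code{r}.
#' @export
distanceMatrixComparison <- function(Xsnp, Xmet) {
  if (is(Xsnp, "GenotypeMatrix")) Xsnp <- dosage(Xsnp)
  if (is(Xmet, "MetaboliteMatrix")) Xmet <- intensities(Xmet)
  if (nrow(Xsnp) < 3) stop("need at least 3 lines")
  if (!identical(rownames(Xsnp), rownames(Xmet)))
    stop("line sets (or their order) differ")
  d1 <- stats::dist(Xsnp)
  d2 <- stats::dist(Xmet)
  list(dSnp = d1, dMet = d2,
       r = stats::cor(as.vector(d1), as.vector(d2)))
}
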