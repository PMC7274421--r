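# Tab-delimited readers/writers for the three data layers plus the
# ground-truth sidecar. All tables carry a header row; the first column is
# always the line id.

#' Read and write genotype dosage tables
#'
#' Genotype TSV layout: columns \code{line_id}, \code{family}, then one
#' column per marker holding dosages 0/1/2 (or NA). \code{write} then
#' \code{read} is the identity.
#'
#' @param path file path.
#' @param map optional marker map data.frame to attach on read.
#' @param validate check that all cells are raw 0/1/2/NA codes; disable
#'   when reading mean-imputed (fractional) matrices.
#' @return \code{readGenotypeTable}: a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeTable <- function(path, map = NULL, validate = TRUE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  if (!all(c("line_id", "family") %in% names(dt)))
    stop("genotype table must start with 'line_id' and 'family' columns")
  lid <- as.character(dt$line_id)
  fam <- as.character(dt$family)
  markerCols <- setdiff(names(dt), c("line_id", "family"))
  d <- as.matrix(dt[, markerCols, with = FALSE])
  storage.mode(d) <- "double"
  dimnames(d) <- list(lid, markerCols)
  if (validate) {
    bad <- which(!(is.na(d) | d %in% c(0, 1, 2)), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf(
        "invalid dosage %s at line '%s', marker '%s' (expected 0/1/2/NA)",
        format(d[bad[1, 1], bad[1, 2]]), lid[bad[1, 1]],
        markerCols[bad[1, 2]]))
  }
  GenotypeMatrix(d, fam, map = map)
}

#' @rdname readGenotypeTable
#' @param g a \linkS4class{GenotypeMatrix}.
#' @export
writeGenotypeTable <- function(g, path) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- dosage(g)
  dt <- data.table::data.table(line_id = rownames(d), family = g@family)
  dt <- cbind(dt, data.table::as.data.table(d))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read and write long-format plot phenotype tables
#'
#' Layout: \code{line_id}, \code{year}, \code{replicate}, \code{trait},
#' \code{value}.
#'
#' @param path file path.
#' @return \code{readPhenotypeTable}: a validated data.frame.
#' @export
readPhenotypeTable <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  plotPhenotypeTable(df)
}

#' @rdname readPhenotypeTable
#' @param p phenotype data.frame.
#' @export
writePhenotypeTable <- function(p, path) {
  p <- plotPhenotypeTable(p)
  data.table::fwrite(p, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read and write metabolite intensity tables
#'
#' Layout: \code{line_id} then one column per metabolite; missing values as
#' NA.
#'
#' @param path file path.
#' @param samplingDate tag attached on read.
#' @return \code{readMetaboliteTable}: a \linkS4class{MetaboliteMatrix}.
#' @export
readMetaboliteTable <- function(path, samplingDate = "unknown") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  if (!"line_id" %in% names(dt))
    stop("metabolite table must start with a 'line_id' column")
  lid <- as.character(dt$line_id)
  cols <- setdiff(names(dt), "line_id")
  m <- as.matrix(dt[, cols, with = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(lid, cols)
  MetaboliteMatrix(m, samplingDate = samplingDate)
}

#' @rdname readMetaboliteTable
#' @param m a \linkS4class{MetaboliteMatrix}.
#' @export
writeMetaboliteTable <- function(m, path) {
  stopifnot(is(m, "MetaboliteMatrix"))
  x <- intensities(m)
  dt <- data.table::data.table(line_id = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(x))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write the simulation ground truth
#'
#' Two files: a TSV of per-QTL effects plus per-metabolite heritabilities,
#' and a plain-text key-value sidecar with the scalar generating parameters.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param pathTsv,pathSidecar output paths.
#' @export
writeTruthFiles <- function(truth, pathTsv, pathSidecar) {
  qtl <- data.table::data.table(
    kind = "trait_qtl",
    id = as.character(truth@qtlIndices),
    value = truth@qtlEffects)
  if (length(truth@metaboliteH2) > 0)
    qtl <- rbind(qtl, data.table::data.table(
      kind = "metabolite_h2",
      id = names(truth@metaboliteH2),
      value = unname(truth@metaboliteH2)))
  data.table::fwrite(qtl, pathTsv, sep = "\t", quote = FALSE)
  kv <- c(
    sprintf("target_h2: %.10g", truth@targetH2),
    sprintf("gxy_variance_ratio: %.10g", truth@gxyRatio),
    sprintf("var_G: %.10g", truth@varG),
    sprintf("var_GY: %.10g", truth@varGY),
    sprintf("var_R: %.10g", truth@varR),
    sprintf("n_trait_qtl: %d", length(truth@qtlIndices)),
    sprintf("n_metabolites: %d", length(truth@metaboliteH2)))
  writeLines(kv, pathSidecar)
  invisible(c(pathTsv, pathSidecar))
}
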