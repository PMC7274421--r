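# Configuration-driven orchestration: simulate, predict, reduce. A thin
# command-line wrapper over these functions ships in inst/cli/metaGP.R.

.defaultConfig <- function() list(
  seed = 1L,
  output_dir = "metaGP_out",
  simulate = list(
    n_chrom = 3L, markers_per_chrom = 150L, chrom_length_cm = 150,
    n_families = 6L, lines_per_family = 30L, selfing_generations = 3L,
    donor_fraction = 0.5, n_qtl = 40L, target_h2 = 0.9, n_years = 4L,
    n_reps = 2L, gxy_ratio = 0.1, trait = "SIMTRAIT",
    n_metabolites = 30L, h2_snp_mean = 0.1, h2_snp_max = 0.5,
    missing_rate = 0.05, shared_qtl_fraction = 0.5),
  qc = list(max_failure = 0.10, max_het = 0.125, max_met_missing = 0.10,
            boxcox_metabolites = FALSE,
            lambda_grid = seq(-3, 3, by = 0.25)),
  cv = list(n_folds = 5L, n_runs = 100L, models = "rr_blup",
            predictor_sets = c("snp", "metabolite", "combined")),
  reduction = list(fractions = c(0.5, 0.25, 0.1),
                   modes = c("best", "random")),
  alpha = 0.01)

.mergeConfig <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      .mergeConfig(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Read a run configuration
#'
#' Plain structured text (YAML). Missing keys fall back to package
#' defaults, which mirror the published analysis settings (QC thresholds
#' 0.10 / 0.125, metabolite missingness 0.10, Box-Cox grid -3..3 by 0.25,
#' 5 folds, 100 runs, alpha 0.01).
#'
#' @param path YAML file path; NULL returns the defaults.
#' @return Nested configuration list; \code{$config_path} records the
#'   source file.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- .mergeConfig(cfg, yaml::read_yaml(path))
    cfg$config_path <- path
  }
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

.writeManifest <- function(cfg, outDir, extra = list()) {
  man <- c(list(
    seed = cfg$seed,
    package = "metaGP",
    package_version = as.character(utils::packageVersion("metaGP")),
    config_md5 = if (!is.null(cfg$config_path))
      unname(tools::md5sum(cfg$config_path)) else NA,
    parameters = cfg[setdiff(names(cfg), "config_path")]), extra)
  yaml::write_yaml(man, file.path(outDir, "manifest.yaml"))
}

# Simulate the three data layers in memory.
.simulateAll <- function(cfg) {
  s <- cfg$simulate
  if (is.null(s)) stop("config has no 'simulate' block and no input paths")
  map <- simulateGeneticMap(s$n_chrom, s$markers_per_chrom,
                            s$chrom_length_cm, seed = cfg$seed)
  geno <- simulateNamPopulation(map, s$n_families, s$lines_per_family,
                                s$selfing_generations, seed = cfg$seed,
                                donorFraction = s$donor_fraction)
  ph <- simulatePhenotypes(geno, s$n_qtl, s$target_h2, s$n_years, s$n_reps,
                           gxyRatio = s$gxy_ratio, seed = cfg$seed,
                           trait = s$trait)
  met <- simulateMetabolites(geno, s$n_metabolites, s$h2_snp_mean,
                             s$h2_snp_max, s$missing_rate,
                             traitTruth = ph$truth,
                             sharedQtlFraction = s$shared_qtl_fraction,
                             seed = cfg$seed)
  list(genotypes = geno, phenotypes = ph$phenotypes,
       metabolites = met$metabolites, truth = met$truth)
}

.loadInputs <- function(cfg) {
  p <- cfg$paths
  if (!is.null(p$genotype)) {
    list(genotypes = readGenotypeTable(p$genotype),
         phenotypes = readPhenotypeTable(p$phenotype),
         metabolites = readMetaboliteTable(p$metabolite),
         truth = NULL)
  } else .simulateAll(cfg)
}

#' Simulate and write a full synthetic data set
#'
#' Writes genotype, phenotype and metabolite TSVs plus the ground-truth
#' TSV, a key-value truth sidecar and a manifest recording the seed and
#' every parameter. Identical configurations produce byte-identical files.
#'
#' @param config configuration list from \code{\link{readRunConfig}}.
#' @param outDir output directory (default from the config).
#' @return Invisibly, the named vector of written paths.
#' @export
cmdSimulate <- function(config = readRunConfig(), outDir = NULL) {
  if (is.null(outDir)) outDir <- config$output_dir
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  dat <- .simulateAll(config)
  paths <- c(genotype = file.path(outDir, "genotypes.tsv"),
             phenotype = file.path(outDir, "phenotypes.tsv"),
             metabolite = file.path(outDir, "metabolites.tsv"),
             truth = file.path(outDir, "truth.tsv"),
             truth_sidecar = file.path(outDir, "truth_params.txt"))
  writeGenotypeTable(dat$genotypes, paths["genotype"])
  writePhenotypeTable(dat$phenotypes, paths["phenotype"])
  writeMetaboliteTable(dat$metabolites, paths["metabolite"])
  writeTruthFiles(dat$truth, paths["truth"], paths["truth_sidecar"])
  .writeManifest(config, outDir, list(stage = "simulate"))
  invisible(paths)
}

# shared preprocessing for predict/reduce
.prepare <- function(cfg) {
  dat <- .loadInputs(cfg)
  qc <- cfg$qc
  g <- monomorphicFamilyRecode(dat$genotypes)
  g <- qcFilterSnps(g, qc$max_failure, qc$max_het, verbose = TRUE)
  g <- imputeMNI(g)
  m <- filterMetabolites(dat$metabolites, qc$max_met_missing, verbose = TRUE)
  m <- imputeMetaboliteMin(m)
  if (isTRUE(qc$boxcox_metabolites)) {
    x <- intensities(m)
    grid <- qc$lambda_grid
    if (length(grid) == 3 && is.null(names(grid)) && grid[3] < grid[2])
      grid <- seq(grid[1], grid[2], by = grid[3])
    for (j in seq_len(ncol(x)))
      x[, j] <- boxcoxTransform(x[, j], grid)$transformed
    m <- MetaboliteMatrix(x, samplingDate = m@samplingDate)
  }
  list(genotypes = g, phenotypes = dat$phenotypes, metabolites = m,
       truth = dat$truth)
}

.predictorMatrix <- function(set, g, m) {
  shared <- intersect(lineIds(g), lineIds(m))
  Xs <- dosage(g)[shared, , drop = FALSE]
  Xm <- intensities(m)[shared, , drop = FALSE]
  switch(set,
         snp = Xs,
         metabolite = scale(Xm),
         combined = combinePredictors(Xs, Xm),
         stop("unknown predictor set: ", set))
}

#' Run the full prediction pipeline
#'
#' Preprocessing, variance components, heritability and BLUEs per trait,
#' then cross-validated prediction for every (trait, predictor set, model)
#' combination, with a significance test of each predictor set against the
#' SNP set on shared partitions. Writes \code{summary.tsv} and a manifest.
#'
#' @param config configuration list from \code{\link{readRunConfig}}.
#' @param outDir output directory (default from the config).
#' @return The summary data.frame (invisibly written to disk).
#' @export
cmdPredict <- function(config = readRunConfig(), outDir = NULL) {
  if (is.null(outDir)) outDir <- config$output_dir
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  prep <- tryCatch(.prepare(config),
                   error = function(e) stop("preprocessing stage: ",
                                            conditionMessage(e)))
  cvc <- config$cv
  rows <- list()
  cvStore <- list()
  for (tr in unique(prep$phenotypes$trait)) {
    vc <- tryCatch(estimateVarianceComponents(prep$phenotypes, tr),
                   error = function(e) stop("variance-component stage: ",
                                            conditionMessage(e)))
    h2 <- broadSenseHeritability(vc)
    bl <- computeBlues(prep$phenotypes, tr, h2 = h2)
    for (set in cvc$predictor_sets) {
      X <- .predictorMatrix(set, prep$genotypes, prep$metabolites)
      lam <- rrblupLambda(vc@components[["V_G"]],
                          max(vc@components[["V_R"]], 1e-8),
                          ncol(X), vc@nYears)
      for (mod in cvc$models) {
        cv <- tryCatch(runCrossValidation(
          bl, X, families(prep$genotypes)[rownames(X)], model = mod,
          nRuns = cvc$n_runs, nFolds = cvc$n_folds, seed = config$seed,
          lambda = lam, h2 = h2, predictorSet = set),
          error = function(e) stop("cross-validation stage: ",
                                   conditionMessage(e)))
        cvStore[[paste(tr, set, mod)]] <- cv
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, predictor_set = set, model = mod, h2 = h2,
          r_ab = cv@rAb, r_ac = cv@rAc, sd = cv@sd)
      }
    }
  }
  summary <- do.call(rbind, rows)
  summary$sig_vs_snp <- NA
  for (i in seq_len(nrow(summary))) {
    key <- paste(summary$trait[i], summary$predictor_set[i], summary$model[i])
    ref <- paste(summary$trait[i], "snp", summary$model[i])
    if (summary$predictor_set[i] != "snp" && !is.null(cvStore[[ref]])) {
      cmp <- compareModels(cvStore[[key]], cvStore[[ref]],
                           alpha = config$alpha, paired = TRUE)
      summary$sig_vs_snp[i] <- cmp$significant
    }
  }
  data.table::fwrite(summary, file.path(outDir, "summary.tsv"), sep = "\t")
  .writeManifest(config, outDir, list(stage = "predict"))
  invisible(summary)
}

#' Run the predictor-reduction experiment
#'
#' For every trait and the SNP predictor set, fits full-data effects and
#' tabulates cross-validated accuracy for each (fraction, mode) subset.
#' Writes \code{reduction.tsv}.
#'
#' @param config configuration list from \code{\link{readRunConfig}}.
#' @param outDir output directory (default from the config).
#' @return The reduction data.frame.
#' @export
cmdReduce <- function(config = readRunConfig(), outDir = NULL) {
  if (is.null(outDir)) outDir <- config$output_dir
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  prep <- .prepare(config)
  cvc <- config$cv
  red <- config$reduction
  rows <- list()
  for (tr in unique(prep$phenotypes$trait)) {
    vc <- estimateVarianceComponents(prep$phenotypes, tr)
    h2 <- broadSenseHeritability(vc)
    bl <- computeBlues(prep$phenotypes, tr, h2 = h2)
    X <- .predictorMatrix("snp", prep$genotypes, prep$metabolites)
    lam <- rrblupLambda(vc@components[["V_G"]],
                        max(vc@components[["V_R"]], 1e-8),
                        ncol(X), vc@nYears)
    tab <- reductionExperiment(
      bl, X, families(prep$genotypes)[rownames(X)],
      model = cvc$models[1], fractions = red$fractions, modes = red$modes,
      nRuns = cvc$n_runs, nFolds = cvc$n_folds, seed = config$seed,
      lambda = lam, h2 = h2, verbose = TRUE)
    tab$trait <- tr
    rows[[length(rows) + 1L]] <- tab
  }
  out <- do.call(rbind, rows)
  data.table::fwrite(out, file.path(outDir, "reduction.tsv"), sep = "\t")
  .writeManifest(config, outDir, list(stage = "reduce"))
  invisible(out)
}
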