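#' Simulate a genetic map with near-uniform marker spacing
#'
#' Markers are laid out evenly along each chromosome with small random
#' jitter, emulating a dense genotyping array whose markers cover the whole
#' genome with few gaps.
#'
#' @param nChrom number of chromosomes.
#' @param markersPerChrom markers per chromosome.
#' @param chromLengthCM genetic length of each chromosome in centiMorgan.
#' @param seed integer seed; the map is fully reproducible given the seed.
#' @return A \linkS4class{GeneticMap}.
#' @examples
#' simulateGeneticMap(7, 100, 150, seed = 1)
#' @export
simulateGeneticMap <- function(nChrom, markersPerChrom, chromLengthCM,
                               seed = 1L) {
  nChrom <- .assertCount(nChrom, "nChrom")
  markersPerChrom <- .assertCount(markersPerChrom, "markersPerChrom")
  if (!is.numeric(chromLengthCM) || chromLengthCM <= 0)
    stop("'chromLengthCM' must be a positive genetic length in cM")
  .withSeed(.subSeed(seed, "genmap"), {
    chroms <- data.frame(id = sprintf("chr%d", seq_len(nChrom)),
                         length = rep(chromLengthCM, nChrom))
    mk <- do.call(rbind, lapply(seq_len(nChrom), function(ci) {
      spacing <- chromLengthCM / markersPerChrom
      pos <- (seq_len(markersPerChrom) - 0.5) * spacing +
        stats::rnorm(markersPerChrom, 0, spacing / 10)
      pos <- sort(pmin(pmax(pos, 0), chromLengthCM))
      data.frame(id = sprintf("chr%d_m%04d", ci, seq_len(markersPerChrom)),
                 chrom = sprintf("chr%d", ci), pos = pos)
    }))
    GeneticMap(chroms, mk)
  })
}

# One meiosis: recombine two haplotypes with crossovers following a Poisson
# process at 1 event / 100 cM, no interference. chromIdx/chromPos/chromLen
# are precomputed per-chromosome marker index sets, positions and lengths.
.meiosis <- function(h1, h2, chromIdx, chromPos, chromLen) {
  out <- h1
  for (ci in seq_along(chromIdx)) {
    idx <- chromIdx[[ci]]
    nco <- stats::rpois(1L, chromLen[ci] / 100)
    start <- stats::runif(1) < 0.5
    if (nco == 0L) {
      if (!start) out[idx] <- h2[idx]
    } else {
      seg <- findInterval(chromPos[[ci]], sort(stats::runif(nco, 0, chromLen[ci])))
      useSecond <- xor(start, seg %% 2L == 1L)
      out[idx] <- ifelse(useSecond, h2[idx], h1[idx])
    }
  }
  out
}

#' Simulate a NAM population by backcrossing and selfing
#'
#' Emulates a nested association mapping design: a panel of fully inbred
#' donors each crossed to one common recurrent elite parent, the F1
#' backcrossed once to the recurrent parent, then advanced by single-seed
#' descent for a number of selfing generations (BC1S3 by default usage).
#' Dosages count donor alleles: recurrent-parent homozygote 0, heterozygote
#' 1, donor homozygote 2. Each donor is polymorphic only at a
#' family-specific subset of markers, so families segregate at different
#' marker sets as in real multi-donor designs.
#'
#' Expected donor allele frequency at segregating loci is 0.25 after the
#' backcross and is unchanged by selfing; expected residual heterozygosity
#' after s selfing generations is 0.5 * (1/2)^s (0.0625 for s = 3).
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param nFamilies number of donor families.
#' @param linesPerFamily lines per family (equal sizes).
#' @param selfingGenerations number of selfing generations after the
#'   backcross (>= 0).
#' @param seed integer seed.
#' @param donorFraction fraction of markers polymorphic in each family.
#' @return A \linkS4class{GenotypeMatrix} with family labels and the map.
#' @examples
#' map <- simulateGeneticMap(2, 40, 120, seed = 1)
#' pop <- simulateNamPopulation(map, 4, 10, 3, seed = 7)
#' @export
simulateNamPopulation <- function(map, nFamilies, linesPerFamily,
                                  selfingGenerations, seed = 1L,
                                  donorFraction = 0.5) {
  stopifnot(is(map, "GeneticMap"))
  if (nrow(map@markers) == 0) stop("empty genetic map")
  nFamilies <- .assertCount(nFamilies, "nFamilies")
  linesPerFamily <- .assertCount(linesPerFamily, "linesPerFamily")
  selfingGenerations <- .assertCount(selfingGenerations,
                                     "selfingGenerations", min = 0)
  if (donorFraction <= 0 || donorFraction > 1)
    stop("'donorFraction' must lie in (0, 1]")

  mk <- map@markers
  m <- nrow(mk)
  chromIds <- map@chromosomes$id
  chromIdx <- lapply(chromIds, function(cc) which(mk$chrom == cc))
  chromPos <- lapply(seq_along(chromIds), function(i) mk$pos[chromIdx[[i]]])
  chromLen <- map@chromosomes$length

  .withSeed(.subSeed(seed, "nampop"), {
    n <- nFamilies * linesPerFamily
    dos <- matrix(0L, n, m)
    fam <- character(n)
    lid <- character(n)
    row <- 0L
    hapR <- integer(m)  # recurrent parent: all zeros
    for (f in seq_len(nFamilies)) {
      donorSet <- sort(sample.int(m, max(1L, round(donorFraction * m))))
      hapD <- integer(m)
      hapD[donorSet] <- 1L
      for (l in seq_len(linesPerFamily)) {
        # BC1: gamete of the F1 (hapR x hapD) united with a recurrent gamete
        h1 <- .meiosis(hapR, hapD, chromIdx, chromPos, chromLen)
        h2 <- hapR
        for (s in seq_len(selfingGenerations)) {
          g1 <- .meiosis(h1, h2, chromIdx, chromPos, chromLen)
          g2 <- .meiosis(h1, h2, chromIdx, chromPos, chromLen)
          h1 <- g1
          h2 <- g2
        }
        row <- row + 1L
        dos[row, ] <- h1 + h2
        fam[row] <- sprintf("F%02d", f)
        lid[row] <- sprintf("F%02d_L%04d", f, l)
      }
    }
    dimnames(dos) <- list(lid, mk$id)
    GenotypeMatrix(dos, fam, map = mk)
  })
}

#' Simulate multi-year replicated phenotypes with known truth
#'
#' Genotypic values are sums of additive QTL effects over sampled
#' polymorphic markers. Plot values add a year main effect (wide normal,
#' cancelling in BLUEs), a genotype-by-year deviate with variance
#' \code{gxyRatio * V_G}, and a plot residual whose variance is solved so
#' the entry-mean heritability h2 = V_G / (V_G + V_GY/y + V_R/(y r))
#' equals \code{targetH2} at the simulated numbers of years y and
#' replicates r.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param nQtl number of trait QTL.
#' @param targetH2 broad-sense heritability to calibrate to, in (0, 1].
#' @param nYears,nReps trial design.
#' @param gxyRatio V_GY / V_G (>= 0).
#' @param seed integer seed.
#' @param trait trait label written into the table.
#' @return list with \code{phenotypes} (long plot table, see
#'   \code{\link{plotPhenotypeTable}}) and \code{truth}
#'   (\linkS4class{SimTruth}).
#' @export
simulatePhenotypes <- function(genotypes, nQtl, targetH2, nYears, nReps,
                               gxyRatio = 0.1, seed = 1L,
                               trait = "SIMTRAIT") {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  if (!is.numeric(targetH2) || targetH2 <= 0 || targetH2 > 1)
    stop("'targetH2' must lie in (0, 1]")
  nYears <- .assertCount(nYears, "nYears")
  nReps <- .assertCount(nReps, "nReps")
  if (gxyRatio < 0) stop("'gxyRatio' must be >= 0")
  X <- dosage(genotypes)
  nQtl <- .assertCount(nQtl, "nQtl")
  if (nQtl > ncol(X)) stop("more QTL requested than markers available")

  .withSeed(.subSeed(seed, "phenos"), {
    polym <- which(.colVars(X) > 0)
    if (length(polym) < nQtl)
      stop("not enough polymorphic markers to place the QTL")
    qtl <- sort(sample(polym, nQtl))
    eff <- stats::rnorm(nQtl)
    gval <- drop(X[, qtl, drop = FALSE] %*% eff)
    names(gval) <- rownames(X)
    vG <- stats::var(gval)
    vGY <- gxyRatio * vG
    vR <- nYears * nReps * (vG / targetH2 - vG - vGY / nYears)
    if (vR < -1e-9)
      stop("targetH2 unattainable: genotype-by-year variance alone ",
           "already exceeds the implied non-genetic budget")
    vR <- max(vR, 0)
    n <- nrow(X)
    yearEff <- stats::rnorm(nYears, 0, 2 * sqrt(vG))
    years <- 2011L + seq_len(nYears) - 1L
    recs <- vector("list", nYears)
    for (yi in seq_len(nYears)) {
      gxy <- stats::rnorm(n, 0, sqrt(vGY))
      for (ri in seq_len(nReps)) {
        val <- gval + yearEff[yi] + gxy +
          stats::rnorm(n, 0, sqrt(vR))
        recs[[length(recs) + 1L]] <- data.frame(
          line_id = rownames(X), year = years[yi], replicate = ri,
          trait = trait, value = val, row.names = NULL)
      }
    }
    tab <- do.call(rbind, recs)
    truth <- new("SimTruth", qtlIndices = as.integer(qtl), qtlEffects = eff,
                 targetH2 = targetH2, gxyRatio = gxyRatio, varG = vG,
                 varGY = vGY, varR = vR, genotypicValues = gval,
                 metaboliteH2 = numeric(), metaboliteQtl = list())
    list(phenotypes = plotPhenotypeTable(tab), truth = truth)
  })
}

#' Simulate a metabolite layer with low genomic heritability
#'
#' Each metabolite carries a small additive genetic signal (a few QTL, a
#' configurable fraction shared with the trait QTL) plus dominant noise, so
#' per-metabolite genomic heritabilities follow a right-skewed distribution
#' with the requested mean and maximum. Missing entries are inserted
#' completely at random per metabolite. Intensities are shifted to be
#' non-negative; the shift does not alter any variance component.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param nMetabolites number of metabolite features.
#' @param h2SnpMean,h2SnpMax target mean and maximum genomic heritability.
#' @param missingRate per-metabolite missingness rate, in [0, 1).
#' @param traitTruth \linkS4class{SimTruth} of a simulated trait (its QTL
#'   seed the shared fraction); may be NULL for fully independent QTL.
#' @param sharedQtlFraction fraction of each metabolite's QTL drawn from the
#'   trait's QTL set, in [0, 1].
#' @param seed integer seed.
#' @param nQtlPerMetabolite QTL per metabolite.
#' @return list with \code{metabolites} (\linkS4class{MetaboliteMatrix}) and
#'   \code{truth} (\linkS4class{SimTruth} carrying per-metabolite
#'   heritabilities and QTL).
#' @export
simulateMetabolites <- function(genotypes, nMetabolites, h2SnpMean = 0.10,
                                h2SnpMax = 0.50, missingRate = 0.05,
                                traitTruth = NULL, sharedQtlFraction = 0.5,
                                seed = 1L, nQtlPerMetabolite = 5L) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  nMetabolites <- .assertCount(nMetabolites, "nMetabolites")
  if (h2SnpMax < h2SnpMean)
    stop("'h2SnpMax' must be >= 'h2SnpMean'")
  if (h2SnpMean <= 0 || h2SnpMax > 1)
    stop("heritability targets must lie in (0, 1]")
  if (missingRate < 0 || missingRate >= 1)
    stop("'missingRate' must lie in [0, 1)")
  if (sharedQtlFraction < 0 || sharedQtlFraction > 1)
    stop("'sharedQtlFraction' must lie in [0, 1]")
  X <- dosage(genotypes)
  n <- nrow(X)

  .withSeed(.subSeed(seed, "metabolites"), {
    polym <- which(.colVars(X) > 0)
    traitQtl <- if (!is.null(traitTruth)) traitTruth@qtlIndices else integer()
    ratio <- h2SnpMean / h2SnpMax
    betaB <- if (ratio >= 0.999) NA_real_ else (1 - ratio) / ratio
    vals <- matrix(NA_real_, n, nMetabolites)
    h2s <- numeric(nMetabolites)
    qtls <- vector("list", nMetabolites)
    for (j in seq_len(nMetabolites)) {
      h2j <- if (is.na(betaB)) h2SnpMax else
        h2SnpMax * stats::rbeta(1, 1, betaB)
      nShared <- round(sharedQtlFraction * nQtlPerMetabolite)
      nShared <- min(nShared, length(traitQtl))
      qtl <- c(if (nShared > 0) sample(traitQtl, nShared),
               sample(polym, nQtlPerMetabolite - nShared))
      gm <- drop(X[, qtl, drop = FALSE] %*%
                   stats::rnorm(length(qtl)))
      vg <- stats::var(gm)
      if (vg <= 0 || h2j <= 1e-6) {
        h2j <- 0
        v <- stats::rnorm(n)
      } else {
        v <- gm + stats::rnorm(n, 0, sqrt(vg * (1 - h2j) / h2j))
      }
      v <- v - min(v) + 0.1 * max(stats::sd(v), 1e-8)  # keep positive
      if (missingRate > 0) {
        nMiss <- round(missingRate * n)
        if (nMiss > 0) v[sample.int(n, nMiss)] <- NA_real_
      }
      vals[, j] <- v
      h2s[j] <- h2j
      qtls[[j]] <- as.integer(qtl)
    }
    ids <- sprintf("MET%03d", seq_len(nMetabolites))
    dimnames(vals) <- list(rownames(X), ids)
    names(h2s) <- ids
    names(qtls) <- ids
    truth <- if (!is.null(traitTruth)) traitTruth else
      new("SimTruth", qtlIndices = integer(), qtlEffects = numeric(),
          targetH2 = 1, gxyRatio = 0, varG = 0, varGY = 0, varR = 0,
          genotypicValues = numeric(), metaboliteH2 = numeric(),
          metaboliteQtl = list())
    truth@metaboliteH2 <- h2s
    truth@metaboliteQtl <- qtls
    list(metabolites = MetaboliteMatrix(vals, samplingDate = "simulated"),
         truth = truth)
  })
}
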