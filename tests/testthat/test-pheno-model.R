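# direct simulation from the two-way random model, used as an oracle
simTwoWay <- function(nl, ny, nr, vG, vGY, vR, seed) {
  set.seed(seed)
  lines <- sprintf("L%03d", seq_len(nl))
  gef <- rnorm(nl, 0, sqrt(vG))
  yef <- rnorm(ny, 0, 3)
  gy <- matrix(rnorm(nl * ny, 0, sqrt(vGY)), nl, ny)
  recs <- expand.grid(line = seq_len(nl), year = seq_len(ny),
                      replicate = seq_len(nr))
  data.frame(line_id = lines[recs$line], year = 2010 + recs$year,
             replicate = recs$replicate, trait = "T",
             value = gef[recs$line] + yef[recs$year] +
               gy[cbind(recs$line, recs$year)] +
               rnorm(nrow(recs), 0, sqrt(vR)))
}

test_that("heritability and repeatability ratios evaluate correctly", {
  expect_equal(broadSenseHeritability(c(V_G = 1, V_GY = 0, V_R = 0),
                                      nYears = 3, nReps = 2), 1)
  expect_equal(broadSenseHeritability(c(V_G = 2, V_GY = 1, V_R = 4),
                                      nYears = 5, nReps = 2),
               2 / (2 + 0.2 + 0.4), tolerance = 1e-12)
  # monotone non-decreasing in the number of years
  h <- vapply(1:8, function(y)
    broadSenseHeritability(c(V_G = 1, V_GY = 0.5, V_R = 2),
                           nYears = y, nReps = 2), numeric(1))
  expect_true(all(diff(h) >= 0))
  expect_error(broadSenseHeritability(c(V_G = 0, V_GY = 0, V_R = 0),
                                      nYears = 2, nReps = 2), "undefined")

  expect_equal(repeatability(1, 3, 3), 0.5)
  expect_equal(repeatability(2, 0, 1), 1)
  expect_gt(repeatability(1, 3, 1e9), 0.999)
  expect_error(repeatability(0, 0, 2), "undefined")

  # both ratios are scale invariant
  expect_equal(broadSenseHeritability(7 * c(V_G = 2, V_GY = 1, V_R = 4),
                                      nYears = 5, nReps = 2),
               broadSenseHeritability(c(V_G = 2, V_GY = 1, V_R = 4),
                                      nYears = 5, nReps = 2))
  expect_equal(repeatability(3 * 1, 3 * 3, 3), repeatability(1, 3, 3))
})

test_that("REML components match the balanced-design ANOVA oracle", {
  p <- simTwoWay(60, 4, 2, 2, 0.5, 1, seed = 4)
  vc <- estimateVarianceComponents(p)
  a <- stats::aov(value ~ factor(line_id) * factor(year), data = p)
  ms <- summary(a)[[1]][["Mean Sq"]]
  mom <- c(V_G = (ms[1] - ms[3]) / (2 * 4), V_GY = (ms[3] - ms[4]) / 2,
           V_R = ms[4])
  expect_equal(varianceComponents(vc), mom, tolerance = 1e-6)
  expect_equal(vc@nYears, 4)
  expect_equal(vc@nReps, 2)
})

test_that("variance components recover generating values and vanish under permutation", {
  p <- simTwoWay(500, 8, 2, 2, 0.5, 1, seed = 9)
  vc <- varianceComponents(estimateVarianceComponents(p))
  expect_lt(abs(vc[["V_G"]] / 2 - 1), 0.15)
  expect_lt(abs(vc[["V_GY"]] / 0.5 - 1), 0.15)
  expect_lt(abs(vc[["V_R"]] / 1 - 1), 0.15)

  # permuting line labels within each year destroys the genotype signal
  set.seed(1)
  pp <- p
  for (yr in unique(pp$year)) {
    i <- which(pp$year == yr)
    pp$line_id[i] <- pp$line_id[sample(i)]
  }
  pp <- pp[!duplicated(paste(pp$line_id, pp$year, pp$replicate)), ]
  vcp <- varianceComponents(estimateVarianceComponents(pp))
  expect_lt(vcp[["V_G"]], 0.2 * vc[["V_G"]])

  # zero-noise data (V_GY = V_R = 0): V_G equals the between-line
  # variance, the other components collapse to ~ 0
  p0 <- simTwoWay(80, 3, 2, 3, 0, 0, seed = 2)
  vc0 <- varianceComponents(estimateVarianceComponents(p0))
  lm0 <- as.numeric(tapply(p0$value, p0$line_id, mean))
  expect_equal(vc0[["V_G"]], stats::var(lm0), tolerance = 1e-10)
  expect_lt(vc0[["V_GY"]] + vc0[["V_R"]], 1e-10)

  expect_error(estimateVarianceComponents(simTwoWay(50, 1, 2, 1, 0, 1, 3)),
               "2 years")
  expect_error(estimateVarianceComponents(simTwoWay(50, 3, 1, 1, 0.2, 1, 3)),
               "not separable")
})

test_that("BLUEs equal line means on balanced single-year data and absorb year shifts", {
  p <- simTwoWay(40, 1, 3, 2, 0, 1, seed = 5)
  p <- p[, c("line_id", "year", "replicate", "trait", "value")]
  b <- computeBlues(p)
  lm <- tapply(p$value, p$line_id, mean)
  expect_equal(unname(blues(b)[names(lm)]), as.numeric(lm),
               tolerance = 1e-10)

  p2 <- simTwoWay(40, 3, 2, 2, 0.1, 1, seed = 6)
  b1 <- blues(computeBlues(p2))
  p2s <- p2
  p2s$value[p2s$year == 2012] <- p2s$value[p2s$year == 2012] + 100
  b2 <- blues(computeBlues(p2s))
  expect_equal(b1 - b1[1], b2 - b2[1], tolerance = 1e-8)

  # BLUEs track true genotypic values at the per-line heritability level
  pop <- fixturePop()
  ph <- simulatePhenotypes(pop, 30, 0.8, 4, 2, 0.1, seed = 13)
  bl <- blues(computeBlues(ph$phenotypes))
  gv <- ph$truth@genotypicValues
  expect_gte(cor(bl[names(gv)], gv), sqrt(0.8) - 0.05)
})

test_that("genomic heritability is bounded, near zero under the null and recovers additive signal", {
  pop <- simulateNamPopulation(simulateGeneticMap(3, 60, 150, seed = 21),
                               10, 50, 3, seed = 21)
  K <- makeGenomicKernels(pop)
  expect_named(K, c("A", "D", "I"))

  set.seed(31)
  yNull <- stats::setNames(rnorm(length(lineIds(pop))), lineIds(pop))
  ghNull <- genomicHeritability(yNull, kernels = K)
  expect_gte(ghNull$h2Snp, 0)
  expect_lte(ghNull$h2Snp, 1)
  expect_lt(ghNull$h2Snp, 0.1)

  # fully additive feature with heritability 0.5
  X <- dosage(pop)
  set.seed(32)
  gsig <- drop(X[, sample(ncol(X), 40)] %*% rnorm(40))
  yAdd <- gsig + rnorm(length(gsig), 0, sd(gsig))
  names(yAdd) <- lineIds(pop)
  ghAdd <- genomicHeritability(yAdd, kernels = K)
  expect_lt(abs(ghAdd$h2Snp - 0.5), 0.1)
  comp <- varianceComponents(ghAdd$components)
  expect_gt(comp[["sigma2_A"]],
            comp[["sigma2_D"]] + comp[["sigma2_I"]])
})
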