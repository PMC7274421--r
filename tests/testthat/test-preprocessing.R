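test_that("genotype tables round-trip through TSV", {
  pop <- fixturePop()
  d <- dosage(pop)
  d[1, 3] <- NA  # inject a missing call
  g <- GenotypeMatrix(d, families(pop))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(g, path)
  back <- readGenotypeTable(path)
  expect_equal(dosage(back), dosage(g))
  expect_equal(unname(families(back)), unname(families(g)))

  # invalid dosage codes are rejected with row/column named
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("line_id\tfamily\tm1\tm2", "L1\tF1\t0\t3", "L2\tF1\t1\t2"),
             bad)
  expect_error(readGenotypeTable(bad), "L1.*m2|m2.*L1")

  toy <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("line_id\tfamily\tm1\tm2", "L1\tF1\t0\t2", "L2\tF1\t1\tNA",
               "L3\tF2\t2\t0"), toy)
  expect_equal(dim(dosage(readGenotypeTable(toy))), c(3L, 2L))
})

test_that("SNP quality control applies the strict thresholds", {
  # 16 lines, 2 families; markers constructed to probe each rule
  d <- cbind(
    mono   = rep(0, 16),                      # monomorphic everywhere
    hetHi  = c(rep(1, 2), rep(0, 13), 2),     # 2/16 = 12.5% het: removed
    hetOk  = c(1, rep(0, 14), 2),             # 6.25% het: retained
    missHi = c(rep(NA, 2), rep(c(0, 2), 7)),  # 12.5% missing: removed
    missOk = c(NA, rep(c(0, 2), 7), 0),       # 6.25% missing: retained
    good   = rep(c(0, 2), 8))
  rownames(d) <- sprintf("L%02d", 1:16)
  g <- toyGenotypes(d, family = rep(c("A", "B"), each = 8))
  kept <- qcFilterSnps(g)
  expect_identical(markerIds(kept), c("hetOk", "missOk", "good"))
  # idempotent
  expect_identical(dosage(qcFilterSnps(kept)), dosage(kept))
})

test_that("mean imputation fills gaps with column means and nothing else", {
  d <- cbind(a = c(0, 2, NA), b = c(0, 0, NA), c = c(1, 2, 0))
  rownames(d) <- c("L1", "L2", "L3")
  g <- imputeMNI(toyGenotypes(d))
  expect_equal(dosage(g)[3, "a"], 1)
  expect_equal(dosage(g)[3, "b"], 0)
  expect_false(anyNA(dosage(g)))
  expect_equal(dosage(g)[1:2, ], d[1:2, ])  # observed untouched
  expect_equal(colMeans(dosage(g)), colMeans(d, na.rm = TRUE))

  allNA <- cbind(a = c(NA, NA), b = c(0, 1))
  rownames(allNA) <- c("L1", "L2")
  expect_error(imputeMNI(toyGenotypes(allNA)), "a")
})

test_that("family-monomorphic markers are recoded to the recurrent state", {
  d <- cbind(m1 = c(0, 2, 2, 2),   # poly in A, monomorphic 2 in B
             m2 = c(0, 0, 0, 0),   # all recurrent
             m3 = c(0, 2, 0, 2))   # polymorphic in both
  rownames(d) <- sprintf("L%d", 1:4)
  g <- toyGenotypes(d, family = c("A", "A", "B", "B"))
  r <- dosage(monomorphicFamilyRecode(g))
  expect_equal(unname(r[c("L3", "L4"), "m1"]), c(0, 0))
  expect_equal(r[, "m2"], d[, "m2"])
  expect_equal(r[, "m3"], d[, "m3"])
})

test_that("metabolite missingness filter is strict and idempotent", {
  x <- matrix(rexp(100 * 3), 100, 3,
              dimnames = list(sprintf("L%03d", 1:100), c("a", "b", "c")))
  x[1:11, "a"] <- NA  # 11% > 10%: removed
  x[1:10, "b"] <- NA  # exactly 10%: retained
  m <- MetaboliteMatrix(x)
  f <- filterMetabolites(m)
  expect_identical(metaboliteIds(f), c("b", "c"))
  expect_identical(intensities(filterMetabolites(f)), intensities(f))

  imp <- imputeMetaboliteMin(f)
  expect_false(anyNA(intensities(imp)))
  expect_equal(min(intensities(imp)[, "b"]),
               min(x[, "b"], na.rm = TRUE))
  expect_equal(intensities(imp)[, "c"], x[, "c"])  # identity when complete
  colMin <- cbind(a = c(5, NA, 2))
  rownames(colMin) <- c("L1", "L2", "L3")
  expect_equal(intensities(imputeMetaboliteMin(
    MetaboliteMatrix(colMin)))["L2", "a"], 2)
})

test_that("Box-Cox picks lambda by profile likelihood on the grid", {
  set.seed(7)
  x <- exp(rnorm(400, 1, 0.4))
  bc <- boxcoxTransform(x)
  expect_lte(abs(bc$lambda - 0), 0.25)  # within one grid step of log

  # fixed-lambda formula values
  one <- boxcoxTransform(x, lambdaGrid = 1)
  expect_equal(one$transformed, x - 1)
  zero <- boxcoxTransform(x, lambdaGrid = 0)
  expect_equal(zero$transformed, log(x))

  # agrees with the MASS profile-likelihood oracle
  grid <- seq(-2, 2, by = 0.25)
  or <- MASS::boxcox(x ~ 1, data = data.frame(x = x), lambda = grid,
                     plotit = FALSE)
  expect_equal(bcLam <- boxcoxTransform(x, grid)$lambda,
               or$x[which.max(or$y)])

  # invariance to positive rescaling up to one grid step
  expect_lte(abs(boxcoxTransform(3.7 * x, grid)$lambda - bcLam), 0.25)

  # non-positive input handled by shifting
  sh <- boxcoxTransform(c(-1, 0, 1, 2, 5))
  expect_equal(sh$shift, 2)
  expect_error(boxcoxTransform(c(1, NA, 2)), "finite")
})
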