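mockCV <- function(values, h2 = 1, seed = 1L) {
  new("CVResult", abilities = values, rAb = mean(values),
      rAc = mean(values) / sqrt(h2), sd = sd(values / sqrt(h2)),
      h2 = h2, model = "rr_blup", predictorSet = "mock", trait = "T",
      nFolds = 5L, nRuns = length(values), seed = as.integer(seed))
}

test_that("stratified partitions cover every family evenly and reproducibly", {
  fams <- rep(sprintf("F%02d", 1:25), each = 10)
  f <- stratifiedPartition(fams, 5, seed = 3)
  expect_setequal(unique(f), 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k), 50)
    expect_true(all(table(fams[f == k]) == 2))
  }
  expect_identical(stratifiedPartition(fams, 5, seed = 3), f)
  expect_false(identical(stratifiedPartition(fams, 5, seed = 4), f))
  expect_warning(stratifiedPartition(c("A", "A", "A", "B"), 3, seed = 1),
                 "distinct folds")
})

test_that("accuracy scaling divides ability by the square root of heritability", {
  expect_equal(round(predictionAccuracy(0.93, 0.91), 2), 0.97)
  expect_equal(round(predictionAccuracy(0.86, 0.83), 2), 0.94)
  expect_equal(predictionAccuracy(0.4, 1), 0.4)
  expect_gt(predictionAccuracy(0.77, 0.58), 1)  # low h2 can exceed 1
  expect_error(predictionAccuracy(0.5, 0), "undefined")
})

test_that("cross-validation isolates test lines and behaves under the null", {
  pop <- fixturePop()
  X <- dosage(pop)
  ph <- simulatePhenotypes(pop, 30, 0.9, 4, 2, 0.1, seed = 17)
  bl <- computeBlues(ph$phenotypes, h2 = 0.9)
  cv <- runCrossValidation(bl, X, families(pop), "rr_blup", nRuns = 10,
                           seed = 5, lambda = 50)
  expect_length(abilities(cv), 10)
  expect_gt(predictionAbility(cv), 0.5)

  # destroying the genotype-phenotype link kills out-of-sample ability
  set.seed(6)
  yPerm <- stats::setNames(sample(blues(bl)), names(blues(bl)))
  cvNull <- runCrossValidation(yPerm, X, families(pop), "rr_blup",
                               nRuns = 20, seed = 5, lambda = 50)
  expect_lt(abs(predictionAbility(cvNull)), 0.1)

  # no leakage: a fitted model's test predictions cannot depend on test y
  fold <- stratifiedPartition(families(pop), 5, seed = 9)
  train <- fold != 1
  y <- blues(bl)
  fit1 <- fitRrblup(y[train], X[train, ], 50)
  yAltered <- y
  yAltered[!train] <- rev(y[!train]) + 100
  fit2 <- fitRrblup(yAltered[train], X[train, ], 50)
  expect_identical(predictValues(fit1, X[!train, ]),
                   predictValues(fit2, X[!train, ]))

  expect_error(runCrossValidation(y, X, families(pop), nRuns = 7,
                                  nFolds = 5), "multiple")
})

test_that("model comparison t-tests have the expected behaviour", {
  set.seed(11)
  a <- mockCV(rnorm(100, 0.60, 0.03))
  expect_equal(compareModels(a, a)$p.value, 1)
  expect_false(compareModels(a, a)$significant)

  b <- mockCV(rnorm(100, 0.70, 0.03))
  cmp <- compareModels(a, b)
  expect_true(cmp$significant)
  rev <- compareModels(b, a)
  expect_equal(rev$statistic, -cmp$statistic)
  expect_equal(rev$p.value, cmp$p.value)

  const <- mockCV(rep(0.5, 100))
  expect_error(compareModels(const, const), "zero variance")
  expect_error(compareModels(a, mockCV(rnorm(50))), "run counts")
})

test_that("predictor subsets have published sizes and sensible membership", {
  set.seed(2)
  g <- stats::setNames(rnorm(33005), sprintf("s%d", 1:33005))
  eff <- new("MarkerEffects", mu = 0, effects = g, model = "bayes_b",
             coding = "dosage-1", inclusionProb = numeric(),
             pi = NA_real_, sigma2e = NA_real_)
  best <- subsetPredictors(eff, 0.25, "best")
  expect_length(best, 8251)
  expect_true(names(which.max(abs(g))) %in% best)
  expect_length(subsetPredictors(eff, 0.25, "random", seed = 1), 8251)
  expect_setequal(subsetPredictors(eff, 1, "best"), names(g))
  expect_error(subsetPredictors(eff, 1e-6, "best"), "below 1")
})

test_that("reduction experiment reproduces the baseline at fraction 1 and favours best subsets", {
  pop <- fixturePop()
  X <- dosage(pop)
  ph <- simulatePhenotypes(pop, 10, 0.9, 4, 2, 0.1, seed = 23)
  bl <- computeBlues(ph$phenotypes, h2 = 0.9)
  base <- runCrossValidation(bl, X, families(pop), "rr_blup", nRuns = 10,
                             seed = 31, lambda = 50, h2 = 0.9)
  eff <- fitBayesb(bl, X, bayesbPriors(nIter = 2000, burnIn = 500,
                                       thin = 2), seed = 31)
  tab <- reductionExperiment(bl, X, families(pop), "rr_blup",
                             fractions = c(1, 0.1),
                             modes = c("best", "random"), nRuns = 10,
                             seed = 31, lambda = 50, h2 = 0.9,
                             effects = eff)
  full <- tab[tab$fraction == 1 & tab$mode == "best", ]
  expect_equal(full$rAb, predictionAbility(base),
               tolerance = 2 * base@sd / sqrt(10) + 0.02)
  expect_gte(tab$rAc[tab$fraction == 0.1 & tab$mode == "best"],
             tab$rAc[tab$fraction == 0.1 & tab$mode == "random"])
})

test_that("trait-metabolite correlations, effect correlations and distance comparison", {
  set.seed(12)
  n <- 400
  lid <- sprintf("L%03d", 1:n)
  b <- stats::setNames(rnorm(n), lid)
  x <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(lid, sprintf("met%d", 1:30)))
  x[, 1] <- b  # metabolite identical to the trait
  tab <- traitMetaboliteCorrelations(list(T1 = b), MetaboliteMatrix(x))
  expect_equal(tab$r[tab$metabolite == "met1"], 1)
  nullR <- tab$r[tab$metabolite != "met1"]
  expect_gte(mean(abs(nullR) < 3 / sqrt(n)), 0.99)
  expect_error(traitMetaboliteCorrelations(list(T1 = b[1:2]),
                                           MetaboliteMatrix(x)), "shared")

  # effect correlations across traits reflect shared genetic control
  pop <- fixturePop()
  X <- dosage(pop)
  phA <- simulatePhenotypes(pop, 25, 0.9, 2, 2, seed = 41)
  same <- phA$truth@genotypicValues +
    rnorm(nrow(X), 0, 0.3 * sd(phA$truth@genotypicValues))
  phB <- simulatePhenotypes(pop, 25, 0.9, 2, 2, seed = 42)  # disjoint QTL
  eA <- fitRrblup(phA$truth@genotypicValues, X, 20)
  eA2 <- fitRrblup(same, X, 20)
  eB <- fitRrblup(phB$truth@genotypicValues, X, 20)
  cm <- effectCorrelationMatrix(list(a = eA, a2 = eA2, b = eB))
  expect_equal(diag(cm), c(a = 1, a2 = 1, b = 1))
  expect_gt(cm["a", "a2"], 0.8)
  expect_lt(abs(cm["a", "b"]), 0.3)
  badIds <- eB
  names(badIds@effects) <- rev(names(badIds@effects))
  expect_error(effectCorrelationMatrix(list(a = eA, b = badIds)),
               "different predictor sets")

  # distance structure
  self <- distanceMatrixComparison(X, X)
  expect_equal(self$r, 1)
  m1 <- matrix(rnorm(200 * 20), 200, 20,
               dimnames = list(sprintf("L%d", 1:200), NULL))
  m2 <- matrix(rnorm(200 * 20), 200, 20, dimnames = dimnames(m1))
  expect_lt(abs(distanceMatrixComparison(m1, m2)$r), 0.1)
  expect_error(distanceMatrixComparison(m1[1:2, ], m2[1:2, ]), "3 lines")
})
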