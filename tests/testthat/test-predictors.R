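randomInstance <- function(n, m, seed) {
  set.seed(seed)
  X <- matrix(sample(0:2, n * m, TRUE), n, m,
              dimnames = list(sprintf("l%d", 1:n), sprintf("s%d", 1:m)))
  y <- stats::setNames(rnorm(n), rownames(X))
  list(X = X, y = y, lambda = rexp(1) + 0.1)
}

test_that("the plug-in ridge penalty follows its defining ratio", {
  expect_equal(rrblupLambda(1, 1, 1, 1), 1)
  expect_equal(rrblupLambda(2, 4, 100, 8), 25)
  expect_equal(rrblupLambda(2, 4, 200, 8), 2 * rrblupLambda(2, 4, 100, 8))
  expect_error(rrblupLambda(0, 1, 10, 2), "sigma2_G")
})

test_that("RR-BLUP solves the mixed-model equations exactly", {
  # closed-form miniature: y = (1, -1), X = ((1), (-1)), lambda = 1
  e <- fitRrblup(c(a = 1, b = -1),
                 matrix(c(1, -1), 2, dimnames = list(c("a", "b"), "x")), 1)
  expect_equal(intercept(e), 0, tolerance = 1e-12)
  expect_equal(unname(effectsVector(e)), 2 / 3, tolerance = 1e-12)

  # matches the brute-force penalized least-squares oracle
  for (seed in 1:10) {
    inst <- randomInstance(sample(8:25, 1), sample(2:40, 1), seed)
    fit <- fitRrblup(inst$y, inst$X, inst$lambda)
    or <- ridgeOracle(inst$y, inst$X, inst$lambda)
    expect_equal(unname(effectsVector(fit)), unname(or$g),
                 tolerance = 1e-8)
    expect_equal(intercept(fit), or$mu, tolerance = 1e-8)
  }

  # ridge limit: effects shrink to zero, intercept to the mean
  inst <- randomInstance(15, 8, 3)
  lim <- fitRrblup(inst$y, inst$X, 1e12)
  expect_lt(max(abs(effectsVector(lim))), 1e-8)
  expect_equal(intercept(lim), mean(inst$y), tolerance = 1e-6)

  expect_error(fitRrblup(inst$y, inst$X[1:10, ], 1), "match")
  expect_error(fitRrblup(inst$y, inst$X, 0), "lambda")
})

test_that("marker-effect and kernel formulations agree and coding shifts are absorbed", {
  for (seed in 1:8) {
    inst <- randomInstance(20, 35, seed + 100)
    mme <- fitRrblup(inst$y, inst$X, inst$lambda, method = "mme")
    ker <- fitRrblup(inst$y, inst$X, inst$lambda, method = "kernel")
    expect_equal(effectsVector(mme), effectsVector(ker), tolerance = 1e-8)

    # 0/1/2 -> -1/0/1 shift changes nothing about predictions
    shifted <- fitRrblup(inst$y, inst$X - 1, inst$lambda)
    expect_equal(predictValues(mme, inst$X),
                 predictValues(shifted, inst$X - 1), tolerance = 1e-8)
  }
})

test_that("predictions are mu + X g with strict column matching", {
  inst <- randomInstance(12, 6, 9)
  fit <- fitRrblup(inst$y, inst$X, 2)
  expect_equal(predictValues(fit, inst$X),
               drop(intercept(fit) + inst$X %*% effectsVector(fit)))
  # the all-zero profile (recurrent parent) predicts the intercept
  z <- matrix(0, 1, 6, dimnames = list("rp", colnames(inst$X)))
  expect_equal(unname(predictValues(fit, z)), intercept(fit))
  expect_error(predictValues(fit, inst$X[, 1:3]), "absent")

  zero <- fit
  zero@effects[] <- 0
  expect_equal(unname(predictValues(zero, inst$X)),
               rep(zero@mu, nrow(inst$X)))
})

test_that("BayesB sampler is reproducible, finds planted effects and has the right limits", {
  set.seed(3)
  n <- 300; m <- 120
  X <- matrix(sample(0:2, n * m, TRUE, prob = c(.5, .3, .2)), n, m,
              dimnames = list(sprintf("l%d", 1:n), sprintf("s%d", 1:m)))
  g0 <- rep(0, m); g0[1:5] <- c(2, -2, 1.5, -1.5, 1)
  y <- stats::setNames(drop(X %*% g0) + rnorm(n), rownames(X))
  pri <- bayesbPriors(nIter = 3000, burnIn = 1000, thin = 2)

  b1 <- fitBayesb(y, X, pri, seed = 10)
  b2 <- fitBayesb(y, X, pri, seed = 10)
  expect_identical(effectsVector(b1), effectsVector(b2))

  b3 <- fitBayesb(y, X, pri, seed = 99)
  expect_gt(cor(effectsVector(b1), effectsVector(b3)), 0.99)

  # the 5 planted predictors occupy the top inclusion ranks
  rk <- rank(-inclusionProb(b1), ties.method = "min")
  expect_true(all(rk[1:5] <= 5))

  # pi forced to 1: pure spike, intercept-only model
  spike <- fitBayesb(y, X, bayesbPriors(fixPi = 1, nIter = 600,
                                        burnIn = 100), seed = 1)
  expect_true(all(effectsVector(spike) == 0))
  expect_equal(intercept(spike), mean(y), tolerance = 3 * sd(y) / sqrt(n))

  # pi ~ 0 with a rigid slab approaches the ridge solution
  ridgeish <- fitBayesb(y, X, bayesbPriors(fixPi = 0, df0 = 1e8,
                                           scale0 = 1, nIter = 3000,
                                           burnIn = 1000, thin = 2),
                        seed = 5)
  ridge <- fitRrblup(y, X, ridgeish@sigma2e / 1)
  expect_gt(cor(effectsVector(ridgeish), effectsVector(ridge)), 0.98)
})

test_that("predictor blocks combine with tagging and metabolite standardization", {
  set.seed(8)
  Xs <- matrix(sample(0:2, 30 * 10, TRUE), 30, 10,
               dimnames = list(sprintf("l%d", 1:30), sprintf("s%d", 1:10)))
  Xm <- matrix(rexp(30 * 4, rate = 1 / 1000), 30, 4,
               dimnames = list(rownames(Xs), sprintf("met%d", 1:4)))
  comb <- combinePredictors(Xs, Xm)
  expect_equal(ncol(comb), 14)
  expect_identical(colnames(comb),
                   c(paste0("SNP:", colnames(Xs)),
                     paste0("MET:", colnames(Xm))))
  metBlock <- comb[, 11:14]
  expect_equal(unname(colMeans(metBlock)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(metBlock, 2, sd)), rep(1, 4),
               tolerance = 1e-12)

  empty <- combinePredictors(Xs, Xm[, 0])
  expect_equal(unname(empty), unname(Xs))

  expect_error(combinePredictors(Xs, Xm[30:1, ]), "line sets")
})
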