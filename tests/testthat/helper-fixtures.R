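# Shared fixtures, built once per test run and cached.

# Small multi-family population for module tests.
fixturePop <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateNamPopulation(
        simulateGeneticMap(3, 80, 150, seed = 42), 6, 30, 3, seed = 42)
    cache
  }
})

# Full-scale NAM population with phenotypes and metabolites; shared by the
# acceptance blocks so the expensive simulation runs once.
fixtureNam <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      map <- simulateGeneticMap(7, 300, 150, seed = 101)
      pop <- simulateNamPopulation(map, 25, 52, 3, seed = 101)
      ph <- simulatePhenotypes(pop, 100, 0.9, 8, 2, 0.1, seed = 101)
      met <- simulateMetabolites(pop, 60, 0.10, 0.50, 0.05,
                                 traitTruth = ph$truth,
                                 sharedQtlFraction = 0.5, seed = 101)
      cache <<- list(pop = pop, phenotypes = ph$phenotypes,
                     truth = met$truth, metabolites = met$metabolites)
    }
    cache
  }
})

# Brute-force penalized least-squares oracle for RR-BLUP: minimises
# ||y - mu - X g||^2 + lambda ||g||^2 via the augmented normal equations
# with an unpenalised intercept.
ridgeOracle <- function(y, X, lambda) {
  Z <- cbind(1, X)
  P <- diag(c(0, rep(1, ncol(X))))
  coef <- solve(crossprod(Z) + lambda * P, crossprod(Z, y))
  list(mu = coef[1], g = coef[-1])
}

# deterministic toy genotype container
toyGenotypes <- function(d, family = NULL) {
  if (is.null(family)) family <- rep("F1", nrow(d))
  GenotypeMatrix(d, family)
}
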