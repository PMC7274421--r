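// BayesB spike-and-slab Gibbs sampler.
//
// Model: y = mu + X g + e. Each effect g_j is exactly zero with
// probability pi; otherwise g_j ~ N(0, s2g_j) with s2g_j carrying a scaled
// inverse chi-squared prior (df0, S0). pi has a Beta(piA, piB) prior on
// the *exclusion* probability; the residual variance has a scaled inverse
// chi-squared prior (dfE, SE); mu has a flat prior. The residual vector is
// updated in place after every effect update (O(n) per predictor); markers
// are swept in fixed index order. Uses R's RNG, so results are exactly
// reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double rinvchisq(double df, double scale) {
  // scaled inverse chi-squared draw: df*scale / chi2(df)
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".bayesbGibbs")]]
List bayesbGibbs(NumericVector y, NumericMatrix X, double df0, double S0,
                 double piA, double piB, double dfE, double SE,
                 int nIter, int burnIn, int thin, double fixPi) {
  const int n = y.size(), m = X.ncol();
  std::vector<double> g(m, 0.0), s2g(m, S0), xx(m);
  std::vector<int> delta(m, 0);
  for (int j = 0; j < m; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xx[j] = s;
  }
  double mu = mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double vy = var(y);
  double s2e = vy > 0 ? 0.5 * vy : 1.0;
  double pi = R_finite(fixPi) ? fixPi : piA / (piA + piB);

  std::vector<double> gSum(m, 0.0), dSum(m, 0.0);
  double muSum = 0.0, piSum = 0.0, s2eSum = 0.0;
  int nSaved = 0;

  RNGScope scope;
  for (int it = 0; it < nIter; ++it) {
    // intercept (flat prior): normal full conditional
    double se = 0.0;
    for (int i = 0; i < n; ++i) se += e[i];
    double muNew = R::rnorm(mu + se / n, std::sqrt(s2e / n));
    double dmu = mu - muNew;
    for (int i = 0; i < n; ++i) e[i] += dmu;
    mu = muNew;

    int nIn = 0;
    for (int j = 0; j < m; ++j) {
      // per-effect slab variance: posterior draw if in the slab, prior
      // draw otherwise (needed for the next inclusion decision)
      if (delta[j])
        s2g[j] = rinvchisq(df0 + 1.0, (df0 * S0 + g[j] * g[j]) / (df0 + 1.0));
      else
        s2g[j] = rinvchisq(df0, S0);

      const double* xj = &X(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      rhs += xx[j] * g[j];

      double p1;
      if (pi >= 1.0) p1 = 0.0;
      else if (pi <= 0.0) p1 = 1.0;
      else {
        double lam = s2e / s2g[j];
        double C = xx[j] + lam;
        double logBF = 0.5 * std::log(lam / C) +
          rhs * rhs / (2.0 * s2e * C);
        double logOdds = std::log((1.0 - pi) / pi) + logBF;
        p1 = 1.0 / (1.0 + std::exp(-logOdds));
      }
      double gNew = 0.0;
      int dNew = (R::unif_rand() < p1) ? 1 : 0;
      if (dNew) {
        double C = xx[j] + s2e / s2g[j];
        gNew = R::rnorm(rhs / C, std::sqrt(s2e / C));
      }
      if (gNew != g[j]) {
        double diff = g[j] - gNew;
        for (int i = 0; i < n; ++i) e[i] += xj[i] * diff;
      }
      g[j] = gNew;
      delta[j] = dNew;
      nIn += dNew;
    }

    if (!R_finite(fixPi))
      pi = R::rbeta(piA + (m - nIn), piB + nIn);

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (dfE * SE + sse) / R::rchisq(dfE + n);
    if (!R_finite(s2e) || s2e > 1e100)
      stop("residual variance diverged; standardize the predictors");

    if (it >= burnIn && (it - burnIn) % thin == 0) {
      ++nSaved;
      muSum += mu;
      piSum += pi;
      s2eSum += s2e;
      for (int j = 0; j < m; ++j) {
        gSum[j] += g[j];
        dSum[j] += delta[j];
      }
    }
  }
  if (nSaved == 0) stop("no retained sweeps: check nIter/burnIn/thin");

  NumericVector gMean(m), incProb(m);
  for (int j = 0; j < m; ++j) {
    gMean[j] = gSum[j] / nSaved;
    incProb[j] = dSum[j] / nSaved;
  }
  return List::create(_["mu"] = muSum / nSaved, _["g"] = gMean,
                      _["inclusionProb"] = incProb,
                      _["pi"] = piSum / nSaved,
                      _["sigma2e"] = s2eSum / nSaved,
                      _["nSaved"] = nSaved);
}
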