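#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs update of (delta_jk, beta_jk) for every locus j and
// trait k, with beta integrated out of the inclusion draw under its
// conditional prior beta_jk | beta_j,-k ~ N(condCoef_k' beta_j,-k, condVar_k)
// implied by beta_j ~ N(0, G). The residual matrix E (n x t, currently
// including all marker effects) is updated in place, as are beta, delta and
// alpha. Rinv is the inverse residual covariance; when diagR is true only
// its diagonal is used (diagonal-residual SEM sampler).
//
// Inclusion odds: prior odds from the mixture probabilities pi over the 2^t
// combination labels (conditional on the other traits' indicators at locus
// j) times the marginal likelihood ratio with beta_jk integrated out.
//
// E, beta, delta, alpha are modified in place; callers own these matrices.
// [[Rcpp::export]]
void cpp_update_markers(NumericMatrix E, NumericMatrix M, NumericVector xpx,
                        NumericMatrix beta, IntegerMatrix delta,
                        NumericMatrix alpha, NumericMatrix Rinv,
                        NumericVector pi, NumericMatrix condCoef,
                        NumericVector condVar, bool diagR) {
  const int n = E.nrow(), t = E.ncol(), p = M.ncol();
  for (int j = 0; j < p; ++j) {
    const double* x = &M(0, j);
    for (int k = 0; k < t; ++k) {
      // conditional prior of beta_jk given beta_j,-k
      double muCond = 0.0;
      for (int k2 = 0; k2 < t; ++k2)
        if (k2 != k) muCond += condCoef(k, k2) * beta(j, k2);
      const double vCond = condVar[k];
      const double aOld = alpha(j, k);
      // rhs = x' (E + x aOld e_k') Rinv e_k ; lhs = x'x Rinv_kk
      double rhs = 0.0;
      if (diagR) {
        const double* ek = &E(0, k);
        double dot = 0.0;
        for (int i = 0; i < n; ++i) dot += x[i] * ek[i];
        rhs = dot * Rinv(k, k);
      } else {
        for (int k2 = 0; k2 < t; ++k2) {
          const double rk = Rinv(k2, k);
          if (rk == 0.0) continue;
          const double* e2 = &E(0, k2);
          double dot = 0.0;
          for (int i = 0; i < n; ++i) dot += x[i] * e2[i];
          rhs += rk * dot;
        }
      }
      rhs += xpx[j] * aOld * Rinv(k, k);
      const double lhs = xpx[j] * Rinv(k, k);
      const double vPost = 1.0 / (lhs + 1.0 / vCond);
      const double muPost = vPost * (rhs + muCond / vCond);
      const double logBF = 0.5 * std::log(vPost / vCond) +
        0.5 * (muPost * muPost / vPost - muCond * muCond / vCond);
      // label indices with delta_jk set to 1 resp. 0 (all-zero label first)
      int base = 0;
      for (int k2 = 0; k2 < t; ++k2)
        if (k2 != k && delta(j, k2) == 1) base += (1 << k2);
      const double pi1 = pi[base + (1 << k)], pi0 = pi[base];
      double p1;
      if (pi1 <= 0.0 && pi0 <= 0.0) p1 = 0.5;
      else if (pi1 <= 0.0) p1 = 0.0;
      else if (pi0 <= 0.0) p1 = 1.0;
      else {
        const double logOdds = std::log(pi1) - std::log(pi0) + logBF;
        p1 = 1.0 / (1.0 + std::exp(-logOdds));
      }
      const double u = R::unif_rand();
      double bNew, aNew;
      int dNew;
      if (u < p1) {
        dNew = 1;
        bNew = muPost + std::sqrt(vPost) * R::norm_rand();
        aNew = bNew;
      } else {
        dNew = 0;
        bNew = muCond + std::sqrt(vCond) * R::norm_rand();
        aNew = 0.0;
      }
      const double diff = aNew - aOld;
      if (diff != 0.0) {
        double* ek = &E(0, k);
        for (int i = 0; i < n; ++i) ek[i] -= x[i] * diff;
      }
      beta(j, k) = bNew;
      delta(j, k) = dNew;
      alpha(j, k) = aNew;
    }
  }
}

// Window variance proportions for one MCMC sample. For each effect type
// (direct, indirect, overall), trait and window: a_w = M_w alpha_w,
// sigma2_w = mean(a_w^2) - mean(a_w)^2 (population variance), and
// q_w = sigma2_w / sigma2_a where sigma2_a is the population variance of
// the genetic values of the OVERALL effects of all markers.
// first/last are 1-based inclusive marker indices per window.
// Returns an nwin x t x 3 array (effect order: direct, indirect, overall).
// [[Rcpp::export]]
NumericVector cpp_window_q(NumericMatrix M, NumericMatrix direct,
                           NumericMatrix indirect, NumericMatrix overall,
                           IntegerVector first, IntegerVector last) {
  const int n = M.nrow(), t = direct.ncol(), nwin = first.size();
  NumericVector out(Dimension(nwin, t, 3));
  std::vector<double> aw(n), atot(n);
  const NumericMatrix* effs[3] = { &direct, &indirect, &overall };
  for (int k = 0; k < t; ++k) {
    // total genetic values from overall effects of all markers
    std::fill(atot.begin(), atot.end(), 0.0);
    for (int j = 0; j < M.ncol(); ++j) {
      const double a = overall(j, k);
      if (a == 0.0) continue;
      const double* x = &M(0, j);
      for (int i = 0; i < n; ++i) atot[i] += x[i] * a;
    }
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += atot[i]; s2 += atot[i] * atot[i]; }
    const double sig2a = s2 / n - (s / n) * (s / n);
    for (int e = 0; e < 3; ++e) {
      const NumericMatrix& eff = *effs[e];
      for (int w = 0; w < nwin; ++w) {
        std::fill(aw.begin(), aw.end(), 0.0);
        for (int j = first[w] - 1; j <= last[w] - 1; ++j) {
          const double a = eff(j, k);
          if (a == 0.0) continue;
          const double* x = &M(0, j);
          for (int i = 0; i < n; ++i) aw[i] += x[i] * a;
        }
        double sw = 0.0, sw2 = 0.0;
        for (int i = 0; i < n; ++i) { sw += aw[i]; sw2 += aw[i] * aw[i]; }
        const double sig2w = sw2 / n - (sw / n) * (sw / n);
        out[w + nwin * (k + t * e)] = (sig2a > 0.0) ? sig2w / sig2a : 0.0;
      }
    }
  }
  return out;
}
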