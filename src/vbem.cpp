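// Variational Bayes EM inner loop for the two-haplotype mixture model.
// Entries must be grouped by fragment and sorted by site within fragment
// (the fragment_set constructor guarantees this).  Mirrors the R reference
// implementation in R/vbem.R; the two are cross-checked in the test suite.
//
// Per entry, the E-step scores depend only on (site, allele), so all
// transcendental work is done once per site x allele value and the entry
// loop reduces to table lookups.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double lse2(double a, double b) {
  if (a == R_NegInf && b == R_NegInf) return R_NegInf;
  double m = a > b ? a : b;
  return m + log1p(std::exp((a > b ? b : a) - m));
}

// [[Rcpp::export]]
List vbem_run_cpp(IntegerVector frag, IntegerVector site, IntegerVector allele,
                  int n_frag, int n_sites, NumericMatrix lam_init,
                  NumericMatrix lam0, double alpha, double tol, int max_iter) {
  const int T = frag.size();
  std::vector<double> lam1(n_sites), lam2(n_sites);
  for (int j = 0; j < n_sites; ++j) {
    lam1[j] = lam_init(j, 0);
    lam2[j] = lam_init(j, 1);
  }
  // offsets of each fragment's entry range (frag is 1-based and contiguous)
  std::vector<int> off(n_frag + 1, 0);
  for (int t = 0; t < T; ++t) off[frag[t]]++;
  for (int i = 0; i < n_frag; ++i) off[i + 1] += off[i];
  // per-entry key: 2 * (site - 1) + allele
  std::vector<int> key(T);
  for (int t = 0; t < T; ++t) key[t] = 2 * (site[t] - 1) + allele[t];

  const double l_match = std::log(1.0 - alpha), l_mis = std::log(alpha);
  const double lhalf = std::log(0.5);
  // per (site, allele) tables: log sum_nu beta for each origin h, and the
  // within-site responsibility of phase (0,1)
  std::vector<double> S0(2 * n_sites), S1(2 * n_sites);
  std::vector<double> R0(2 * n_sites), R1(2 * n_sites);
  NumericVector q0v(n_frag), q1v(n_frag);
  std::vector<double> elbo_trace;

  for (int it = 0; it < max_iter; ++it) {
    for (int j = 0; j < n_sites; ++j) {
      double ds = R::digamma(lam1[j] + lam2[j]);
      double el1 = R::digamma(lam1[j]) - ds;
      double el2 = R::digamma(lam2[j]) - ds;
      for (int a = 0; a < 2; ++a) {
        double lpa0 = (a == 0) ? l_match : l_mis;  // log pe(a | true 0)
        double lpa1 = (a == 1) ? l_match : l_mis;
        double b01 = lpa0 + el1, b02 = lpa1 + el2;  // h = 0
        double b11 = lpa1 + el1, b12 = lpa0 + el2;  // h = 1
        int k = 2 * j + a;
        S0[k] = lse2(b01, b02);
        S1[k] = lse2(b11, b12);
        R0[k] = std::exp(b01 - S0[k]);
        R1[k] = std::exp(b11 - S1[k]);
      }
    }
    // E-step: fragment-origin posteriors and the ELBO data term
    double elbo = 0.0;
    for (int i = 0; i < n_frag; ++i) {
      double acc0 = 0.0, acc1 = 0.0;
      for (int t = off[i]; t < off[i + 1]; ++t) {
        acc0 += S0[key[t]];
        acc1 += S1[key[t]];
      }
      double lq0 = lhalf + acc0, lq1 = lhalf + acc1;
      double lz = lse2(lq0, lq1);
      q0v[i] = std::exp(lq0 - lz);
      q1v[i] = std::exp(lq1 - lz);
      elbo += lz;
    }
    // minus KL(Dir(lam) || Dir(lam0)) for the state used in this E-step
    for (int j = 0; j < n_sites; ++j) {
      double s = lam1[j] + lam2[j];
      double p1 = lam0(j, 0), p2 = lam0(j, 1), sp = p1 + p2;
      double dgs = R::digamma(s);
      elbo -= R::lgammafn(s) - R::lgammafn(sp)
            - (R::lgammafn(lam1[j]) - R::lgammafn(p1))
            - (R::lgammafn(lam2[j]) - R::lgammafn(p2))
            + (lam1[j] - p1) * (R::digamma(lam1[j]) - dgs)
            + (lam2[j] - p2) * (R::digamma(lam2[j]) - dgs);
    }
    elbo_trace.push_back(elbo);
    // M-step: conjugate Dirichlet update
    for (int j = 0; j < n_sites; ++j) {
      lam1[j] = lam0(j, 0);
      lam2[j] = lam0(j, 1);
    }
    for (int i = 0; i < n_frag; ++i) {
      for (int t = off[i]; t < off[i + 1]; ++t) {
        int k = key[t];
        double n1 = q0v[i] * R0[k] + q1v[i] * R1[k];  // mass on nu = (0,1)
        int j = k >> 1;
        lam1[j] += n1;
        lam2[j] += 1.0 - n1;
      }
    }
    int n = elbo_trace.size();
    if (n > 1 && std::fabs(elbo_trace[n - 1] - elbo_trace[n - 2]) < tol) break;
  }

  NumericMatrix lam_out(n_sites, 2);
  for (int j = 0; j < n_sites; ++j) {
    lam_out(j, 0) = lam1[j];
    lam_out(j, 1) = lam2[j];
  }
  NumericMatrix q(n_frag, 2);
  for (int i = 0; i < n_frag; ++i) {
    q(i, 0) = q0v[i];
    q(i, 1) = q1v[i];
  }
  return List::create(_["lam"] = lam_out, _["q"] = q,
                      _["elbo"] = NumericVector(elbo_trace.begin(), elbo_trace.end()),
                      _["n_iter"] = (int) elbo_trace.size());
}
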