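#include <Rcpp.h>
using namespace Rcpp;

// Conditional-Gaussian filter likelihood for the quadratic-hazard
// stochastic process model on the integer-year age grid, with optional
// exact gradient via forward sensitivities of the filter recursion.
// Mirrors the R reference implementation in likelihood.R; the R engine
// is the readable definition, this is the hot loop used by the fitter.
//
// theta layout: 0 a_Y, 1 b_Y, 2 sigma1, 3 sigma0, 4 a_Q, 5 b_Q,
//               6 a_mu0, 7 b_mu0, 8 a_f0d, 9 b_f0d.
// f0 is a raw cubic in age, lowest degree first (fixed, no gradient).
// [[Rcpp::export]]
List spm_cohort_loglik_cpp(IntegerVector entry, IntegerVector tend,
                           IntegerVector death, IntegerVector exam_ptr,
                           IntegerVector exam_age, NumericVector exam_val,
                           NumericVector theta, NumericVector f0c,
                           bool grad = false) {
  const double a_Y = theta[0], b_Y = theta[1];
  const double sigma1 = theta[2], sigma0 = theta[3];
  const double a_Q = theta[4], b_Q = theta[5];
  const double a_mu0 = theta[6], b_mu0 = theta[7];
  const double a_f0d = theta[8], b_f0d = theta[9];
  const double s1sq = sigma1 * sigma1;
  const double log2pi = 1.8378770664093454836;
  const int P = 10;

  const int n = entry.size();
  double ll = 0.0;
  std::vector<double> dll(P, 0.0), dm(P), dg(P);
  int n_obs = 0, n_death = 0;

  for (int j = 0; j < n; ++j) {
    int t = entry[j];
    const int T = tend[j];
    int i = exam_ptr[j];
    const int iend = exam_ptr[j + 1];
    double m = 0.0, g = 0.0;
    bool first = true;
    if (grad) std::fill(dm.begin(), dm.end(), 0.0),
              std::fill(dg.begin(), dg.end(), 0.0);

    while (true) {
      const double td = (double)t;
      const double f0 = f0c[0] + td * (f0c[1] + td * (f0c[2] + td * f0c[3]));
      // observation at this age?
      if (i < iend && exam_age[i] == t) {
        const double y = exam_val[i];
        if (first) {
          const double v = sigma0 * sigma0;
          const double r = y - (f0 + a_f0d + b_f0d * td);
          ll += -0.5 * (log2pi + std::log(v) + r * r / v);
          if (grad) {
            dll[3] += (-1.0 / v + r * r / (v * v)) * sigma0;
            dll[8] += r / v;
            dll[9] += r / v * td;
          }
          first = false;
        } else {
          if (g <= 0.0)
            stop("data-alignment error: repeated observation at age %d", t);
          const double r = y - m;
          ll += -0.5 * (log2pi + std::log(g) + r * r / g);
          if (grad) {
            const double d_dm = r / g;                         // dterm/dm
            const double d_dg = -0.5 / g + 0.5 * r * r / (g * g);
            for (int k = 0; k < P; ++k)
              dll[k] += d_dm * dm[k] + d_dg * dg[k];
          }
        }
        m = y; g = 0.0;
        if (grad) std::fill(dm.begin(), dm.end(), 0.0),
                  std::fill(dg.begin(), dg.end(), 0.0);
        ++n_obs; ++i;
      }
      const double Q = a_Q + b_Q * td;
      const double emu = std::exp(b_mu0 * td);
      const double mu0 = a_mu0 * emu;
      if (Q < 0.0) stop("Q(t) < 0 at age %d", t);
      if (mu0 < 0.0) stop("mu0(t) < 0 at age %d", t);
      const double k = 1.0 + 2.0 * Q * g;
      if (k <= 0.0) stop("constraint violation: 1 + 2*Q*gamma <= 0 at age %d", t);
      const double dev = m - f0;
      // one-year survival factor under the current belief
      const double logprob = -mu0 - 0.5 * std::log(k) - Q * dev * dev / k;
      // partials of logprob wrt (mu0, Q, m, g); chain through theta below
      double dlp[10];
      if (grad) {
        const double dlp_dQ = -g / k - dev * dev / (k * k);
        const double dlp_dm = -2.0 * Q * dev / k;
        const double dlp_dg = -Q / k + 2.0 * Q * Q * dev * dev / (k * k);
        for (int kk = 0; kk < P; ++kk)
          dlp[kk] = dlp_dm * dm[kk] + dlp_dg * dg[kk];
        dlp[4] += dlp_dQ;
        dlp[5] += dlp_dQ * td;
        dlp[6] += -emu;
        dlp[7] += -mu0 * td;
      }
      if (t == T) {
        if (death[j] == 1) {
          const double pr = std::exp(logprob);
          ll += std::log1p(-pr);
          if (grad) {
            const double w = -pr / (1.0 - pr);
            for (int kk = 0; kk < P; ++kk) dll[kk] += w * dlp[kk];
          }
          ++n_death;
        }
        break;
      }
      ll += logprob;
      // selection update, then one-year dynamics step
      const double ms = f0 + dev / k;
      const double gs = g / k;
      const double a = a_Y + b_Y * td;
      const double f1 = f0 + a_f0d + b_f0d * td;
      m = ms + a * (ms - f1);
      g = (1.0 + a) * (1.0 + a) * gs + s1sq;
      if (grad) {
        // survival-term gradient, then sensitivities of the selection
        // update (ms, gs) and the propagated (m, g); g_old = gs * k is
        // the pre-update variance
        const double g_old = gs * k;
        for (int kk = 0; kk < P; ++kk) {
          dll[kk] += dlp[kk];
          double dQk = 0.0;
          if (kk == 4) dQk = 1.0;
          else if (kk == 5) dQk = td;
          const double dk_dtheta = 2.0 * (Q * dg[kk] + g_old * dQk);
          const double dms = dm[kk] / k - (dev / (k * k)) * dk_dtheta;
          const double dgs = dg[kk] / k - (g_old / (k * k)) * dk_dtheta;
          double da = 0.0;
          if (kk == 0) da = 1.0;
          else if (kk == 1) da = td;
          double df1 = 0.0;
          if (kk == 8) df1 = 1.0;
          else if (kk == 9) df1 = td;
          dm[kk] = (1.0 + a) * dms + (ms - f1) * da - a * df1;
          dg[kk] = (1.0 + a) * (1.0 + a) * dgs + 2.0 * (1.0 + a) * gs * da;
          if (kk == 2) dg[kk] += 2.0 * sigma1;
        }
      }
      ++t;
    }
  }
  List out = List::create(_["loglik"] = ll,
                          _["n_death_terms"] = n_death,
                          _["n_observation_terms"] = n_obs);
  if (grad) out["gradient"] = NumericVector(dll.begin(), dll.end());
  return out;
}
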