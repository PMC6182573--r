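#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Euler-Maruyama integration of a network of delayed stochastic Jansen-Rit
// neural masses. Six states per ROI; inter-ROI coupling C_{y->x} * y1(t - tau)
// enters the excitatory interneuron velocity equation (x5). The Wiener
// increment, scaled by A*a*sigma_w*sqrt(dt), perturbs x5 only.
//
// Returns the local potential x2 - x3 at every integration step, laid out as
// a vector indexed [step, roi, trial] (step fastest).
//
// `strict_printed` switches the leak term of the inhibitory velocity (x6)
// from the standard -b^2*x3 to -a^2*x3; see the R-level documentation.
// [[Rcpp::export]]
NumericVector nmm_integrate_cpp(int n_roi, int n_trials, int n_steps,
                                IntegerVector edge_src, IntegerVector edge_dst,
                                NumericVector edge_C, IntegerVector edge_delay,
                                NumericVector par, NumericVector I_mean,
                                double sigma_w, double dt, bool strict_printed) {
  const double A  = par["A"],  a  = par["a"], B = par["B"], b = par["b"];
  const double e0 = par["e0"], v0 = par["v0"], rho = par["rho"];
  const double C1 = par["C1"], C2 = par["C2"], C3 = par["C3"], C4 = par["C4"];
  const double x3coef = strict_printed ? a * a : b * b;
  const double sqdt = std::sqrt(dt);
  const double noise_amp = A * a * sigma_w * sqdt;

  const int n_edges = edge_src.size();
  int max_delay = 0;
  for (int e = 0; e < n_edges; ++e)
    if (edge_delay[e] > max_delay) max_delay = edge_delay[e];
  const int cap = max_delay + 1;

  // group inbound edges by destination ROI
  std::vector< std::vector<int> > inbound(n_roi);
  for (int e = 0; e < n_edges; ++e) inbound[edge_dst[e]].push_back(e);

  NumericVector out((R_xlen_t)n_steps * n_roi * n_trials);
  std::vector<double> x(6 * n_roi), d(6 * n_roi);
  std::vector<double> hist((size_t)cap * n_roi);

  auto S = [&](double v) { return 2.0 * e0 / (1.0 + std::exp(-rho * (v - v0))); };

  for (int tr = 0; tr < n_trials; ++tr) {
    std::fill(x.begin(), x.end(), 0.0);
    std::fill(hist.begin(), hist.end(), 0.0); // initial-state-valued history
    int pos = 0;
    R_xlen_t base_tr = (R_xlen_t)n_steps * n_roi * tr;
    for (int k = 0; k < n_steps; ++k) {
      // record x1(t) so delayed lookups see the pre-update state
      for (int r = 0; r < n_roi; ++r) hist[(size_t)pos * n_roi + r] = x[6 * r];
      for (int r = 0; r < n_roi; ++r) {
        const double x1 = x[6 * r], x2 = x[6 * r + 1], x3 = x[6 * r + 2];
        const double x4 = x[6 * r + 3], x5 = x[6 * r + 4], x6 = x[6 * r + 5];
        double coup = I_mean[r];
        for (size_t j = 0; j < inbound[r].size(); ++j) {
          const int e = inbound[r][j];
          const int lag = (pos - edge_delay[e] + cap) % cap;
          coup += edge_C[e] * hist[(size_t)lag * n_roi + edge_src[e]];
        }
        d[6 * r]     = x4;
        d[6 * r + 1] = x5;
        d[6 * r + 2] = x6;
        d[6 * r + 3] = A * a * S(x2 - x3) - 2.0 * a * x4 - a * a * x1;
        d[6 * r + 4] = A * a * (coup + C2 * S(C1 * x1)) - 2.0 * a * x5 - a * a * x2;
        d[6 * r + 5] = B * b * (C4 * S(C3 * x1)) - 2.0 * b * x6 - x3coef * x3;
      }
      for (int r = 0; r < n_roi; ++r) {
        for (int s = 0; s < 6; ++s) x[6 * r + s] += d[6 * r + s] * dt;
        if (sigma_w > 0.0) x[6 * r + 4] += noise_amp * R::norm_rand();
        const double pot = x[6 * r + 1] - x[6 * r + 2];
        if (!std::isfinite(pot) || std::fabs(pot) > 1e6)
          stop("neural-mass integration diverged at step %d (|x2-x3| > 1e6); use a smaller dt", k + 1);
        out[base_tr + (R_xlen_t)n_steps * r + k] = pot;
      }
      pos = (pos + 1) % cap;
    }
  }
  return out;
}
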