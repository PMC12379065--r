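#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integrator for the Hill regulatory circuit.
//
// Drift for node i:  basal[i] - deg[i] * x[i] + sum over incoming edges e:
//   activating:  b_e * x_src^n / (K^n + x_src^n)
//   inhibiting:  b_e * K^n / (K^n + x_src^n)
// Additive noise of strength sigma on every node (same sigma, per-node
// scaling handled by the caller if needed).
//
// Uses R's RNG (rnorm), so results are reproducible under set.seed().

static inline double hill_act(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  double xn = (n == 2.0) ? x * x : std::pow(x, n);
  double Kn = (n == 2.0) ? K * K : std::pow(K, n);
  return xn / (Kn + xn);
}

static void drift(const NumericVector& x, const NumericVector& basal,
                  const NumericVector& deg, const IntegerVector& esrc,
                  const IntegerVector& etgt, const NumericVector& eb,
                  const NumericVector& eK, const NumericVector& en,
                  const IntegerVector& esign, NumericVector& out) {
  int G = x.size();
  for (int i = 0; i < G; ++i) out[i] = basal[i] - deg[i] * x[i];
  int E = esrc.size();
  for (int e = 0; e < E; ++e) {
    double h = hill_act(x[esrc[e]], eK[e], en[e]);
    out[etgt[e]] += eb[e] * (esign[e] > 0 ? h : 1.0 - h);
  }
}

// [[Rcpp::export(name = ".em_simulate")]]
NumericMatrix em_simulate(NumericVector x0, NumericVector basal,
                          NumericVector deg, IntegerVector esrc,
                          IntegerVector etgt, NumericVector eb,
                          NumericVector eK, NumericVector en,
                          IntegerVector esign, double dt, double sigma,
                          int n_burn, int n_cells, int n_interval,
                          bool restart, double state_cap) {
  int G = x0.size();
  NumericMatrix out(G, n_cells);
  NumericVector x = clone(x0), d(G);
  double sq = sigma * std::sqrt(dt);
  bool burned = false;
  for (int c = 0; c < n_cells; ++c) {
    if (restart) { x = clone(x0); burned = false; }
    int nstep = burned ? n_interval : n_burn;
    for (int i = 0; i < nstep; ++i) {
      drift(x, basal, deg, esrc, etgt, eb, eK, en, esign, d);
      for (int g = 0; g < G; ++g) {
        x[g] += d[g] * dt + sq * norm_rand();
        if (!R_finite(x[g]) || std::fabs(x[g]) > state_cap)
          stop("simulation instability: state exceeded cap %g (dt = %g, sigma = %g)",
               state_cap, dt, sigma);
      }
    }
    burned = true;
    for (int g = 0; g < G; ++g) out(g, c) = x[g] > 0.0 ? x[g] : 0.0;
  }
  return out;
}
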