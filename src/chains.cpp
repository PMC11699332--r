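#include <Rcpp.h>
using namespace Rcpp;

// Sample n_steps states following `start` from a discrete Markov chain.
// cumP is the row-wise cumulative transition matrix; states are 1-based.
// Uses R's RNG so results are controlled by set.seed() on the R side.
// [[Rcpp::export]]
IntegerVector cpp_sample_chain(NumericMatrix cumP, int start, int n_steps) {
  const int n = cumP.nrow();
  if (start < 1 || start > n) stop("start state out of range");
  IntegerVector out(n_steps);
  int s = start - 1;
  for (int t = 0; t < n_steps; ++t) {
    const double u = R::unif_rand();
    int j = 0;
    while (j < n - 1 && u > cumP(s, j)) ++j;
    s = j;
    out[t] = s + 1;
  }
  return out;
}

// Monte-Carlo committor estimate: for every state, launch n_walkers
// independent chains and record the fraction that enter U before B.
// Boundary states return their fixed values (0 on B, 1 on U).
// Walkers exceeding max_steps are counted in the third return column.
// [[Rcpp::export]]
NumericMatrix cpp_mc_committor(NumericMatrix cumP, LogicalVector in_b,
                               LogicalVector in_u, int n_walkers,
                               int max_steps) {
  const int n = cumP.nrow();
  NumericMatrix res(n, 2); // col 0: q estimate, col 1: unfinished fraction
  for (int i = 0; i < n; ++i) {
    if (in_b[i]) { res(i, 0) = 0.0; continue; }
    if (in_u[i]) { res(i, 0) = 1.0; continue; }
    int hits = 0, lost = 0;
    for (int w = 0; w < n_walkers; ++w) {
      int s = i;
      int t = 0;
      for (; t < max_steps; ++t) {
        const double u = R::unif_rand();
        int j = 0;
        while (j < n - 1 && u > cumP(s, j)) ++j;
        s = j;
        if (in_u[s]) { ++hits; break; }
        if (in_b[s]) { break; }
      }
      if (t == max_steps) ++lost;
    }
    res(i, 0) = static_cast<double>(hits) / n_walkers;
    res(i, 1) = static_cast<double>(lost) / n_walkers;
  }
  return res;
}

// Overdamped Euler-Maruyama dynamics in a 2-D radial funnel potential:
//   U(r, theta) = Eb * g(r) * (1 - contrast * cos(n_channels * theta))
//                 + 0.5 * wall_k * max(0, r - wall_r)^2
// with g(r) = (r/rb)^2 * exp(1 - (r/rb)^2): a well at the origin, a
// barrier ridge of height Eb at r = rb modulated by angular channels,
// and a soft confining wall at wall_r. Energies are in units where
// kT = 1 at reference temperature; drift is -(D/kT) grad U.
// Returns the n_steps positions following `start` (start not included).
// [[Rcpp::export]]
NumericMatrix cpp_langevin_funnel(NumericVector start, int n_steps,
                                  double dt, double kT, double D,
                                  double Eb, double rb, int n_channels,
                                  double contrast, double wall_r,
                                  double wall_k) {
  NumericMatrix out(n_steps, 2);
  double x = start[0], y = start[1];
  // D is the mobility (= diffusion coefficient at reference kT = 1);
  // Einstein relation with fixed mobility: diffusion = D * kT, so the
  // kT -> 0 limit is noiseless with finite drift.
  const double noise = std::sqrt(2.0 * D * kT * dt);
  const double mob = D;
  for (int t = 0; t < n_steps; ++t) {
    const double r2 = x * x + y * y;
    const double r = std::sqrt(r2);
    double fx = 0.0, fy = 0.0;
    if (r > 1e-12) {
      const double u = r2 / (rb * rb);
      const double eu = std::exp(1.0 - u);
      const double th = std::atan2(y, x);
      const double m = 1.0 - contrast * std::cos(n_channels * th);
      // dU/dr and dU/dtheta
      double dur = Eb * (2.0 * r / (rb * rb)) * eu * (1.0 - u) * m;
      if (r > wall_r) dur += wall_k * (r - wall_r);
      const double dut =
          Eb * u * eu * contrast * n_channels * std::sin(n_channels * th);
      fx = -(dur * x / r - dut * y / r2);
      fy = -(dur * y / r + dut * x / r2);
    }
    if (!std::isfinite(fx) || !std::isfinite(fy))
      stop("non-finite force at step %d", t + 1);
    x += mob * fx * dt + noise * R::norm_rand();
    y += mob * fy * dt + noise * R::norm_rand();
    out(t, 0) = x;
    out(t, 1) = y;
  }
  return out;
}
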