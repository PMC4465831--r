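#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) on a piecewise-linear 1D free-energy
// surface G(x) plus a harmonic bias k*(x - center)^2.  Positions are reflected
// at the grid edges.  Uses R's RNG so set.seed() governs reproducibility.
//
// grid, values : piecewise-linear reference profile (grid strictly increasing)
// x0           : starting position
// n_steps      : number of integration steps
// save_stride  : keep every save_stride-th position
// D, dt, kT    : diffusion coefficient (A^2/ps), timestep (ps), k_B*T (kcal/mol)
// [[Rcpp::export]]
NumericVector bd_trajectory(NumericVector grid, NumericVector values,
                            double center, double kbias,
                            double x0, double n_steps_d, int save_stride,
                            double D, double dt, double kT) {
  const int n_seg = grid.size() - 1;
  std::vector<double> slope(n_seg);
  for (int s = 0; s < n_seg; ++s)
    slope[s] = (values[s + 1] - values[s]) / (grid[s + 1] - grid[s]);

  const double lo = grid[0], hi = grid[n_seg];
  const double amp = std::sqrt(2.0 * D * dt);
  const double mob = D * dt / kT;
  const long long n_steps = (long long) n_steps_d;
  const long long n_save = n_steps / save_stride;
  NumericVector out(n_save);

  double x = std::min(std::max(x0, lo), hi);
  int seg = std::upper_bound(grid.begin(), grid.end(), x) - grid.begin() - 1;
  if (seg < 0) seg = 0;
  if (seg >= n_seg) seg = n_seg - 1;

  long long isave = 0;
  for (long long step = 1; step <= n_steps; ++step) {
    double grad = slope[seg] + 2.0 * kbias * (x - center);
    x += -mob * grad + amp * norm_rand();
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
    if (x < lo) x = lo;  // pathological double reflection
    // update segment index (walker moves < 1 segment per step in practice,
    // but search locally to stay exact)
    while (seg > 0 && x < grid[seg]) --seg;
    while (seg < n_seg - 1 && x >= grid[seg + 1]) ++seg;
    if (step % save_stride == 0 && isave < n_save) out[isave++] = x;
  }
  return out;
}
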