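#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Random-walk diffusion inside an impermeable cylinder (axis = z, radius
// r), with specular reflection at the boundary and free motion along the
// axis. Phase is accumulated for K gradient waveforms simultaneously
// (the trajectories do not depend on the gradient), using the midpoint
// of each step. Gradients are effective (refocusing sign flips already
// applied); gamma_um converts (mT/m * ms * um) to radians.

static const double GAMMA_UM = 2.6751525e-4;

// Reflect a proposed in-plane step off the circular boundary, recursing
// on the remaining sub-step (preserves the uniform equilibrium
// distribution). x, y: current position (inside); dx, dy: proposed step.
static inline void reflect_step(double r2, double &x, double &y,
                                double dx, double dy) {
  for (int iter = 0; iter < 16; ++iter) {
    double nx = x + dx, ny = y + dy;
    if (nx * nx + ny * ny <= r2) { x = nx; y = ny; return; }
    // solve |p + t d|^2 = r^2 for t in (0, 1]
    double a = dx * dx + dy * dy;
    double bq = 2.0 * (x * dx + y * dy);
    double c = x * x + y * y - r2;
    double disc = bq * bq - 4.0 * a * c;
    if (disc < 0.0 || a == 0.0) return; // numerical guard: stay put
    double t = (-bq + std::sqrt(disc)) / (2.0 * a);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double hx = x + t * dx, hy = y + t * dy;
    double hn = std::sqrt(hx * hx + hy * hy);
    if (hn == 0.0) return;
    double ux = hx / hn, uy = hy / hn;       // outward normal
    double rx = (1.0 - t) * dx, ry = (1.0 - t) * dy;
    double dot = rx * ux + ry * uy;
    dx = rx - 2.0 * dot * ux;
    dy = ry - 2.0 * dot * uy;
    // nudge just inside to avoid boundary sticking
    x = hx * (1.0 - 1e-12);
    y = hy * (1.0 - 1e-12);
  }
}

// [[Rcpp::export(name = ".walk_cylinder_cpp")]]
List walk_cylinder_cpp(double r, double D0, int n_walkers, double dt,
                       NumericMatrix Gx, NumericMatrix Gy, NumericMatrix Gz,
                       int n_checkpoints = 8) {
  const int n_steps = Gx.nrow();
  const int K = Gx.ncol();
  const double r2 = r * r;
  const double sigma = std::sqrt(2.0 * D0 * dt);

  std::vector<double> sum_cos(K, 0.0), sum_sin(K, 0.0);
  std::vector<double> sum_cos2(K, 0.0), sum_sin2(K, 0.0), sum_cs(K, 0.0);
  std::vector<double> phi(K);
  std::vector<int> cp_steps(n_checkpoints);
  for (int c = 0; c < n_checkpoints; ++c)
    cp_steps[c] = (int)std::floor((double)(c + 1) * n_steps / n_checkpoints) - 1;
  std::vector<double> msd_z(n_checkpoints, 0.0);

  RNGScope scope;
  for (int w = 0; w < n_walkers; ++w) {
    // uniform start in the disc (rejection), z = 0
    double x, y;
    do {
      x = (2.0 * unif_rand() - 1.0) * r;
      y = (2.0 * unif_rand() - 1.0) * r;
    } while (x * x + y * y > r2);
    double z = 0.0;
    std::fill(phi.begin(), phi.end(), 0.0);
    int cp = 0;
    for (int s = 0; s < n_steps; ++s) {
      double ox = x, oy = y, oz = z;
      double dx = sigma * norm_rand();
      double dy = sigma * norm_rand();
      double dz = sigma * norm_rand();
      reflect_step(r2, x, y, dx, dy);
      z += dz;
      double mx = 0.5 * (ox + x), my = 0.5 * (oy + y), mz = 0.5 * (oz + z);
      for (int k = 0; k < K; ++k)
        phi[k] += GAMMA_UM * dt * (Gx(s, k) * mx + Gy(s, k) * my + Gz(s, k) * mz);
      if (cp < n_checkpoints && s == cp_steps[cp]) {
        msd_z[cp] += z * z;
        ++cp;
      }
    }
    for (int k = 0; k < K; ++k) {
      double cphi = std::cos(phi[k]), sphi = std::sin(phi[k]);
      sum_cos[k] += cphi; sum_sin[k] += sphi;
      sum_cos2[k] += cphi * cphi; sum_sin2[k] += sphi * sphi;
      sum_cs[k] += cphi * sphi;
    }
  }

  NumericVector S(K), SE(K);
  const double n = (double)n_walkers;
  for (int k = 0; k < K; ++k) {
    double mc = sum_cos[k] / n, ms = sum_sin[k] / n;
    double vc = sum_cos2[k] / n - mc * mc;
    double vs = sum_sin2[k] / n - ms * ms;
    double cc = sum_cs[k] / n - mc * ms;
    double A = std::sqrt(mc * mc + ms * ms);
    S[k] = A;
    if (A > 0)
      SE[k] = std::sqrt(std::max(0.0, (mc * mc * vc + ms * ms * vs +
                                       2.0 * mc * ms * cc)) / (A * A) / n);
    else
      SE[k] = std::sqrt((vc + vs) / n);
  }
  NumericVector msd(n_checkpoints), msd_t(n_checkpoints);
  for (int c = 0; c < n_checkpoints; ++c) {
    msd[c] = msd_z[c] / n;
    msd_t[c] = (cp_steps[c] + 1) * dt;
  }
  return List::create(_["S"] = S, _["SE"] = SE,
                      _["msd_z"] = msd, _["msd_t"] = msd_t);
}
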