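#include <Rcpp.h>
using namespace Rcpp;

// Overdamped (Brownian) dynamics of a harmonic spring network:
//   x <- x - (dt / zeta) * grad U + sqrt(2 kT dt / zeta) * eta
// with U = sum_springs (gamma / 2) (|d| - d0)^2. Noise comes from R's
// normal RNG, so set.seed() in R makes trajectories bitwise reproducible.
// Frames are saved every `save_every` steps after `n_equil` equilibration
// steps, flattened as (x1, y1, z1, x2, ...) per row.
// [[Rcpp::export]]
NumericMatrix bd_integrate(NumericMatrix coords, IntegerVector si,
                           IntegerVector sj, NumericVector rest,
                           double gamma, double kT, double friction,
                           double dt, int n_steps, int n_equil,
                           int save_every) {
  const int n = coords.nrow();
  const int ns = si.size();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  const double mob = dt / friction;
  const double amp = std::sqrt(2.0 * kT * dt / friction);
  const int n_frames = n_steps / save_every;
  NumericMatrix frames(n_frames, 3 * n);
  int frame = 0;

  for (int step = 1; step <= n_equil + n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      const int i = si[s] - 1, j = sj[s] - 1;
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < 1e-12) continue;
      const double f = -gamma * (d - rest[s]) / d;
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
      fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
    }
    for (int i = 0; i < n; ++i) {
      x[i] += mob * fx[i] + amp * norm_rand();
      y[i] += mob * fy[i] + amp * norm_rand();
      z[i] += mob * fz[i] + amp * norm_rand();
    }
    if (step % 1000 == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e8 ||
            !std::isfinite(y[i]) || std::fabs(y[i]) > 1e8 ||
            !std::isfinite(z[i]) || std::fabs(z[i]) > 1e8) {
          stop("Brownian dynamics diverged at step %d: time step too large for this network", step);
        }
      }
    }
    if (step > n_equil && (step - n_equil) % save_every == 0 &&
        frame < n_frames) {
      for (int i = 0; i < n; ++i) {
        frames(frame, 3 * i) = x[i];
        frames(frame, 3 * i + 1) = y[i];
        frames(frame, 3 * i + 2) = z[i];
      }
      ++frame;
    }
  }
  return frames;
}

// Per frame, mean distance of each selected bead to all other selected
// beads (1-based indices into the bead list). Rows = frames.
// [[Rcpp::export]]
NumericMatrix mean_bead_distances(NumericMatrix frames,
                                  IntegerVector bead_idx) {
  const int nf = frames.nrow();
  const int m = bead_idx.size();
  NumericMatrix out(nf, m);
  for (int f = 0; f < nf; ++f) {
    for (int a = 0; a < m; ++a) {
      const int ia = bead_idx[a] - 1;
      const double xa = frames(f, 3 * ia), ya = frames(f, 3 * ia + 1),
                   za = frames(f, 3 * ia + 2);
      double acc = 0.0;
      for (int b = 0; b < m; ++b) {
        if (b == a) continue;
        const int ib = bead_idx[b] - 1;
        const double dx = xa - frames(f, 3 * ib);
        const double dy = ya - frames(f, 3 * ib + 1);
        const double dz = za - frames(f, 3 * ib + 2);
        acc += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      out(f, a) = acc / (m - 1);
    }
  }
  return out;
}
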