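#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Overdamped (Brownian / first-order Langevin) integrator for bead-spring
// networks in reduced units: lengths nm, times ps, forces pN, energies
// pN nm.
//
//   dx = (F/gamma) dt + sqrt(2 kBT dt / gamma) xi
//
// Bonds are harmonic in the displacement of the bond vector from its
// relaxed reference (elastic-network form): F_j = -k (d - d0) with
// d = x_j - x_i. The network is therefore exactly Gaussian, so its
// mechanical ground truth (series/parallel spring composition) holds at
// any temperature. Remaining terms: harmonic head restraints (reaction
// forces recorded), flat-bottom lateral (xy) confinement about the z axis,
// and constant external forces. Uses R's RNG so set.seed() governs the
// noise.
//
// Aborts with a diagnostic if any bond stretches beyond 10x its reference
// length (an unstable or out-of-regime state).

// [[Rcpp::export]]
List bd_integrate(NumericMatrix coords0, IntegerMatrix bonds,
                  NumericVector bond_k, NumericMatrix bond_d0,
                  IntegerVector restr_idx, NumericMatrix restr_anchor,
                  double restr_k, IntegerVector flat_idx, double flat_radius,
                  double flat_k, NumericMatrix ext_force, double gamma,
                  double dt, int n_steps, int save_every, double kBT) {
  const int n = coords0.nrow();
  const int nb = bonds.nrow();
  const int nr = restr_idx.size();
  const int nfl = flat_idx.size();
  if (n_steps <= 0 || dt <= 0) stop("dt and n_steps must be positive");
  if (save_every <= 0) stop("save_every must be positive");

  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords0(i, d);
  std::vector<double> f(3 * n);
  std::vector<double> ref_len(nb);
  for (int b = 0; b < nb; ++b)
    ref_len[b] = std::sqrt(bond_d0(b, 0) * bond_d0(b, 0) +
                           bond_d0(b, 1) * bond_d0(b, 1) +
                           bond_d0(b, 2) * bond_d0(b, 2));

  const int n_saved = n_steps / save_every;
  NumericVector xyz_out((R_xlen_t)n_saved * n * 3);
  NumericVector react_out((R_xlen_t)n_saved * nr * 3);
  NumericVector times_out(n_saved);

  const double mob = dt / gamma;
  const double noise = (kBT > 0) ? std::sqrt(2.0 * kBT * dt / gamma) : 0.0;

  // fast internal normal generator, seeded from R's RNG stream so that
  // set.seed() fully determines the run
  std::mt19937_64 rng;
  {
    RNGScope scope;
    uint64_t s1 = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t s2 = (uint64_t)(unif_rand() * 4294967296.0);
    rng.seed((s1 << 32) ^ s2);
  }
  std::normal_distribution<double> gauss(0.0, 1.0);
  int saved = 0;
  for (int step = 1; step <= n_steps; ++step) {
    std::fill(f.begin(), f.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) f[3 * i + d] += ext_force(i, d);
    for (int b = 0; b < nb; ++b) {
      const int i = bonds(b, 0), j = bonds(b, 1);
      double dx = x[3 * j] - x[3 * i];
      double dy = x[3 * j + 1] - x[3 * i + 1];
      double dz = x[3 * j + 2] - x[3 * i + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > 100.0 * ref_len[b] * ref_len[b])
        stop("unstable integration: bond %d extended to %.2f nm (reference %.3f nm) at step %d; reduce dt or forces",
             b + 1, std::sqrt(r2), ref_len[b], step);
      double fx = bond_k[b] * (dx - bond_d0(b, 0));
      double fy = bond_k[b] * (dy - bond_d0(b, 1));
      double fz = bond_k[b] * (dz - bond_d0(b, 2));
      f[3 * i] += fx;     f[3 * j] -= fx;
      f[3 * i + 1] += fy; f[3 * j + 1] -= fy;
      f[3 * i + 2] += fz; f[3 * j + 2] -= fz;
    }
    bool at_save = (step % save_every == 0);
    for (int r = 0; r < nr; ++r) {
      const int i = restr_idx[r];
      for (int d = 0; d < 3; ++d) {
        double fr = -restr_k * (x[3 * i + d] - restr_anchor(r, d));
        f[3 * i + d] += fr;
        if (at_save)
          react_out[(R_xlen_t)saved + (R_xlen_t)n_saved * (r + (R_xlen_t)nr * d)] = fr;
      }
    }
    for (int k = 0; k < nfl; ++k) {
      const int i = flat_idx[k];
      double rxy = std::sqrt(x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1]);
      if (rxy > flat_radius && rxy > 1e-12) {
        double fmag = -flat_k * (rxy - flat_radius) / rxy;
        f[3 * i] += fmag * x[3 * i];
        f[3 * i + 1] += fmag * x[3 * i + 1];
      }
    }
    if (noise > 0) {
      for (int i = 0; i < 3 * n; ++i)
        x[i] += mob * f[i] + noise * gauss(rng);
    } else {
      for (int i = 0; i < 3 * n; ++i) x[i] += mob * f[i];
    }
    if (at_save) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          xyz_out[(R_xlen_t)saved + (R_xlen_t)n_saved * (i + (R_xlen_t)n * d)] =
            x[3 * i + d];
      times_out[saved] = step * dt;
      ++saved;
    }
  }
  xyz_out.attr("dim") = IntegerVector::create(n_saved, n, 3);
  react_out.attr("dim") = IntegerVector::create(n_saved, nr, 3);
  return List::create(_["xyz"] = xyz_out, _["times"] = times_out,
                      _["reaction"] = react_out);
}
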