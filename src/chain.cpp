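// Compiled core: potential/force evaluation for the bead-spring chain
// (Morse bonds, harmonic bends, cosine-series torsions) and a BAOAB
// Langevin integrator with optional end-bead pinning (isometric) or a
// constant axial pulling force (isotensional).
//
// Internal units: kcal/mol, Angstrom, fs, K, g/mol.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static const double MVSQ = 4.184e-4;     // kcal/mol -> (g/mol) A^2 / fs^2
static const double KB = 0.0019872041;   // kcal/(mol K)

struct FF {
  int N;
  std::vector<double> mass;
  double D, alpha, r0, Kb, th0;
  // cosine-series coefficients, one row per dihedral (N-3 rows)
  std::vector<std::vector<double> > Kt;
};

static FF parse_ff(const List& ffr) {
  FF ff;
  ff.N = as<int>(ffr["n_beads"]);
  NumericVector m = ffr["masses"];
  ff.mass.assign(m.begin(), m.end());
  ff.D = as<double>(ffr["bond_D"]);
  ff.alpha = as<double>(ffr["bond_alpha"]);
  ff.r0 = as<double>(ffr["bond_r0"]);
  ff.Kb = as<double>(ffr["bend_K"]);
  ff.th0 = as<double>(ffr["bend_theta0"]);
  List kt = ffr["torsion_K"];
  for (int i = 0; i < kt.size(); ++i) {
    NumericVector k = kt[i];
    ff.Kt.push_back(std::vector<double>(k.begin(), k.end()));
  }
  return ff;
}

static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Potential energy and forces (-grad V).  Returns V; accumulates the largest
// alpha*(r - r0) seen over the bonds into *max_stretch (bond-break monitor).
static double eval_fu(const std::vector<double>& x, const FF& ff,
                      std::vector<double>& F, double* max_stretch) {
  const int N = ff.N;
  double V = 0.0;
  std::fill(F.begin(), F.end(), 0.0);

  // Morse bonds
  for (int i = 0; i < N - 1; ++i) {
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = x[3 * (i + 1) + k] - x[3 * i + k];
    double r = std::sqrt(dot3(d, d));
    if (r < 1e-10) stop("overlapping consecutive beads (bond length ~ 0)");
    double s = ff.alpha * (r - ff.r0);
    if (max_stretch && s > *max_stretch) *max_stretch = s;
    double e = std::exp(-s);
    V += ff.D * (1.0 - e) * (1.0 - e);
    double dUdr = 2.0 * ff.D * ff.alpha * e * (1.0 - e);
    for (int k = 0; k < 3; ++k) {
      double g = dUdr * d[k] / r;  // pulls i toward i+1 when stretched
      F[3 * i + k] += g;
      F[3 * (i + 1) + k] -= g;
    }
  }

  // harmonic bends
  if (ff.Kb > 0.0) {
    for (int j = 1; j < N - 1; ++j) {
      double a[3], b[3];
      for (int k = 0; k < 3; ++k) {
        a[k] = x[3 * (j - 1) + k] - x[3 * j + k];
        b[k] = x[3 * (j + 1) + k] - x[3 * j + k];
      }
      double la = std::sqrt(dot3(a, a)), lb = std::sqrt(dot3(b, b));
      double ca = dot3(a, b) / (la * lb);
      if (ca > 1.0) ca = 1.0;
      if (ca < -1.0) ca = -1.0;
      double th = std::acos(ca);
      double dth = th - ff.th0;
      V += 0.5 * ff.Kb * dth * dth;
      double sth = std::sqrt(1.0 - ca * ca);
      if (sth < 1e-8) continue;  // collinear: force contribution dropped
      double dUdth = ff.Kb * dth;
      for (int k = 0; k < 3; ++k) {
        double ga = (dUdth / sth) * (b[k] / (la * lb) - ca * a[k] / (la * la));
        double gb = (dUdth / sth) * (a[k] / (la * lb) - ca * b[k] / (lb * lb));
        F[3 * (j - 1) + k] += ga;
        F[3 * (j + 1) + k] += gb;
        F[3 * j + k] -= ga + gb;
      }
    }
  }

  // cosine-series torsions
  for (int t = 0; t < (int)ff.Kt.size(); ++t) {
    const std::vector<double>& K = ff.Kt[t];
    if (K.empty()) continue;
    double b1[3], b2[3], b3[3];
    for (int k = 0; k < 3; ++k) {
      b1[k] = x[3 * (t + 1) + k] - x[3 * t + k];
      b2[k] = x[3 * (t + 2) + k] - x[3 * (t + 1) + k];
      b3[k] = x[3 * (t + 3) + k] - x[3 * (t + 2) + k];
    }
    double n1[3], n2[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    double b1sq = dot3(b1, b1), b2sq = dot3(b2, b2), b3sq = dot3(b3, b3);
    // near-collinear adjacent bends: dihedral undefined, contribution dropped
    if (n1sq < 1e-12 * b1sq * b2sq || n2sq < 1e-12 * b2sq * b3sq) continue;
    double ln1 = std::sqrt(n1sq), ln2 = std::sqrt(n2sq);
    double c = dot3(n1, n2) / (ln1 * ln2);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    // V = sum_c K_c cos^{c-1}(phi)
    double pw = 1.0, dUdc = 0.0;
    for (size_t ci = 0; ci < K.size(); ++ci) {
      V += K[ci] * pw;
      if (ci + 1 < K.size()) dUdc += (double)(ci + 1) * K[ci + 1] * pw;
      pw *= c;
    }
    double lb2 = std::sqrt(b2sq);
    double cx[3];
    cross3(n1, n2, cx);
    double sphi = dot3(cx, b2) / (ln1 * ln2 * lb2);
    double dUdphi = -sphi * dUdc;
    double g1[3], g4[3], g2[3], g3[3];
    double t1 = dot3(b1, b2) / b2sq, t3 = dot3(b3, b2) / b2sq;
    for (int k = 0; k < 3; ++k) {
      g1[k] = -(lb2 / n1sq) * n1[k];
      g4[k] = (lb2 / n2sq) * n2[k];
    }
    for (int k = 0; k < 3; ++k) {
      g2[k] = -(1.0 + t1) * g1[k] + t3 * g4[k];
      g3[k] = t1 * g1[k] - (1.0 + t3) * g4[k];
    }
    for (int k = 0; k < 3; ++k) {
      F[3 * t + k] -= dUdphi * g1[k];
      F[3 * (t + 1) + k] -= dUdphi * g2[k];
      F[3 * (t + 2) + k] -= dUdphi * g3[k];
      F[3 * (t + 3) + k] -= dUdphi * g4[k];
    }
  }
  return V;
}

// [[Rcpp::export]]
double cpp_potential(NumericMatrix pos, List ffr) {
  FF ff = parse_ff(ffr);
  std::vector<double> x(3 * ff.N), F(3 * ff.N);
  for (int i = 0; i < ff.N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  return eval_fu(x, ff, F, (double*)0);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, List ffr) {
  FF ff = parse_ff(ffr);
  std::vector<double> x(3 * ff.N), F(3 * ff.N);
  for (int i = 0; i < ff.N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  eval_fu(x, ff, F, (double*)0);
  NumericMatrix out(ff.N, 3);
  for (int i = 0; i < ff.N; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return out;
}

// BAOAB Langevin trajectory.
// mode: 0 = free, 1 = isometric (beads 1 and N pinned, no thermostat on them),
//       2 = isotensional (constant force -f z on bead 1, +f z on bead N).
// Observable per sample: mode 1 -> 0.5*(Fint_1 - Fint_N).z  (equals dF/dx in
// the mean, positive for a stretched chain); otherwise z(r_N) - z(r_1).
// With gamma = 0 the O-step is the identity and the scheme is velocity Verlet.
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos0, NumericMatrix vel0, List ffr, int n_steps,
             double dt, double gamma, double temperature, int mode,
             double fext, int sample_every, double seed,
             bool draw_velocities) {
  FF ff = parse_ff(ffr);
  const int N = ff.N;
  std::vector<double> x(3 * N), v(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = pos0(i, k);
      v[3 * i + k] = vel0(i, k);
    }

  std::vector<int> free_beads;
  for (int i = 0; i < N; ++i)
    if (!(mode == 1 && (i == 0 || i == N - 1))) free_beads.push_back(i);
  const int nfree = (int)free_beads.size();

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> nd(0.0, 1.0);

  if (draw_velocities) {
    for (int fi = 0; fi < nfree; ++fi) {
      int i = free_beads[fi];
      double sd = std::sqrt(KB * temperature * MVSQ / ff.mass[i]);
      for (int k = 0; k < 3; ++k) v[3 * i + k] = sd * nd(rng);
    }
  }
  if (mode == 1) {  // pinned beads carry no momentum
    for (int k = 0; k < 3; ++k) { v[k] = 0.0; v[3 * (N - 1) + k] = 0.0; }
  }

  double c1 = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (gamma > 0.0) ? std::sqrt(1.0 - c1 * c1) : 0.0;

  double max_stretch = -1e30;
  double V = eval_fu(x, ff, F, &max_stretch);

  int n_samp = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericVector obs(n_samp), epot(n_samp), ekin(n_samp);
  int is = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick (internal + external forces)
    for (int fi = 0; fi < nfree; ++fi) {
      int i = free_beads[fi];
      double inv = 0.5 * dt * MVSQ / ff.mass[i];
      for (int k = 0; k < 3; ++k) {
        double Fk = F[3 * i + k];
        if (mode == 2 && k == 2) {
          if (i == 0) Fk -= fext;
          if (i == N - 1) Fk += fext;
        }
        v[3 * i + k] += inv * Fk;
      }
    }
    // A: half drift
    for (int fi = 0; fi < nfree; ++fi) {
      int i = free_beads[fi];
      for (int k = 0; k < 3; ++k) x[3 * i + k] += 0.5 * dt * v[3 * i + k];
    }
    // O: friction + noise
    if (gamma > 0.0) {
      for (int fi = 0; fi < nfree; ++fi) {
        int i = free_beads[fi];
        double sd = std::sqrt(KB * temperature * MVSQ / ff.mass[i]);
        for (int k = 0; k < 3; ++k)
          v[3 * i + k] = c1 * v[3 * i + k] + c2 * sd * nd(rng);
      }
    }
    // A: half drift
    for (int fi = 0; fi < nfree; ++fi) {
      int i = free_beads[fi];
      for (int k = 0; k < 3; ++k) x[3 * i + k] += 0.5 * dt * v[3 * i + k];
    }
    // recompute forces, B: half kick
    V = eval_fu(x, ff, F, &max_stretch);
    for (int fi = 0; fi < nfree; ++fi) {
      int i = free_beads[fi];
      double inv = 0.5 * dt * MVSQ / ff.mass[i];
      for (int k = 0; k < 3; ++k) {
        double Fk = F[3 * i + k];
        if (mode == 2 && k == 2) {
          if (i == 0) Fk -= fext;
          if (i == N - 1) Fk += fext;
        }
        v[3 * i + k] += inv * Fk;
      }
    }

    if (!std::isfinite(V) || !std::isfinite(x[0]))
      stop("integration failure (non-finite coordinates) at step %d", step);

    if (sample_every > 0 && step % sample_every == 0 && is < n_samp) {
      double ob;
      if (mode == 1) ob = 0.5 * (F[2] - F[3 * (N - 1) + 2]);
      else ob = x[3 * (N - 1) + 2] - x[2];
      double ke = 0.0;
      for (int fi = 0; fi < nfree; ++fi) {
        int i = free_beads[fi];
        double vv = dot3(&v[3 * i], &v[3 * i]);
        ke += 0.5 * ff.mass[i] * vv / MVSQ;  // back to kcal/mol
      }
      obs[is] = ob;
      epot[is] = V;
      ekin[is] = ke;
      ++is;
    }
  }

  NumericMatrix pos(N, 3), vel(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) {
      pos(i, k) = x[3 * i + k];
      vel(i, k) = v[3 * i + k];
    }
  return List::create(_["pos"] = pos, _["vel"] = vel, _["obs"] = obs,
                      _["epot"] = epot, _["ekin"] = ekin,
                      _["n_free"] = nfree,
                      _["max_stretch"] = max_stretch);
}
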