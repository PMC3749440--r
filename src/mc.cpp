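#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise-linear stretch-energy lookup for the series tether.
// x0 is always 0; `rigid` is inelastic length subtracted from the
// bead-bead distance before lookup (folded hairpin width). Beyond the
// tabulated range the chain is overstretched: infinite energy, so the
// Metropolis move is rejected rather than erroring.
struct EnergyTable {
  double dx, x_max, rigid;
  const double *E;
  int n;
  bool active;
};

static inline double table_energy(const EnergyTable &t, double r) {
  if (!t.active) return 0.0;
  double x = r - t.rigid;
  if (x <= 0.0) return 0.0;          // slack / buckled: no restoring force
  if (x >= t.x_max) return R_PosInf; // overstretched
  double u = x / t.dx;
  int i = (int)u;
  if (i >= t.n - 1) return R_PosInf;
  double w = u - i;
  return t.E[i] * (1.0 - w) + t.E[i + 1] * w;
}

// Total energy: two anisotropic 3D harmonic traps (trap1 at origin,
// trap2 at (d,0,0); x is the pulling axis) plus tether stretch energy
// at the bead-bead distance.
static inline double total_energy_c(const double b1[3], const double b2[3],
                                    double d, const double k[6],
                                    const EnergyTable &t) {
  double e = 0.5 * (k[0] * b1[0] * b1[0] + k[1] * b1[1] * b1[1] +
                    k[2] * b1[2] * b1[2]);
  double dx2 = b2[0] - d;
  e += 0.5 * (k[3] * dx2 * dx2 + k[4] * b2[1] * b2[1] +
              k[5] * b2[2] * b2[2]);
  double rx = b2[0] - b1[0], ry = b2[1] - b1[1], rz = b2[2] - b1[2];
  double r = std::sqrt(rx * rx + ry * ry + rz * rz);
  double et = table_energy(t, r);
  return e + et;
}

static EnergyTable as_table(List tab) {
  EnergyTable t;
  if (tab.size() == 0) {
    t.active = false; t.dx = 1; t.x_max = 0; t.rigid = 0; t.E = NULL; t.n = 0;
    return t;
  }
  t.active = true;
  t.dx = as<double>(tab["dx"]);
  t.x_max = as<double>(tab["x_max"]);
  t.rigid = as<double>(tab["rigid"]);
  NumericVector E = tab["E"];
  t.E = E.begin();
  t.n = E.size();
  return t;
}

// One Metropolis step: perturb all 6 coordinates simultaneously, uniform
// within +/- step, accept with min(1, exp(-dE/kT)). Returns new energy.
static inline bool metro_step(double b1[3], double b2[3], double d,
                              const double k[6], const EnergyTable &t,
                              double step, double kT, double &Ecur) {
  double p1[3], p2[3];
  for (int i = 0; i < 3; ++i) {
    p1[i] = b1[i] + step * (2.0 * unif_rand() - 1.0);
    p2[i] = b2[i] + step * (2.0 * unif_rand() - 1.0);
  }
  double Enew = total_energy_c(p1, p2, d, k, t);
  double dE = Enew - Ecur;
  bool acc;
  if (dE <= 0.0) acc = true;
  else if (!R_finite(Enew)) acc = false;
  else acc = (unif_rand() < std::exp(-dE / kT));
  if (acc) {
    for (int i = 0; i < 3; ++i) { b1[i] = p1[i]; b2[i] = p2[i]; }
    Ecur = Enew;
  }
  return acc;
}

// Force-ramp (pulling) protocol: the trap separation grows by dx_accept
// after every accepted step. Per-step observables are block-averaged by
// `factor` (mc_rate / output_rate). Stops when the block-mean force
// reaches max_force or after max_steps steps.
// [[Rcpp::export]]
List mc_pull_cpp(NumericVector b1_init, NumericVector b2_init, double d0,
                 NumericVector kvec, double step, double kT, List table,
                 double dx_accept, double max_force, int max_steps,
                 int factor, int burn_in) {
  EnergyTable t = as_table(table);
  double b1[3] = {b1_init[0], b1_init[1], b1_init[2]};
  double b2[3] = {b2_init[0], b2_init[1], b2_init[2]};
  double k[6];
  for (int i = 0; i < 6; ++i) k[i] = kvec[i];
  double d = d0;
  double Ecur = total_energy_c(b1, b2, d, k, t);

  for (int i = 0; i < burn_in; ++i)
    metro_step(b1, b2, d, k, t, step, kT, Ecur);

  int max_blocks = max_steps / factor;
  NumericVector out_d(max_blocks), out_f(max_blocks), out_e(max_blocks),
      out_d1(max_blocks), out_d2(max_blocks);
  long n_acc = 0, n_tot = 0;
  int block = 0;
  double sd = 0, sf = 0, se = 0, s1 = 0, s2 = 0;
  int in_block = 0;
  bool done = false;

  for (int s = 0; s < max_steps && !done; ++s) {
    bool acc = metro_step(b1, b2, d, k, t, step, kT, Ecur);
    ++n_tot;
    if (acc) {
      ++n_acc;
      d += dx_accept;
      Ecur = total_energy_c(b1, b2, d, k, t); // trap2 centre moved
    }
    double defl1 = b1[0];
    double defl2 = b2[0] - d;
    double force = 0.5 * (k[0] * defl1 - k[3] * defl2);
    double ext = b2[0] - b1[0];
    sd += d; s1 += defl1; s2 += defl2; sf += force; se += ext;
    if (++in_block == factor) {
      out_d[block] = sd / factor; out_d1[block] = s1 / factor;
      out_d2[block] = s2 / factor; out_f[block] = sf / factor;
      out_e[block] = se / factor;
      if (out_f[block] >= max_force) done = true;
      ++block;
      sd = sf = se = s1 = s2 = 0; in_block = 0;
    }
  }

  return List::create(
      _["trap_sep_nm"] = out_d[Range(0, block - 1)],
      _["defl1_nm"] = out_d1[Range(0, block - 1)],
      _["defl2_nm"] = out_d2[Range(0, block - 1)],
      _["force_pN"] = out_f[Range(0, block - 1)],
      _["extension_nm"] = out_e[Range(0, block - 1)],
      _["acceptance"] = (double)n_acc / (double)n_tot,
      _["b1"] = NumericVector::create(b1[0], b1[1], b1[2]),
      _["b2"] = NumericVector::create(b2[0], b2[1], b2[2]));
}

// Constant-trap-distance protocol. `states` gives the hidden hairpin
// state (0 = folded, 1 = unfolded) for each output sample; the tether
// energy table is swapped accordingly. On every state switch the bead
// coordinates are re-equilibrated with burn_switch unrecorded sweeps,
// so each output sample is drawn from the equilibrium ensemble of its
// state. Each output sample is the block mean of `factor` MC steps.
// [[Rcpp::export]]
List mc_cd_cpp(NumericVector b1_init, NumericVector b2_init, double d,
               NumericVector kvec, double step, double kT, List table0,
               List table1, IntegerVector states, int factor, int burn_in,
               int burn_switch) {
  EnergyTable t0 = as_table(table0);
  EnergyTable t1 = as_table(table1);
  double b1[3] = {b1_init[0], b1_init[1], b1_init[2]};
  double b2[3] = {b2_init[0], b2_init[1], b2_init[2]};
  double k[6];
  for (int i = 0; i < 6; ++i) k[i] = kvec[i];
  int n_out = states.size();
  NumericVector out_f(n_out), out_e(n_out), out_d1(n_out), out_d2(n_out);
  long n_acc = 0, n_tot = 0;
  int cur = states[0];
  const EnergyTable *tc = (cur == 0) ? &t0 : &t1;
  double Ecur = total_energy_c(b1, b2, d, k, *tc);
  for (int i = 0; i < burn_in; ++i)
    metro_step(b1, b2, d, k, *tc, step, kT, Ecur);

  for (int j = 0; j < n_out; ++j) {
    if (states[j] != cur) {
      cur = states[j];
      tc = (cur == 0) ? &t0 : &t1;
      Ecur = total_energy_c(b1, b2, d, k, *tc);
      for (int i = 0; i < burn_switch; ++i)
        metro_step(b1, b2, d, k, *tc, step, kT, Ecur);
    }
    double sf = 0, se = 0, s1 = 0, s2 = 0;
    for (int i = 0; i < factor; ++i) {
      bool acc = metro_step(b1, b2, d, k, *tc, step, kT, Ecur);
      ++n_tot; if (acc) ++n_acc;
      double defl1 = b1[0];
      double defl2 = b2[0] - d;
      s1 += defl1; s2 += defl2;
      sf += 0.5 * (k[0] * defl1 - k[3] * defl2);
      se += (b2[0] - b1[0]);
    }
    out_d1[j] = s1 / factor; out_d2[j] = s2 / factor;
    out_f[j] = sf / factor; out_e[j] = se / factor;
  }

  return List::create(
      _["defl1_nm"] = out_d1, _["defl2_nm"] = out_d2,
      _["force_pN"] = out_f, _["extension_nm"] = out_e,
      _["acceptance"] = (double)n_acc / (double)n_tot,
      _["b1"] = NumericVector::create(b1[0], b1[1], b1[2]),
      _["b2"] = NumericVector::create(b2[0], b2[1], b2[2]));
}
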