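#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// positive remainder mod 360 without libm fmod
static inline double mod360(double a) {
  return a - 360.0 * std::floor(a / 360.0);
}

// circular distance on the 360-degree domain, in [0, 180]
static inline double circ_dist(double a, double b) {
  double d = mod360(a - b);
  if (d > 180.0) d = 360.0 - d;
  return d;
}

static inline double rep_energy(double t1, double t2, double dint) {
  double delta = circ_dist(t1, t2);
  if (delta <= 0.0) return R_PosInf;
  double q = dint / delta;
  double q3 = q * q * q;
  double q6 = q3 * q3;
  return q6 * q6; // (d/delta)^12
}

static inline double well_energy_c(double th, double mu, double sigma) {
  double d = circ_dist(th, mu);
  return -std::exp(-(d * d) / (2.0 * sigma * sigma));
}

static inline double hamiltonian_c(double t1, double t2, double rho, double w1,
                                   double w2, double mu1, double mu2,
                                   double sigma, double dint,
                                   bool wells_active) {
  double h = rho * rep_energy(t1, t2, dint);
  if (wells_active) {
    h += w1 * well_energy_c(t1, mu1, sigma) + w2 * well_energy_c(t2, mu2, sigma);
  }
  return h;
}

// Metropolis-Hastings chain for the two-cell rotation model. Per step three
// uniforms are drawn in fixed order (cell choice, direction, acceptance) so
// that an R-level reference loop with the same seed reproduces the chain
// exactly. theta are degrees on a step_deg lattice of the circle; proposals
// that would superpose the cells have infinite repulsive energy and are
// rejected. Wells are switched on after `breaking` steps.
// [[Rcpp::export(name = ".mh_run_cpp")]]
List mh_run_cpp(double theta1, double theta2, double rho, double w1, double w2,
                double mu1, double mu2, double sigma, double dint,
                double step_deg, double beta, int n_steps, int breaking) {
  NumericVector th1(n_steps + 1), th2(n_steps + 1), energy(n_steps + 1);
  LogicalVector accepted(n_steps);

  double t1 = theta1, t2 = theta2;
  bool active = breaking <= 0;
  double h = hamiltonian_c(t1, t2, rho, w1, w2, mu1, mu2, sigma, dint, active);
  th1[0] = t1;
  th2[0] = t2;
  energy[0] = h;

  for (int i = 0; i < n_steps; ++i) {
    if (!active && i >= breaking) {
      active = true;
      h = hamiltonian_c(t1, t2, rho, w1, w2, mu1, mu2, sigma, dint, active);
    }
    double u_cell = unif_rand();
    double u_dir = unif_rand();
    double u_acc = unif_rand();
    bool move_first = u_cell < 0.5;
    double delta = (u_dir < 0.5) ? -step_deg : step_deg;
    double p1 = t1, p2 = t2;
    if (move_first) {
      p1 = mod360(t1 + delta);
    } else {
      p2 = mod360(t2 + delta);
    }
    double h_new =
        hamiltonian_c(p1, p2, rho, w1, w2, mu1, mu2, sigma, dint, active);
    bool acc;
    if (!std::isfinite(h_new)) {
      acc = false;
    } else {
      double dh = h_new - h;
      acc = (dh <= 0.0) ? true : (u_acc < std::exp(-beta * dh));
    }
    if (acc) {
      t1 = p1;
      t2 = p2;
      h = h_new;
    }
    accepted[i] = acc;
    th1[i + 1] = t1;
    th2[i + 1] = t2;
    energy[i + 1] = h;
  }

  return List::create(_["theta1"] = th1, _["theta2"] = th2,
                      _["energy"] = energy, _["accepted"] = accepted);
}
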