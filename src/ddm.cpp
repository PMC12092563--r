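// Core numerics for the diffusion decision model (DDM):
//  - first-passage-time density of a Wiener process between absorbing
//    boundaries, via the classic small-time / large-time series with an
//    automatic switch chosen from per-series truncation bounds;
//  - analytic integration over normal across-trial drift variability;
//  - Gauss-Legendre integration over uniform start-point variability
//    (nodes/weights supplied by the R side);
//  - Euler-Maruyama trial simulator.
// Scaling convention throughout: diffusion coefficient s = 1.

#include <Rcpp.h>
using namespace Rcpp;

static const double SQRT_2PI = 2.5066282746310002;

// Zero-drift first-passage density at the *lower* boundary on the unit
// scale: boundary separation 1, relative start w in (0,1), scaled time
// tau = t / a^2.  Series truncation follows the standard bounds that
// guarantee absolute error below eps on this scale.
static double fpt_lower_unit(double tau, double w, double eps) {
  if (tau <= 0.0) return 0.0;

  // number of terms needed by each representation
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double f = 0.0;
  if (ks < kl) {          // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2), hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double u = w + 2.0 * k;
      f += u * std::exp(-u * u / (2.0 * tau));
    }
    f /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {                // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// Drift-dependent factor of the lower-boundary density, with the normal
// across-trial drift distribution N(v, sv^2) integrated out analytically:
//   E_v[ exp(-v a w - v^2 t / 2) ]
//     = (1 + sv^2 t)^{-1/2} exp( (sv^2 a^2 w^2 - 2 v a w - v^2 t)
//                                / (2 (1 + sv^2 t)) ).
static double drift_factor(double t, double aw, double v, double sv) {
  double s2t = 1.0 + sv * sv * t;
  return std::exp((sv * sv * aw * aw - 2.0 * v * aw - v * v * t) / (2.0 * s2t)) /
         std::sqrt(s2t);
}

// Defective density for one boundary at decision time td (= rt - t0), for
// relative start w (upper boundary handled by reflection w -> 1 - w,
// v -> -v done by the caller through `upper`).
static double ddm_dens_one(double td, double a, double v, double w, double sv,
                           double eps, bool upper) {
  if (td <= 0.0) return 0.0;
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - w : w;
  double tau = td / (a * a);
  double f0 = fpt_lower_unit(tau, ww, eps);
  if (f0 <= 0.0) return 0.0;
  return drift_factor(td, a * ww, vv, sv) * f0 / (a * a);
}

// [[Rcpp::export(name = ".ddm_density_cpp")]]
NumericVector ddm_density_cpp(NumericVector rt, double a, double v, double z,
                              double sv, double sz, double t0, bool upper,
                              NumericVector gl_nodes, NumericVector gl_weights,
                              double eps) {
  int n = rt.size(), m = gl_nodes.size();
  NumericVector out(n);
  double w = z / a;
  double half_sw = 0.5 * sz / a;   // half-range of w under uniform z-variability
  for (int i = 0; i < n; ++i) {
    double td = rt[i] - t0;
    if (td <= 0.0) { out[i] = 0.0; continue; }
    double f;
    if (sz <= 0.0) {
      f = ddm_dens_one(td, a, v, w, sv, eps, upper);
    } else {
      f = 0.0;
      for (int j = 0; j < m; ++j) {
        double wj = w + half_sw * gl_nodes[j];
        f += 0.5 * gl_weights[j] * ddm_dens_one(td, a, v, wj, sv, eps, upper);
      }
    }
    out[i] = f;
  }
  return out;
}

// Sum of log defective densities over trials (one parameter set); trials
// split by boundary on the R side would double the loop, so both are
// handled here.  Returns -Inf when any trial has zero density.
// [[Rcpp::export(name = ".ddm_loglik_cpp")]]
double ddm_loglik_cpp(NumericVector rt, LogicalVector upper, double a,
                      double v, double z, double sv, double sz, double t0,
                      NumericVector gl_nodes, NumericVector gl_weights,
                      double eps) {
  int n = rt.size(), m = gl_nodes.size();
  double w = z / a, half_sw = 0.5 * sz / a, ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double td = rt[i] - t0;
    if (td <= 0.0) return R_NegInf;
    double f;
    if (sz <= 0.0) {
      f = ddm_dens_one(td, a, v, w, sv, eps, upper[i]);
    } else {
      f = 0.0;
      for (int j = 0; j < m; ++j) {
        double wj = w + half_sw * gl_nodes[j];
        f += 0.5 * gl_weights[j] * ddm_dens_one(td, a, v, wj, sv, eps, upper[i]);
      }
    }
    if (!(f > 0.0)) return R_NegInf;
    ll += std::log(f);
  }
  return ll;
}

// Standard normal via the Marsaglia polar transform of R's uniform
// stream (deterministic under set.seed; cheaper than the inversion used
// by norm_rand for the volumes simulated here).  The spare cache is
// local to each simulate call.
struct PolarNormal {
  bool has_spare = false;
  double spare = 0.0;
  double draw() {
    if (has_spare) { has_spare = false; return spare; }
    double u, w, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      w = 2.0 * unif_rand() - 1.0;
      s = u * u + w * w;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = w * f;
    has_spare = true;
    return u * f;
  }
};

// Euler-Maruyama simulation of the diffusion path.  Per trial the drift is
// drawn from N(v, sv^2) and the start point from U(z - sz/2, z + sz/2);
// the path is advanced in steps of `dt` until absorption at 0 or a, or
// until `tmax` (flagged with boundary = NA).  Between consecutive interior
// positions a Brownian-bridge test absorbs paths that cross and return
// within a step, removing the O(sqrt(dt)) crossing bias of the bare
// scheme.  Uses R's RNG stream.
// [[Rcpp::export(name = ".ddm_simulate_cpp")]]
List ddm_simulate_cpp(int n, double a, double v, double z, double sv,
                      double sz, double t0, double dt, double tmax) {
  NumericVector rt(n);
  IntegerVector boundary(n);   // 1 = upper, 0 = lower, NA = capped
  double sqdt = std::sqrt(dt);
  long max_steps = (long)std::ceil(tmax / dt);
  // bridge crossing probability exp(-2 d0 d1 / dt) is negligible beyond
  // this product of distances to the boundary
  double bridge_cut = 10.0 * dt;
  RNGScope scope;
  PolarNormal rng;
  for (int i = 0; i < n; ++i) {
    double vi = v + sv * rng.draw();
    double x = z + sz * (unif_rand() - 0.5);
    double mu = vi * dt;
    long step = 0;
    int hit = NA_INTEGER;
    while (step < max_steps) {
      double x_new = x + mu + sqdt * rng.draw();
      ++step;
      if (x_new >= a) { hit = 1; break; }
      if (x_new <= 0.0) { hit = 0; break; }
      double du = (a - x) * (a - x_new);
      if (du < bridge_cut &&
          unif_rand() < std::exp(-2.0 * du / dt)) { hit = 1; break; }
      double dl = x * x_new;
      if (dl < bridge_cut &&
          unif_rand() < std::exp(-2.0 * dl / dt)) { hit = 0; break; }
      x = x_new;
    }
    boundary[i] = hit;
    rt[i] = step * dt + t0;
  }
  return List::create(_["rt"] = rt, _["boundary"] = boundary);
}
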