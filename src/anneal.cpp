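// Annealed overdamped dynamics for the particle-on-a-string genome model.
// One call runs a single resolution stage: a temperature ladder of noisy
// steepest-descent steps under flat-bottom harmonic restraints (contacts and
// backbone bonds) plus a soft short-range pair repulsion that prevents
// particle superposition. Deterministic for a given seed (std::mt19937,
// independent of R's RNG).
#include <Rcpp.h>
#include <random>
#include <cmath>
#include <unordered_set>
using namespace Rcpp;

// pairs carrying an explicit restraint (contact or backbone) are excluded
// from the generic repulsion: their own lower bounds prevent superposition
static std::unordered_set<long long> restrained_pairs(const IntegerVector& ri,
                                                      const IntegerVector& rj,
                                                      const IntegerVector& bi,
                                                      const IntegerVector& bj,
                                                      int n) {
  std::unordered_set<long long> s;
  for (int t = 0; t < ri.size(); ++t)
    s.insert(static_cast<long long>(std::min(ri[t], rj[t])) * n +
             std::max(ri[t], rj[t]));
  for (int t = 0; t < bi.size(); ++t)
    s.insert(static_cast<long long>(std::min(bi[t], bj[t])) * n +
             std::max(bi[t], bj[t]));
  return s;
}

static inline double flat_bottom_energy(double d, double lo, double up, double k) {
  if (d < lo) { double x = lo - d; return 0.5 * k * x * x; }
  if (d > up) { double x = d - up; return 0.5 * k * x * x; }
  return 0.0;
}

// returns total energy; writes the contact-restraint component to *e_rest
static double total_energy(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z,
                           const IntegerVector& ri, const IntegerVector& rj,
                           const NumericVector& rlo, const NumericVector& rup,
                           const IntegerVector& bi, const IntegerVector& bj,
                           const NumericVector& blo, const NumericVector& bup,
                           double k_rest, double k_bb, double k_rep,
                           double rep_dist, double* e_rest,
                           const std::unordered_set<long long>& excl) {
  const int n = x.size();
  double e = 0.0;
  for (int t = 0; t < ri.size(); ++t) {
    int i = ri[t], j = rj[t];
    double dx = x[j]-x[i], dy = y[j]-y[i], dz = z[j]-z[i];
    e += flat_bottom_energy(std::sqrt(dx*dx+dy*dy+dz*dz), rlo[t], rup[t], k_rest);
  }
  *e_rest = e;
  for (int t = 0; t < bi.size(); ++t) {
    int i = bi[t], j = bj[t];
    double dx = x[j]-x[i], dy = y[j]-y[i], dz = z[j]-z[i];
    e += flat_bottom_energy(std::sqrt(dx*dx+dy*dy+dz*dz), blo[t], bup[t], k_bb);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j]-x[i], dy = y[j]-y[i], dz = z[j]-z[i];
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 < rep_dist * rep_dist) {
        if (excl.count(static_cast<long long>(i) * n + j)) continue;
        double d = std::sqrt(d2);
        double xx = rep_dist - d;
        e += 0.5 * k_rep * xx * xx;
      }
    }
  }
  return e;
}

static inline void add_pair_force(std::vector<double>& fx, std::vector<double>& fy,
                                  std::vector<double>& fz,
                                  const std::vector<double>& x,
                                  const std::vector<double>& y,
                                  const std::vector<double>& z,
                                  int i, int j, double lo, double up, double k,
                                  std::mt19937& gen) {
  double dx = x[j]-x[i], dy = y[j]-y[i], dz = z[j]-z[i];
  double d = std::sqrt(dx*dx+dy*dy+dz*dz);
  double mag = 0.0; // >0 pulls together, <0 pushes apart
  if (d > up) mag = k * (d - up);
  else if (d < lo) mag = -k * (lo - d);
  else return;
  double ux, uy, uz;
  if (d < 1e-12) { // coincident particles: random push direction
    std::normal_distribution<double> nd(0.0, 1.0);
    ux = nd(gen); uy = nd(gen); uz = nd(gen);
    double nn = std::sqrt(ux*ux+uy*uy+uz*uz) + 1e-12;
    ux /= nn; uy /= nn; uz /= nn;
  } else {
    ux = dx / d; uy = dy / d; uz = dz / d;
  }
  fx[i] += mag * ux; fy[i] += mag * uy; fz[i] += mag * uz;
  fx[j] -= mag * ux; fy[j] -= mag * uy; fz[j] -= mag * uz;
}

// [[Rcpp::export]]
List anneal_stage_cpp(NumericMatrix coords,
                      IntegerVector ri, IntegerVector rj,
                      NumericVector rlo, NumericVector rup,
                      IntegerVector bi, IntegerVector bj,
                      NumericVector blo, NumericVector bup,
                      NumericVector temps, int steps_per_temp,
                      double k_rest, double k_bb, double k_rep,
                      double rep_dist, double dt, double max_step,
                      double noise_scale, int seed) {
  const int n = coords.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i]=coords(i,0); y[i]=coords(i,1); z[i]=coords(i,2); }
  std::mt19937 gen(static_cast<unsigned>(seed));
  std::normal_distribution<double> nd(0.0, 1.0);
  const std::unordered_set<long long> excl =
    restrained_pairs(ri, rj, bi, bj, n);
  double er0 = 0.0, er1 = 0.0;
  const double e_init = total_energy(x, y, z, ri, rj, rlo, rup, bi, bj, blo, bup,
                                     k_rest, k_bb, k_rep, rep_dist, &er0, excl);
  for (int ti = 0; ti < temps.size(); ++ti) {
    const double noise_sd = noise_scale * std::sqrt(dt * temps[ti]);
    for (int s = 0; s < steps_per_temp; ++s) {
      std::fill(fx.begin(), fx.end(), 0.0);
      std::fill(fy.begin(), fy.end(), 0.0);
      std::fill(fz.begin(), fz.end(), 0.0);
      for (int t = 0; t < ri.size(); ++t)
        add_pair_force(fx, fy, fz, x, y, z, ri[t], rj[t], rlo[t], rup[t], k_rest, gen);
      for (int t = 0; t < bi.size(); ++t)
        add_pair_force(fx, fy, fz, x, y, z, bi[t], bj[t], blo[t], bup[t], k_bb, gen);
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double dx = x[j]-x[i], dy = y[j]-y[i], dz = z[j]-z[i];
          double d2 = dx*dx+dy*dy+dz*dz;
          if (d2 < rep_dist * rep_dist) {
            if (excl.count(static_cast<long long>(i) * n + j)) continue;
            add_pair_force(fx, fy, fz, x, y, z, i, j, rep_dist, 1e30, k_rep, gen);
          }
        }
      }
      for (int i = 0; i < n; ++i) {
        double sx = dt * fx[i], sy = dt * fy[i], sz = dt * fz[i];
        if (noise_sd > 0.0) {
          sx += noise_sd * nd(gen); sy += noise_sd * nd(gen); sz += noise_sd * nd(gen);
        }
        double sn = std::sqrt(sx*sx+sy*sy+sz*sz);
        if (sn > max_step) { sx *= max_step/sn; sy *= max_step/sn; sz *= max_step/sn; }
        x[i] += sx; y[i] += sy; z[i] += sz;
        if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
          stop("non-finite coordinates during annealing (temp index %d)", ti);
      }
    }
  }
  const double e_final = total_energy(x, y, z, ri, rj, rlo, rup, bi, bj, blo, bup,
                                      k_rest, k_bb, k_rep, rep_dist, &er1, excl);
  if (!std::isfinite(e_final)) stop("non-finite energy after annealing");
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0)=x[i]; out(i,1)=y[i]; out(i,2)=z[i]; }
  return List::create(_["coords"] = out, _["e_init"] = e_init,
                      _["e_final"] = e_final, _["e_restraint"] = er1);
}
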