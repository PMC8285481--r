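// Potential-energy kernels and the steepest-descent loop.
//
// Units: the bead diameter a is the unit length. Terms:
//   backbone (adjacent beads, same chromosome): (k/2) (r - a)^2
//   contact pair (c != 0):  -2 ln r - (c/2) ln((r0-r)/(r0+r)) for r < 0.995 r0,
//     first-order Taylor extension anchored at 0.995 r0 beyond it
//   non-contact pair (c == 0): -2 ln r + s ln(1 + e^{-rate (r - r0)}) up to
//     the 3a plateau, constant beyond (zero force there)
//
// Total energy loops all i<j pairs as c = 0 and corrects the contacted pairs
// by (eps_c - eps_0); the plateau constant of far pairs is added analytically
// from the pair count, so the grid-accelerated path (cell size 3a) and the
// dense loop agree.
//
// Single-threaded throughout: results are bit-reproducible for a given input.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>

using namespace Rcpp;

struct EnergyPars {
  double a, r0, k, sexp, rate, tfrac, plateau;
};

static EnergyPars as_pars(const List &p) {
  EnergyPars e;
  e.a = as<double>(p["a"]);
  e.r0 = as<double>(p["r0"]);
  e.k = as<double>(p["k"]);
  e.sexp = as<double>(p["s_exponent"]);
  e.rate = as<double>(p["sigmoid_rate"]);
  e.tfrac = as<double>(p["taylor_fraction"]);
  e.plateau = as<double>(p["plateau_radius"]);
  return e;
}

// c == 0 term before the plateau cap
static inline double eps0_raw(double r, const EnergyPars &p) {
  return -2.0 * std::log(r) +
         p.sexp * std::log1p(std::exp(-p.rate * (r - p.r0)));
}

static inline double eps0(double r, const EnergyPars &p) {
  double rp = p.plateau * p.a;
  return (r <= rp) ? eps0_raw(r, p) : eps0_raw(rp, p);
}

static inline double deps0(double r, const EnergyPars &p) {
  double rp = p.plateau * p.a;
  if (r > rp) return 0.0;
  return -2.0 / r - p.sexp * p.rate / (1.0 + std::exp(p.rate * (r - p.r0)));
}

// c != 0 term in the regular region r < tfrac * r0
static inline double epsc_raw(double r, double c, const EnergyPars &p) {
  return -2.0 * std::log(r) -
         0.5 * c * std::log((p.r0 - r) / (p.r0 + r));
}

static inline double depsc_raw(double r, double c, const EnergyPars &p) {
  return -2.0 / r + c * p.r0 / (p.r0 * p.r0 - r * r);
}

static inline double epsc(double r, double c, const EnergyPars &p) {
  double rt = p.tfrac * p.r0;
  if (r < rt) return epsc_raw(r, c, p);
  return epsc_raw(rt, c, p) + depsc_raw(rt, c, p) * (r - rt);
}

static inline double depsc(double r, double c, const EnergyPars &p) {
  double rt = p.tfrac * p.r0;
  return (r < rt) ? depsc_raw(r, c, p) : depsc_raw(rt, c, p);
}

// [[Rcpp::export(name = ".eps_cont_cpp")]]
NumericVector eps_cont_cpp(NumericVector r, NumericVector c, List params) {
  EnergyPars p = as_pars(params);
  int n = r.size();
  NumericVector cc(n);
  for (int q = 0; q < n; ++q) cc[q] = c[q % c.size()];
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    if (!(r[q] > 0.0)) stop("epsilon_cont is singular at r = 0");
    out[q] = (cc[q] == 0.0) ? eps0(r[q], p) : epsc(r[q], cc[q], p);
  }
  return out;
}

// [[Rcpp::export(name = ".deps_cont_cpp")]]
NumericVector deps_cont_cpp(NumericVector r, NumericVector c, List params) {
  EnergyPars p = as_pars(params);
  int n = r.size();
  NumericVector cc(n);
  for (int q = 0; q < n; ++q) cc[q] = c[q % c.size()];
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    if (!(r[q] > 0.0)) stop("epsilon_cont is singular at r = 0");
    out[q] = (cc[q] == 0.0) ? deps0(r[q], p) : depsc(r[q], cc[q], p);
  }
  return out;
}

static inline double pair_dist(const NumericMatrix &X, int i, int j,
                               double *d) {
  d[0] = X(i, 0) - X(j, 0);
  d[1] = X(i, 1) - X(j, 1);
  d[2] = X(i, 2) - X(j, 2);
  return std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
}

// --- cell list (cell size = plateau radius) --------------------------------

struct CellList {
  double cell;
  double org[3];
  int dim[3];
  std::unordered_map<long long, std::vector<int>> cells;

  long long key(int cx, int cy, int cz) const {
    return (static_cast<long long>(cx) * dim[1] + cy) *
               static_cast<long long>(dim[2]) + cz;
  }

  void build(const NumericMatrix &X, double cell_size) {
    cell = cell_size;
    int n = X.nrow();
    for (int k = 0; k < 3; ++k) {
      double lo = X(0, k), hi = X(0, k);
      for (int i = 1; i < n; ++i) {
        if (X(i, k) < lo) lo = X(i, k);
        if (X(i, k) > hi) hi = X(i, k);
      }
      org[k] = lo;
      dim[k] = std::max(1, (int)std::floor((hi - lo) / cell) + 1);
    }
    cells.clear();
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor((X(i, 0) - org[0]) / cell);
      int cy = (int)std::floor((X(i, 1) - org[1]) / cell);
      int cz = (int)std::floor((X(i, 2) - org[2]) / cell);
      cells[key(cx, cy, cz)].push_back(i);
    }
  }

  // visit all unordered pairs (i, j) lying within `cell` of each other
  // (plus corner cases in adjacent cells); calls f(i, j) with i < j
  template <typename F> void for_pairs(const NumericMatrix &X, F f) const {
    for (const auto &kv : cells) {
      long long k = kv.first;
      int cz = (int)(k % dim[2]);
      long long t = k / dim[2];
      int cy = (int)(t % dim[1]);
      int cx = (int)(t / dim[1]);
      const std::vector<int> &A = kv.second;
      // within the cell
      for (size_t u = 0; u < A.size(); ++u)
        for (size_t v = u + 1; v < A.size(); ++v)
          f(std::min(A[u], A[v]), std::max(A[u], A[v]));
      // with the 13 forward neighbour cells
      static const int nb[13][3] = {
          {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
          {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
          {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
      for (int q = 0; q < 13; ++q) {
        int nx = cx + nb[q][0], ny = cy + nb[q][1], nz = cz + nb[q][2];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= dim[0] || ny >= dim[1] ||
            nz >= dim[2])
          continue;
        auto it = cells.find(key(nx, ny, nz));
        if (it == cells.end()) continue;
        const std::vector<int> &B = it->second;
        for (int ia : A)
          for (int ib : B)
            f(std::min(ia, ib), std::max(ia, ib));
      }
    }
  }
};

// --- energy ---------------------------------------------------------------

static double energy_impl(const NumericMatrix &X, const IntegerVector &b1,
                          const IntegerVector &b2, const IntegerVector &ci,
                          const IntegerVector &cj, const IntegerVector &cc,
                          const EnergyPars &p, bool use_grid) {
  int n = X.nrow();
  double d[3];
  double e = 0.0;
  for (int q = 0; q < b1.size(); ++q) {
    double r = pair_dist(X, b1[q], b2[q], d);
    double dr = r - p.a;
    e += 0.5 * p.k * dr * dr;
  }
  double rp = p.plateau * p.a;
  double plat = eps0_raw(rp, p);
  double npairs = (double)n * (n - 1) / 2.0;
  double acc = 0.0;
  if (use_grid) {
    CellList cl;
    cl.build(X, rp);
    cl.for_pairs(X, [&](int i, int j) {
      double dd[3];
      double r = pair_dist(X, i, j, dd);
      if (r <= rp) {
        if (!(r > 0.0)) stop("coincident beads %d and %d", i + 1, j + 1);
        acc += eps0_raw(r, p) - plat;
      }
    });
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double r = pair_dist(X, i, j, d);
        if (r <= rp) {
          if (!(r > 0.0)) stop("coincident beads %d and %d", i + 1, j + 1);
          acc += eps0_raw(r, p) - plat;
        }
      }
  }
  e += acc + npairs * plat;
  for (int q = 0; q < ci.size(); ++q) {
    double r = pair_dist(X, ci[q], cj[q], d);
    if (!(r > 0.0)) stop("coincident beads %d and %d", ci[q] + 1, cj[q] + 1);
    e += epsc(r, (double)cc[q], p) - eps0(r, p);
  }
  return e;
}

// [[Rcpp::export(name = ".total_energy_cpp")]]
double total_energy_cpp(NumericMatrix X, IntegerVector b1, IntegerVector b2,
                        IntegerVector ci, IntegerVector cj, IntegerVector cc,
                        List params, bool use_grid) {
  return energy_impl(X, b1, b2, ci, cj, cc, as_pars(params), use_grid);
}

static void forces_impl(const NumericMatrix &X, const IntegerVector &b1,
                        const IntegerVector &b2, const IntegerVector &ci,
                        const IntegerVector &cj, const IntegerVector &cc,
                        const EnergyPars &p, bool use_grid,
                        NumericMatrix &F) {
  int n = X.nrow();
  std::fill(F.begin(), F.end(), 0.0);
  double d[3];
  double rp = p.plateau * p.a;
  // f_i = -(d eps / d r) * (r_i - r_j) / r ; accumulate for i, negate for j
  auto add_pair = [&](int i, int j, double r, const double *dd,
                      double dedr) {
    double g = -dedr / r;
    F(i, 0) += g * dd[0];
    F(i, 1) += g * dd[1];
    F(i, 2) += g * dd[2];
    F(j, 0) -= g * dd[0];
    F(j, 1) -= g * dd[1];
    F(j, 2) -= g * dd[2];
  };
  for (int q = 0; q < b1.size(); ++q) {
    double r = pair_dist(X, b1[q], b2[q], d);
    if (!(r > 0.0))
      stop("coincident bonded beads %d and %d", b1[q] + 1, b2[q] + 1);
    add_pair(b1[q], b2[q], r, d, p.k * (r - p.a));
  }
  if (use_grid) {
    CellList cl;
    cl.build(X, rp);
    cl.for_pairs(X, [&](int i, int j) {
      double dd[3];
      double r = pair_dist(X, i, j, dd);
      if (r <= rp) {
        if (!(r > 0.0)) stop("coincident beads %d and %d", i + 1, j + 1);
        double g = -deps0(r, p) / r;
        F(i, 0) += g * dd[0];
        F(i, 1) += g * dd[1];
        F(i, 2) += g * dd[2];
        F(j, 0) -= g * dd[0];
        F(j, 1) -= g * dd[1];
        F(j, 2) -= g * dd[2];
      }
    });
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double r = pair_dist(X, i, j, d);
        if (r <= rp) {
          if (!(r > 0.0)) stop("coincident beads %d and %d", i + 1, j + 1);
          add_pair(i, j, r, d, deps0(r, p));
        }
      }
  }
  for (int q = 0; q < ci.size(); ++q) {
    double r = pair_dist(X, ci[q], cj[q], d);
    if (!(r > 0.0)) stop("coincident beads %d and %d", ci[q] + 1, cj[q] + 1);
    add_pair(ci[q], cj[q], r, d, depsc(r, (double)cc[q], p) - deps0(r, p));
  }
}

// [[Rcpp::export(name = ".forces_cpp")]]
NumericMatrix forces_cpp(NumericMatrix X, IntegerVector b1, IntegerVector b2,
                         IntegerVector ci, IntegerVector cj,
                         IntegerVector cc, List params, bool use_grid) {
  NumericMatrix F(X.nrow(), 3);
  forces_impl(X, b1, b2, ci, cj, cc, as_pars(params), use_grid, F);
  for (int i = 0; i < F.nrow(); ++i)
    for (int k = 0; k < 3; ++k)
      if (!std::isfinite(F(i, k)))
        stop("non-finite force on bead %d", i + 1);
  return F;
}

// --- descent --------------------------------------------------------------

// One stage of steepest descent: n_steps displacement updates of
// d_i = (step_factor * a / f_max) f_i, with the structure shrunk by
// (sum a / sum r)^shrink_exp over contacted pairs after every
// `shrink_every`-th step (0 = no shrinking). Returns the final coordinates
// and an energy trace sampled every `trace_every` steps (0 = none).
// [[Rcpp::export(name = ".descent_cpp")]]
List descent_cpp(NumericMatrix X0, IntegerVector b1, IntegerVector b2,
                 IntegerVector ci, IntegerVector cj, IntegerVector cc,
                 List params, int n_steps, int shrink_every,
                 double step_factor, double shrink_exp, bool use_grid,
                 int trace_every) {
  EnergyPars p = as_pars(params);
  NumericMatrix X = clone(X0);
  NumericMatrix F(X.nrow(), 3);
  std::vector<double> trace;
  double d[3];
  int n = X.nrow();
  for (int step = 1; step <= n_steps; ++step) {
    forces_impl(X, b1, b2, ci, cj, cc, p, use_grid, F);
    double fmax = 0.0;
    int badi = -1;
    for (int i = 0; i < n; ++i) {
      double f2 = F(i, 0) * F(i, 0) + F(i, 1) * F(i, 1) + F(i, 2) * F(i, 2);
      if (!std::isfinite(f2)) { badi = i; break; }
      double f = std::sqrt(f2);
      if (f > fmax) fmax = f;
    }
    if (badi >= 0) stop("non-finite force on bead %d", badi + 1);
    if (fmax > 0.0) {
      double s = step_factor * p.a / fmax;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) X(i, k) += s * F(i, k);
    }
    if (shrink_every > 0 && step % shrink_every == 0 && ci.size() > 0) {
      double sum_r = 0.0;
      for (int q = 0; q < ci.size(); ++q)
        sum_r += pair_dist(X, ci[q], cj[q], d);
      double fac = std::pow(ci.size() * p.a / sum_r, shrink_exp);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) X(i, k) *= fac;
    }
    if (trace_every > 0 && step % trace_every == 0)
      trace.push_back(energy_impl(X, b1, b2, ci, cj, cc, p, use_grid));
  }
  return List::create(_["coords"] = X, _["trace"] = wrap(trace));
}
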