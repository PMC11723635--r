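// Centre-based soft-sphere mechanics: pairwise linear repulsion on
// overlap, optional contact-inhibition force magnification, overdamped
// Euler motion, and iterative relaxation to mechanical equilibrium.
// Positions are in micrometres; forces in newtons.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Hash {
  // spatial hash with cell size = search radius
  double cell;
  double ox, oy, oz;
  int nx, ny, nz;
  std::unordered_map<long long, std::vector<int>> buckets;

  void build(const NumericMatrix& pos, double L) {
    cell = L;
    int n = pos.nrow();
    ox = oy = oz = 0.0;
    if (n > 0) {
      ox = pos(0, 0); oy = pos(0, 1); oz = pos(0, 2);
      for (int i = 1; i < n; ++i) {
        ox = std::min(ox, pos(i, 0));
        oy = std::min(oy, pos(i, 1));
        oz = std::min(oz, pos(i, 2));
      }
    }
    buckets.clear();
    buckets.reserve(n * 2 + 8);
    for (int i = 0; i < n; ++i) {
      buckets[key(pos(i, 0), pos(i, 1), pos(i, 2))].push_back(i);
    }
  }

  long long key(double x, double y, double z) const {
    long long cx = (long long)std::floor((x - ox) / cell);
    long long cy = (long long)std::floor((y - oy) / cell);
    long long cz = (long long)std::floor((z - oz) / cell);
    return ((cx + 1048576LL) << 42) ^ ((cy + 1048576LL) << 21) ^
           (cz + 1048576LL);
  }

  template <typename F>
  void neighbours(const NumericMatrix& pos, int i, F fun) const {
    long long cx = (long long)std::floor((pos(i, 0) - ox) / cell);
    long long cy = (long long)std::floor((pos(i, 1) - oy) / cell);
    long long cz = (long long)std::floor((pos(i, 2) - oz) / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          long long k = (((cx + dx) + 1048576LL) << 42) ^
                        (((cy + dy) + 1048576LL) << 21) ^
                        ((cz + dz) + 1048576LL);
          auto it = buckets.find(k);
          if (it == buckets.end()) continue;
          for (int j : it->second) fun(j);
        }
  }
};

// net forces (N) on every agent; returns total overlap through *total
void compute_forces(const NumericMatrix& pos, const NumericVector& radius,
                    const LogicalVector& mobile, double k1, double k2,
                    double L_nghbr, int N_max, double L_overlap,
                    NumericMatrix& F, IntegerVector& ncount,
                    double* total_overlap) {
  int n = pos.nrow();
  Hash hash;
  hash.build(pos, L_nghbr);
  double tot = 0.0;
  double L2 = L_nghbr * L_nghbr;
  for (int i = 0; i < n; ++i) {
    double fx = 0, fy = 0, fz = 0;
    int cnt = 1;  // includes self
    hash.neighbours(pos, i, [&](int j) {
      if (j == i) return;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > L2) return;
      ++cnt;
      double d = std::sqrt(d2);
      double delta = radius[i] + radius[j] - d;
      if (delta <= L_overlap) return;
      tot += 0.5 * delta;  // each pair visited from both ends
      double ux, uy, uz;
      if (d < 1e-9) {
        // coincident centres: deterministic jitter direction from R's RNG
        double a = unif_rand() * 2.0 * M_PI;
        double c = 2.0 * unif_rand() - 1.0;
        double s = std::sqrt(std::max(0.0, 1.0 - c * c));
        ux = s * std::cos(a); uy = s * std::sin(a); uz = c;
      } else {
        ux = dx / d; uy = dy / d; uz = dz / d;
      }
      double f = k1 * delta * 1e-6;  // um -> m
      fx += f * ux; fy += f * uy; fz += f * uz;
    });
    if (mobile[i] && cnt > N_max) {
      fx *= k2; fy *= k2; fz *= k2;
    }
    F(i, 0) = fx; F(i, 1) = fy; F(i, 2) = fz;
    ncount[i] = cnt;
  }
  *total_overlap = tot;
}

inline double voxel_M(const NumericVector& M_arr, const IntegerVector& dims,
                      double L_voxel, double x, double y, double z) {
  if (M_arr.size() == 0) return 0.0;
  int ix = (int)std::floor(x / L_voxel);
  int iy = (int)std::floor(y / L_voxel);
  int iz = (int)std::floor(z / L_voxel);
  ix = std::min(std::max(ix, 0), dims[0] - 1);
  iy = std::min(std::max(iy, 0), dims[1] - 1);
  iz = std::min(std::max(iz, 0), dims[2] - 1);
  return M_arr.at(ix + dims[0] * (iy + dims[1] * iz));
}

inline double reflect(double x, double side, double k4) {
  if (x < 0) x = std::min(k4 * (-x), side);
  else if (x > side) x = std::max(side - k4 * (x - side), 0.0);
  return x;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_net_forces")]]
List cpp_net_forces(NumericMatrix pos, NumericVector radius,
                    LogicalVector mobile, double k1, double k2,
                    double L_nghbr, int N_max, double L_overlap) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  IntegerVector ncount(n);
  double tot = 0.0;
  compute_forces(pos, radius, mobile, k1, k2, L_nghbr, N_max, L_overlap, F,
                 ncount, &tot);
  return List::create(_["forces"] = F, _["neigh_count"] = ncount,
                      _["total_overlap"] = tot);
}

// [[Rcpp::export(name = ".cpp_resolve")]]
List cpp_resolve(NumericMatrix pos, NumericVector radius,
                 LogicalVector mobile, NumericVector M_arr,
                 IntegerVector dims, double L_voxel, double side, double k1,
                 double k2, double mu, double dt, double L_nghbr, int N_max,
                 double L_overlap, double k4, int max_iters, double tol) {
  int n = pos.nrow();
  NumericMatrix p = clone(pos);
  NumericMatrix F(n, 3);
  IntegerVector ncount(n);
  NumericVector x0(n), y0(n), z0(n);
  for (int i = 0; i < n; ++i) {
    x0[i] = p(i, 0); y0[i] = p(i, 1); z0[i] = p(i, 2);
  }
  double overlap_first = NA_REAL, overlap_last = NA_REAL;
  double max_step_disp = 0.0;
  int iters = 0;
  GetRNGstate();
  while (iters < max_iters) {
    ++iters;
    double tot = 0.0;
    compute_forces(p, radius, mobile, k1, k2, L_nghbr, N_max, L_overlap, F,
                   ncount, &tot);
    if (iters == 1) overlap_first = tot;
    overlap_last = tot;
    double maxd = 0.0;
    for (int i = 0; i < n; ++i) {
      double M = voxel_M(M_arr, dims, L_voxel, p(i, 0), p(i, 1), p(i, 2));
      double fac = dt / (mu * (1.0 + M)) * 1e6;  // m -> um
      double dx = F(i, 0) * fac, dy = F(i, 1) * fac, dz = F(i, 2) * fac;
      double nx = reflect(p(i, 0) + dx, side, k4);
      double ny = reflect(p(i, 1) + dy, side, k4);
      double nz = reflect(p(i, 2) + dz, side, k4);
      double d = std::sqrt((nx - p(i, 0)) * (nx - p(i, 0)) +
                           (ny - p(i, 1)) * (ny - p(i, 1)) +
                           (nz - p(i, 2)) * (nz - p(i, 2)));
      if (d > maxd) maxd = d;
      p(i, 0) = nx; p(i, 1) = ny; p(i, 2) = nz;
    }
    if (maxd > max_step_disp) max_step_disp = maxd;
    if (maxd < tol) break;
  }
  PutRNGstate();
  NumericVector net(n);
  for (int i = 0; i < n; ++i) {
    double dx = p(i, 0) - x0[i], dy = p(i, 1) - y0[i], dz = p(i, 2) - z0[i];
    net[i] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return List::create(
      _["positions"] = p, _["iters"] = iters,
      _["max_step_disp"] = max_step_disp, _["net_disp"] = net,
      _["neigh_count"] = ncount, _["total_overlap_first"] = overlap_first,
      _["total_overlap_last"] = overlap_last);
}
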