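// Brownian-dynamics chemistry for one spur (a spatially isolated group
// of radiolysis species).
//
// Pairwise radical-radical reactions follow the step-by-step scheme:
// particles diffuse, a pair reacts when its separation falls below the
// Smoluchowski radius R derived from the rate table, and a Brownian
// bridge correction P = exp(-(d0-R)(d1-R)/(D' dt)) accounts for
// crossings of R inside a step.  The adaptive time step shrinks as
// reactive pairs approach so encounters are resolved.  Species-DNA encounters (deoxyribose, base, histone)
// are first-order channels whose rates depend on the chromatin class of
// the voxel the radical currently occupies.  The time step adapts to the
// closest reactive pair.  An optional periodic box supports well-mixed
// benchmark kinetics.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Sp {
  double x, y, z;
  int type;
  bool alive;
};

inline double pdist2(const Sp& a, const Sp& b, double box) {
  double dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
  if (box > 0) {
    dx -= box * std::round(dx / box);
    dy -= box * std::round(dy / box);
    dz -= box * std::round(dz / box);
  }
  return dx * dx + dy * dy + dz * dz;
}

} // namespace

// [[Rcpp::export]]
List cpp_chemistry_spur(NumericMatrix pos0,
                        IntegerVector type0,
                        NumericVector Dcoef,
                        NumericMatrix Rpair,
                        IntegerMatrix prod1,
                        IntegerMatrix prod2,
                        IntegerMatrix prod3,
                        NumericMatrix rate_dr,
                        NumericMatrix rate_base,
                        NumericMatrix rate_hist,
                        IntegerVector lattice,
                        IntegerVector dims,
                        NumericVector origin_nm,
                        double voxel_nm,
                        IntegerVector vox_class,
                        double end_time_ns,
                        double dt_min,
                        double dt_max,
                        double periodic_box_nm) {
  const int ntype = Dcoef.size();
  std::vector<Sp> sp;
  for (int i = 0; i < pos0.nrow(); ++i) {
    Sp s; s.x = pos0(i, 0); s.y = pos0(i, 1); s.z = pos0(i, 2);
    s.type = type0[i]; s.alive = true;
    sp.push_back(s);
  }
  const double box = periodic_box_nm;

  std::vector<double> enc_t, enc_x, enc_y, enc_z;
  std::vector<int> enc_type, enc_target, enc_vox;
  std::vector<double> rx_t;
  std::vector<int> rx_a, rx_b;

  // chromatin class (0 none, 1 eu, 2 het) and voxel row at a position
  auto class_at = [&](double x, double y, double z, int* vox_out) -> int {
    *vox_out = 0;
    if (dims.size() != 3 || dims[0] == 0) return 0;
    int ix = (int)std::floor((x - origin_nm[0]) / voxel_nm);
    int iy = (int)std::floor((y - origin_nm[1]) / voxel_nm);
    int iz = (int)std::floor((z - origin_nm[2]) / voxel_nm);
    if (ix < 0 || ix >= dims[0] || iy < 0 || iy >= dims[1] ||
        iz < 0 || iz >= dims[2]) return 0;
    int row = lattice[ix + dims[0] * (iy + dims[1] * iz)];
    if (row == 0) return 0;
    *vox_out = row;
    return vox_class[row - 1];
  };

  double t = 0.0;
  int guard = 0;
  while (t < end_time_ns) {
    if (++guard > 2000000) stop("chemistry step budget exceeded");
    // skip the pair machinery entirely when no present pair of types
    // can react (e.g. pure-diffusion benchmarks)
    std::vector<int> tcount(ntype, 0);
    int nalive = 0;
    double Dmax = 0.0;
    for (size_t i = 0; i < sp.size(); ++i) {
      if (!sp[i].alive) continue;
      ++nalive;
      tcount[sp[i].type]++;
      if (Dcoef[sp[i].type] > Dmax) Dmax = Dcoef[sp[i].type];
    }
    if (nalive == 0) break;
    bool any_react = false;
    for (int a = 0; a < ntype && !any_react; ++a) {
      if (!tcount[a]) continue;
      for (int b = a; b < ntype; ++b) {
        if (!tcount[b] || (a == b && tcount[a] < 2)) continue;
        if (Rpair(a, b) > 0) { any_react = true; break; }
      }
    }
    // adaptive dt from the closest reactive pair
    double dmin = 1e30;
    if (any_react) {
      for (size_t i = 0; i < sp.size(); ++i) {
        if (!sp[i].alive) continue;
        for (size_t j = i + 1; j < sp.size(); ++j) {
          if (!sp[j].alive) continue;
          double R = Rpair(sp[i].type, sp[j].type);
          if (R <= 0) continue;
          double g = std::sqrt(pdist2(sp[i], sp[j], box)) - R;
          if (g < dmin) dmin = g;
        }
      }
    }
    double dt = dt_max;
    if (dmin < 1e29) {
      double cand = (dmin / 4.0) * (dmin / 4.0) / (4.0 * (2.0 * Dmax) + 1e-12);
      dt = std::min(dt_max, std::max(dt_min, cand));
    }
    if (t + dt > end_time_ns) dt = end_time_ns - t;
    if (dt <= 0) break;

    // remember pre-step positions, then diffuse
    std::vector<Sp> old(sp);
    for (size_t i = 0; i < sp.size(); ++i) {
      if (!sp[i].alive) continue;
      double s = std::sqrt(2.0 * Dcoef[sp[i].type] * dt);
      sp[i].x += R::rnorm(0.0, s);
      sp[i].y += R::rnorm(0.0, s);
      sp[i].z += R::rnorm(0.0, s);
      if (box > 0) {
        sp[i].x -= box * std::floor(sp[i].x / box);
        sp[i].y -= box * std::floor(sp[i].y / box);
        sp[i].z -= box * std::floor(sp[i].z / box);
      }
    }

    // pairwise reactions: contact at step end, or bridge crossing
    size_t nold = old.size();
    for (size_t i = 0; any_react && i < nold; ++i) {
      if (!sp[i].alive) continue;
      for (size_t j = i + 1; j < nold; ++j) {
        if (!sp[i].alive) break;
        if (!sp[j].alive) continue;
        double R = Rpair(sp[i].type, sp[j].type);
        if (R <= 0) continue;
        double Dp = Dcoef[sp[i].type] + Dcoef[sp[j].type];
        double d1 = std::sqrt(pdist2(sp[i], sp[j], box));
        bool hit = d1 <= R;
        if (!hit) {
          double d0 = std::sqrt(pdist2(old[i], old[j], box));
          if (d0 - R < 8.0 * std::sqrt(2.0 * Dp * dt)) {
            double Pb = std::exp(-(d0 - R) * (d1 - R) / (Dp * dt));
            hit = R::runif(0.0, 1.0) < Pb;
          }
        }
        if (hit) {
          int ta = sp[i].type, tb = sp[j].type;
          double mx = 0.5 * (sp[i].x + sp[j].x);
          double my = 0.5 * (sp[i].y + sp[j].y);
          double mz = 0.5 * (sp[i].z + sp[j].z);
          sp[i].alive = false; sp[j].alive = false;
          rx_t.push_back(t + dt); rx_a.push_back(ta); rx_b.push_back(tb);
          int pr[3] = { prod1(ta, tb), prod2(ta, tb), prod3(ta, tb) };
          for (int q = 0; q < 3; ++q) {
            if (pr[q] >= 0) {
              Sp np; np.x = mx; np.y = my; np.z = mz;
              np.type = pr[q]; np.alive = true;
              sp.push_back(np);
            }
          }
        }
      }
    }

    // first-order DNA channels
    for (size_t i = 0; i < sp.size(); ++i) {
      if (!sp[i].alive) continue;
      int vox = 0;
      int cls = class_at(sp[i].x, sp[i].y, sp[i].z, &vox);
      if (cls == 0) continue;
      int ty = sp[i].type;
      double rdr = rate_dr(ty, cls);
      double rb = rate_base(ty, cls);
      double rh = rate_hist(ty, cls);
      double rtot = rdr + rb + rh;
      if (rtot <= 0) continue;
      if (R::runif(0.0, 1.0) < 1.0 - std::exp(-rtot * dt)) {
        double u = R::runif(0.0, 1.0) * rtot;
        int target = (u < rdr) ? 0 : (u < rdr + rb ? 1 : 2);
        enc_t.push_back(t + dt); enc_type.push_back(ty);
        enc_target.push_back(target); enc_vox.push_back(vox);
        enc_x.push_back(sp[i].x); enc_y.push_back(sp[i].y);
        enc_z.push_back(sp[i].z);
        sp[i].alive = false;
      }
    }

    t += dt;
  }

  int nsurv = 0;
  for (auto& s : sp) if (s.alive) ++nsurv;
  NumericMatrix surv(nsurv, 4);
  int k = 0;
  for (auto& s : sp) {
    if (!s.alive) continue;
    surv(k, 0) = s.x; surv(k, 1) = s.y; surv(k, 2) = s.z; surv(k, 3) = s.type;
    ++k;
  }
  int ne = enc_t.size();
  NumericMatrix enc(ne, 7);
  for (int i = 0; i < ne; ++i) {
    enc(i, 0) = enc_t[i]; enc(i, 1) = enc_type[i]; enc(i, 2) = enc_target[i];
    enc(i, 3) = enc_x[i]; enc(i, 4) = enc_y[i]; enc(i, 5) = enc_z[i];
    enc(i, 6) = enc_vox[i];
  }
  int nr = rx_t.size();
  NumericMatrix rx(nr, 3);
  for (int i = 0; i < nr; ++i) {
    rx(i, 0) = rx_t[i]; rx(i, 1) = rx_a[i]; rx(i, 2) = rx_b[i];
  }
  (void)ntype;
  return List::create(_["encounters"] = enc, _["reactions"] = rx,
                      _["survivors"] = surv);
}
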