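// Table-driven track-structure electron walk in liquid water.
//
// Alternates exponential free flights (effective inelastic mean free path)
// with inelastic events (excitation or ionization).  Ionizations eject a
// secondary; secondaries above `delta_branch_eV` are transported as
// branches of the same track, smaller ones deposit at the parent site.
// Elastic deflection uses a screened-Rutherford angular model applied at
// each inelastic event (compounded at sub-keV energies).  Energy is conserved exactly: deposited site
// energies plus energy escaping the bounding box sum to the start energy.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

double interp_loglog(double e, const NumericVector& logE,
                     const NumericVector& logY) {
  const int n = logE.size();
  double le = std::log(e);
  if (le <= logE[0]) le = logE[0];
  if (le >= logE[n - 1]) le = logE[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (logE[mid] <= le) lo = mid; else hi = mid;
  }
  double t = (le - logE[lo]) / (logE[hi] - logE[lo]);
  return std::exp(logY[lo] + t * (logY[hi] - logY[lo]));
}

struct Particle {
  double x, y, z;    // nm
  double ux, uy, uz; // unit direction
  double E;          // eV
  bool primary;
};

void rotate_direction(Particle& p, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double ux = p.ux, uy = p.uy, uz = p.uz;
  double nx, ny, nz;
  if (std::fabs(uz) < 0.99999) {
    double s = std::sqrt(1.0 - uz * uz);
    nx = sint * (ux * uz * cphi - uy * sphi) / s + ux * cost;
    ny = sint * (uy * uz * cphi + ux * sphi) / s + uy * cost;
    nz = -sint * cphi * s + uz * cost;
  } else {
    // beam along +/- z: rotate about z directly
    nx = sint * cphi;
    ny = sint * sphi;
    nz = (uz > 0 ? cost : -cost);
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  p.ux = nx / norm; p.uy = ny / norm; p.uz = nz / norm;
}

bool in_box(const Particle& p, const NumericVector& bbox) {
  return p.x >= bbox[0] && p.x <= bbox[1] &&
         p.y >= bbox[2] && p.y <= bbox[3] &&
         p.z >= bbox[4] && p.z <= bbox[5];
}

} // namespace

// [[Rcpp::export]]
List cpp_transport_electron(double E0_eV,
                            NumericVector pos0_nm,
                            NumericVector dir0,
                            double cut_eV,
                            NumericVector logE_grid,
                            NumericVector log_lambda_nm,
                            NumericVector bbox_nm,
                            double p_excitation,
                            double delta_branch_eV,
                            double screening_const,
                            int max_sites) {
  std::vector<double> sx, sy, sz, se;
  std::vector<int> skind; // 1 ionization, 2 excitation, 3 sub-cut termination
  double escape = 0.0;
  double primary_path = 0.0;

  std::vector<Particle> stack;
  {
    Particle p;
    p.x = pos0_nm[0]; p.y = pos0_nm[1]; p.z = pos0_nm[2];
    double n0 = std::sqrt(dir0[0] * dir0[0] + dir0[1] * dir0[1] +
                          dir0[2] * dir0[2]);
    p.ux = dir0[0] / n0; p.uy = dir0[1] / n0; p.uz = dir0[2] / n0;
    p.E = E0_eV;
    p.primary = true;
    stack.push_back(p);
  }

  const double T0 = 15.0;   // eV, shape parameter of the delta-ray spectrum
  const double B_lo = 10.0, B_hi = 30.0;  // effective ionization potentials

  while (!stack.empty()) {
    Particle p = stack.back();
    stack.pop_back();

    while (p.E >= cut_eV) {
      if ((int)sx.size() >= max_sites) stop("site budget exceeded");
      // free flight
      double lambda = interp_loglog(p.E, logE_grid, log_lambda_nm);
      double step = -lambda * std::log(R::runif(0.0, 1.0));
      p.x += step * p.ux; p.y += step * p.uy; p.z += step * p.uz;
      if (p.primary) primary_path += step;
      if (!in_box(p, bbox_nm)) { escape += p.E; p.E = 0.0; break; }

      // inelastic event
      double eps_site, eps_loss;
      int kind;
      if (R::runif(0.0, 1.0) < p_excitation) {
        kind = 2;
        eps_loss = R::runif(8.0, 13.0);
        if (eps_loss > p.E) eps_loss = p.E;
        eps_site = eps_loss;
      } else {
        kind = 1;
        double B = R::runif(B_lo, B_hi);
        if (B >= p.E) { B = p.E; }
        double Tm = (p.E - B) / 2.0;
        double T = 0.0;
        if (Tm > 0.0) {
          double u = R::runif(0.0, 1.0);
          double inv = 1.0 / T0 - u * (1.0 / T0 - 1.0 / (Tm + T0));
          T = 1.0 / inv - T0;
          if (T < 0.0) T = 0.0;
          if (T > Tm) T = Tm;
        }
        eps_loss = B + T;
        if (T > delta_branch_eV) {
          // branch a secondary; its energy is carried, not deposited here
          Particle s = p;
          s.primary = false;
          double cs = std::sqrt(R::runif(0.0, 1.0));  // forward hemisphere
          rotate_direction(s, cs, R::runif(0.0, 2.0 * M_PI));
          s.E = T;
          stack.push_back(s);
          eps_site = B;
        } else {
          eps_site = B + T;
        }
      }
      sx.push_back(p.x); sy.push_back(p.y); sz.push_back(p.z);
      se.push_back(eps_site); skind.push_back(kind);
      p.E -= eps_loss;

      // elastic deflection (screened Rutherford, one effective sample)
      double tau = p.E / 511000.0;
      if (p.E > 0.0) {
        double eta = screening_const / (tau * (tau + 2.0));
        // compound several elastic deflections per inelastic event at low
        // energy, where the elastic/inelastic cross-section ratio is large
        int n_el = 1 + (int)std::floor(2.5 * std::exp(-p.E / 300.0));
        for (int j = 0; j < n_el; ++j) {
          double u = R::runif(0.0, 1.0);
          double cost = 1.0 - 2.0 * eta * u / (1.0 + eta - u);
          if (cost < -1.0) cost = -1.0;
          rotate_direction(p, cost, R::runif(0.0, 2.0 * M_PI));
        }
      }
    }
    if (p.E > 0.0 && p.E < cut_eV) {
      // residual energy below the tracking cut deposits locally
      sx.push_back(p.x); sy.push_back(p.y); sz.push_back(p.z);
      se.push_back(p.E); skind.push_back(3);
    }
  }

  const int n = sx.size();
  NumericMatrix sites(n, 4);
  IntegerVector kindv(n);
  for (int i = 0; i < n; ++i) {
    sites(i, 0) = sx[i]; sites(i, 1) = sy[i]; sites(i, 2) = sz[i];
    sites(i, 3) = se[i]; kindv[i] = skind[i];
  }
  return List::create(_["sites"] = sites, _["kind"] = kindv,
                      _["escape_eV"] = escape,
                      _["primary_path_nm"] = primary_path);
}
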