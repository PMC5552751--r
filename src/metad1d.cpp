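// 1D Langevin (BAOAB) integrator with optional on-the-fly well-tempered
// metadynamics on the particle position. The bias and its derivative are
// accumulated on a grid at each deposition, so per-step cost is independent
// of the number of kernels. Units: A, ps, kcal/mol, K, amu.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 0.0019872041;   // kcal/mol/K
static const double F2A = 418.4;         // kcal/mol -> amu A^2/ps^2

// [[Rcpp::export]]
List cpp_metad_1d(double x0, double v0, double mass, double dt, double friction,
                  double temperature, double nsteps_d,
                  double barrier, double spacing,
                  double h0, int deposit_stride, double deltaT,
                  int adaptive_steps, double width_floor, double fixed_width,
                  double grid_min, double grid_max, int grid_n,
                  int sample_stride) {
  long long nsteps = (long long)nsteps_d;
  double kT = KB * temperature * F2A;
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);
  double dg = (grid_max - grid_min) / (grid_n - 1);

  std::vector<double> vgrid(grid_n, 0.0), dgrid(grid_n, 0.0);

  // linear interpolation of the bias and its derivative on the grid
  auto bias_at = [&](double x, double &dvdx) -> double {
    if (x <= grid_min) { dvdx = 0.0; return vgrid[0]; }
    if (x >= grid_max) { dvdx = 0.0; return vgrid[grid_n - 1]; }
    double u = (x - grid_min) / dg;
    int i = (int)u;
    double f = u - i;
    dvdx = (1.0 - f) * dgrid[i] + f * dgrid[i + 1];
    return (1.0 - f) * vgrid[i] + f * vgrid[i + 1];
  };

  auto phys_force = [&](double x) -> double {
    double u = x / spacing;
    return -4.0 * barrier * x * (u * u - 1.0) / (spacing * spacing);
  };

  std::vector<double> k_time, k_center, k_width, k_height;
  std::vector<double> s_time, s_x, s_v, s_bias;

  // ring buffer of recent CV values for the adaptive width
  std::vector<double> ring(std::max(adaptive_steps, 1), x0);
  int ring_pos = 0;
  long long ring_fill = 0;

  RNGScope scope;
  double x = x0, v = v0;
  double dvdx = 0.0, vb = 0.0;
  vb = bias_at(x, dvdx);
  double f = phys_force(x) - dvdx;

  for (long long s = 1; s <= nsteps; ++s) {
    v += 0.5 * dt * f * F2A / mass;
    x += 0.5 * dt * v;
    v = c1 * v + c2 * norm_rand();
    x += 0.5 * dt * v;
    vb = bias_at(x, dvdx);
    f = phys_force(x) - dvdx;
    v += 0.5 * dt * f * F2A / mass;

    if (adaptive_steps > 0) {
      ring[ring_pos] = x;
      ring_pos = (ring_pos + 1) % ring.size();
      ring_fill++;
    }

    if (h0 > 0.0 && deposit_stride > 0 && s % deposit_stride == 0) {
      double width = fixed_width;
      if (width <= 0.0) {
        size_t nfill = (size_t)std::min<long long>(ring_fill, (long long)ring.size());
        double mu = 0.0, ss = 0.0;
        for (size_t i = 0; i < nfill; ++i) mu += ring[i];
        mu /= nfill;
        for (size_t i = 0; i < nfill; ++i) ss += (ring[i] - mu) * (ring[i] - mu);
        width = nfill > 1 ? std::sqrt(ss / (nfill - 1)) : 0.0;
      }
      if (width < width_floor) width = width_floor;
      double dtmp;
      double vhere = bias_at(x, dtmp);
      double height = deltaT > 0.0 ? h0 * std::exp(-vhere / (KB * deltaT)) : h0;
      for (int i = 0; i < grid_n; ++i) {
        double g = grid_min + i * dg;
        double dxg = (g - x) / width;
        double e = height * std::exp(-0.5 * dxg * dxg);
        vgrid[i] += e;
        dgrid[i] += -e * (g - x) / (width * width);
      }
      vb = bias_at(x, dvdx);
      f = phys_force(x) - dvdx;
      k_time.push_back(s * dt);
      k_center.push_back(x);
      k_width.push_back(width);
      k_height.push_back(height);
    }

    if (sample_stride > 0 && s % sample_stride == 0) {
      s_time.push_back(s * dt);
      s_x.push_back(x);
      s_v.push_back(v);
      s_bias.push_back(vb);
    }
    if (s % 1000000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["kernels"] = DataFrame::create(_["time"] = k_time, _["center"] = k_center,
                                     _["width"] = k_width, _["height"] = k_height),
    _["samples"] = DataFrame::create(_["time"] = s_time, _["x"] = s_x,
                                     _["v"] = s_v, _["bias"] = s_bias),
    _["vgrid"] = NumericVector(vgrid.begin(), vgrid.end()),
    _["grid"] = NumericVector::create(grid_min, grid_max, (double)grid_n),
    _["x"] = x, _["v"] = v);
}
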