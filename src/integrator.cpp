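#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin / metadynamics engine on a sum-of-Gaussian-wells
// landscape with a soft harmonic confinement wall.
//
// Beads: a rigid two-probe ligand (CF3 probe + O1 probe). bond_length == 0
// switches to point-ligand mode (single probe, o1 mirrors cf3).
//
// Well bead codes: 0 = acts on every bead, 1 = CF3 probe only, 2 = O1 only.
// In point mode every well acts once on the single probe.
//
// Noise is drawn from R's RNG (norm_rand) so set.seed() on the R side fixes
// the trajectory bit-for-bit.

static inline double sq(double x) { return x * x; }

// accumulate -grad U_wells(x) for a bead; also return U if wanted
static void well_force(const NumericMatrix& wc, const NumericVector& wd,
                       const NumericVector& ww, const IntegerVector& wb,
                       int bead_code, bool point_mode,
                       const std::vector<double>& x, std::vector<double>& f) {
  const int d = x.size(), nw = wd.size();
  for (int w = 0; w < nw; ++w) {
    if (!point_mode && wb[w] != 0 && wb[w] != bead_code) continue;
    double r2 = 0.0;
    for (int j = 0; j < d; ++j) r2 += sq(x[j] - wc(w, j));
    const double w2 = sq(ww[w]);
    const double g = wd[w] * std::exp(-r2 / (2.0 * w2)) / w2; // |dU/dx| factor
    for (int j = 0; j < d; ++j) f[j] -= g * (x[j] - wc(w, j));
  }
}

static void wall_force(double wall_radius, double wall_k,
                       const std::vector<double>& x, std::vector<double>& f) {
  const int d = x.size();
  double r2 = 0.0;
  for (int j = 0; j < d; ++j) r2 += sq(x[j]);
  const double r = std::sqrt(r2);
  if (r > wall_radius && r > 0.0) {
    const double g = wall_k * (r - wall_radius) / r;
    for (int j = 0; j < d; ++j) f[j] -= g * x[j];
  }
}

// [[Rcpp::export]]
List cpp_run_dynamics(NumericMatrix well_center, NumericVector well_depth,
                      NumericVector well_width, IntegerVector well_bead,
                      double wall_radius, double wall_k,
                      NumericVector cf3_start, NumericVector o1_start,
                      double bond_length,
                      double kBT, double friction, double dt,
                      int n_steps, int save_stride,
                      bool do_metad, NumericVector anchor_centroid,
                      double hill_h0, double hill_w, int hill_stride,
                      bool tempered, double bias_factor) {
  const int d = cf3_start.size();
  const bool point_mode = (bond_length == 0.0);
  const int n_frames = n_steps / save_stride + 1;

  std::vector<double> cf3(cf3_start.begin(), cf3_start.end());
  std::vector<double> o1(o1_start.begin(), o1_start.end());
  std::vector<double> fcf3(d), fo1(d), cen(d);

  NumericMatrix out_cf3(n_frames, d), out_o1(n_frames, d);
  NumericVector out_t(n_frames);
  std::vector<double> h_time, h_center, h_height;
  if (do_metad) {
    const int nh = n_steps / hill_stride + 1;
    h_time.reserve(nh); h_center.reserve(nh); h_height.reserve(nh);
  }

  const double mob = dt / friction;
  const double noise = std::sqrt(2.0 * kBT * dt / friction);
  const double inv2w2 = do_metad ? 1.0 / (2.0 * hill_w * hill_w) : 0.0;

  // bias potential tabulated on a dense CV grid: hill heights are computed
  // exactly from the hill list at deposition time, while per-step forces
  // interpolate the gridded bias (grid spacing << hill width)
  const double grid_h = 0.02;
  const double cv_max = wall_radius + 10.0;
  const int n_grid = do_metad ? (int)(cv_max / grid_h) + 2 : 0;
  std::vector<double> vgrid(n_grid, 0.0);

  int frame = 0;
  auto save_frame = [&](int step) {
    out_t[frame] = step * dt;
    for (int j = 0; j < d; ++j) {
      out_cf3(frame, j) = cf3[j];
      out_o1(frame, j) = point_mode ? cf3[j] : o1[j];
    }
    ++frame;
  };

  auto cv_value = [&]() {
    double r2 = 0.0;
    for (int j = 0; j < d; ++j) {
      cen[j] = point_mode ? cf3[j] : 0.5 * (cf3[j] + o1[j]);
      r2 += sq(cen[j] - anchor_centroid[j]);
    }
    return std::sqrt(r2);
  };

  auto bias_at = [&](double s) {
    double v = 0.0;
    for (size_t h = 0; h < h_height.size(); ++h)
      v += h_height[h] * std::exp(-sq(s - h_center[h]) * inv2w2);
    return v;
  };

  save_frame(0);

  for (int step = 1; step <= n_steps; ++step) {
    std::fill(fcf3.begin(), fcf3.end(), 0.0);
    std::fill(fo1.begin(), fo1.end(), 0.0);

    well_force(well_center, well_depth, well_width, well_bead, 1, point_mode,
               cf3, fcf3);
    wall_force(wall_radius, wall_k, cf3, fcf3);
    if (!point_mode) {
      well_force(well_center, well_depth, well_width, well_bead, 2, point_mode,
                 o1, fo1);
      wall_force(wall_radius, wall_k, o1, fo1);
    }

    if (do_metad && !h_height.empty()) {
      const double s = cv_value();
      if (s > 1e-12) {
        // dV/ds from central differences of the gridded bias
        double sc = s < grid_h ? grid_h : (s > cv_max ? cv_max : s);
        int i = (int)(sc / grid_h);
        if (i < 1) i = 1;
        if (i > n_grid - 3) i = n_grid - 3;
        const double f0 = (vgrid[i + 1] - vgrid[i - 1]) / (2.0 * grid_h);
        const double f1 = (vgrid[i + 2] - vgrid[i]) / (2.0 * grid_h);
        const double w1 = sc / grid_h - i;
        const double dv = (1.0 - w1) * f0 + w1 * f1;
        const double share = point_mode ? 1.0 : 0.5;
        for (int j = 0; j < d; ++j) {
          const double dsd = share * (cen[j] - anchor_centroid[j]) / s;
          fcf3[j] -= dv * dsd;
          if (!point_mode) fo1[j] -= dv * dsd;
        }
      }
    }

    for (int j = 0; j < d; ++j) {
      cf3[j] += mob * fcf3[j] + noise * norm_rand();
      if (!point_mode) o1[j] += mob * fo1[j] + noise * norm_rand();
    }

    if (!point_mode) {
      // rigid bond: restore |cf3 - o1| = bond_length about the midpoint
      double b2 = 0.0;
      for (int j = 0; j < d; ++j) b2 += sq(cf3[j] - o1[j]);
      const double b = std::sqrt(b2);
      if (b < 1e-12) stop("rigid-bond projection failed at step %d", step);
      const double scale = 0.5 * bond_length / b;
      for (int j = 0; j < d; ++j) {
        const double mid = 0.5 * (cf3[j] + o1[j]);
        const double v = cf3[j] - o1[j];
        cf3[j] = mid + scale * v;
        o1[j] = mid - scale * v;
      }
    }

    for (int j = 0; j < d; ++j)
      if (!std::isfinite(cf3[j]) || (!point_mode && !std::isfinite(o1[j])))
        stop("coordinates diverged (non-finite) at step %d", step);

    if (do_metad && step % hill_stride == 0) {
      const double s = cv_value();
      double h = hill_h0;
      if (tempered) h *= std::exp(-bias_at(s) / ((bias_factor - 1.0) * kBT));
      h_time.push_back(step * dt);
      h_center.push_back(s);
      h_height.push_back(h);
      // spread the new hill onto the grid (6 sigma support)
      const int lo = std::max(0, (int)((s - 6.0 * hill_w) / grid_h));
      const int hi = std::min(n_grid - 1, (int)((s + 6.0 * hill_w) / grid_h) + 1);
      for (int g = lo; g <= hi; ++g)
        vgrid[g] += h * std::exp(-sq(g * grid_h - s) * inv2w2);
    }

    if (step % save_stride == 0) save_frame(step);
  }

  return List::create(
      _["times"] = out_t, _["cf3"] = out_cf3, _["o1"] = out_o1,
      _["hill_time"] = wrap(h_time), _["hill_center"] = wrap(h_center),
      _["hill_height"] = wrap(h_height));
}
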