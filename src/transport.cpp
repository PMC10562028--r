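// Desk-scale kerma-approximation photon Monte Carlo engine.
//
// Physics: Woodcock (delta) tracking through the voxel phantom with a
// global energy-dependent majorant; at real interactions the type is
// sampled from the partial cross sections. Photoelectric deposits the full
// photon energy locally; Compton deposits E - E' (Klein-Nishina sampling by
// rejection) and continues the scattered photon; pair production above
// 1.022 MeV deposits E - 1.022 locally and emits two back-to-back 0.511 MeV
// annihilation photons. Photons below 10 keV are absorbed locally. No
// electron transport (kerma approximation).
//
// Reproducibility: every history h of a run draws from its own splitmix64
// stream keyed by (base_seed, global history index). Dose sums are
// therefore independent of how histories are partitioned into jobs, which
// makes split/merge equivalence exact up to floating-point addition order.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double MEC2 = 0.51099895;      // MeV
static const double E_CUTOFF = 0.010;       // MeV, local absorption below
static const double MEV_PER_G_TO_GY = 1.602176634e-10;

// ---- RNG: splitmix64, one stream per history --------------------------------
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { // in (0,1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) + 5.551115123125783e-17;
  }
};

static inline uint64_t mix_key(uint64_t a, uint64_t b) {
  Rng r(a * 0x9E3779B97F4A7C15ULL + 0x2545F4914F6CDD1DULL);
  r.s ^= b * 0xD6E8FEB86659FD93ULL;
  r.next();
  return r.next();
}

// ---- cross-section tables ----------------------------------------------------
struct MatXS {
  std::vector<double> log_e, log_mu, p_pe, p_pair;
  double le0, dle;
  double interp(const std::vector<double>& v, double loge) const {
    double f = (loge - le0) / dle;
    int n = (int)log_e.size();
    if (f <= 0) return v[0];
    if (f >= n - 1) return v[n - 1];
    int i = (int)f; double t = f - i;
    return v[i] * (1 - t) + v[i + 1] * t;
  }
  double mu_rho(double e) const { return std::exp(interp(log_mu, std::log(e))); }
};

// ---- Compton sampling ---------------------------------------------------------
// Rejection on cos(theta): weight eps^2 (eps + 1/eps - sin^2 theta) <= 2.
static inline void sample_compton(double e, Rng& rng, double& eprime,
                                  double& costh) {
  double a = e / MEC2;
  for (;;) {
    double mu = 2.0 * rng.unif() - 1.0;
    double eps = 1.0 / (1.0 + a * (1.0 - mu));
    double w = eps * eps * (eps + 1.0 / eps - (1.0 - mu * mu));
    if (rng.unif() * 2.0 < w) { eprime = e * eps; costh = mu; return; }
  }
}

// rotate unit vector d by polar angle (costh) about itself with azimuth phi
static inline void rotate_dir(double* d, double costh, double phi) {
  double sinth = std::sqrt(std::max(0.0, 1.0 - costh * costh));
  double u = d[0], v = d[1], w = d[2];
  double sp = std::sin(phi), cp = std::cos(phi);
  double norm = std::sqrt(u * u + v * v);
  if (norm > 1e-12) {
    d[0] = costh * u + sinth * (u * w * cp - v * sp) / norm;
    d[1] = costh * v + sinth * (v * w * cp + u * sp) / norm;
    d[2] = costh * w - sinth * norm * cp;
  } else {
    d[0] = sinth * cp; d[1] = sinth * sp; d[2] = (w > 0 ? costh : -costh);
  }
}

struct Segment {
  double src[3], xb[3], yb[3], iso[3];
  double rect[4];                       // sampling rectangle at iso plane
  std::vector<double> leaf_edges, leaf_a, leaf_b;
  double transmission;
  double h_lo, h_hi;                    // global history index range [lo, hi)
};

struct Photon { double pos[3], dir[3], e, wt; };

// [[Rcpp::export]]
List mc_run_cpp(IntegerVector mat, NumericVector dens, IntegerVector dims,
                NumericVector origin, NumericVector spacing, List xs_list,
                List seg_list, NumericVector spec_e, NumericVector spec_cdf,
                double base_seed, double hist_offset, double n_hist,
                bool attenuation_only) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<double> sum(nvox, 0.0), sumsq(nvox, 0.0);

  // geometry (mm)
  double lo[3], hi[3];
  for (int i = 0; i < 3; ++i) {
    lo[i] = origin[i] - spacing[i] / 2.0;
    hi[i] = lo[i] + dims[i] * spacing[i];
  }
  const double vol_cm3 = spacing[0] * spacing[1] * spacing[2] / 1000.0;

  // cross sections
  int nmat = xs_list.size();
  std::vector<MatXS> xs(nmat);
  for (int m = 0; m < nmat; ++m) {
    List e = xs_list[m];
    xs[m].log_e = as<std::vector<double>>(e["log_e"]);
    xs[m].log_mu = as<std::vector<double>>(e["log_mu"]);
    xs[m].p_pe = as<std::vector<double>>(e["p_pe"]);
    xs[m].p_pair = as<std::vector<double>>(e["p_pair"]);
    xs[m].le0 = xs[m].log_e.front();
    xs[m].dle = xs[m].log_e[1] - xs[m].log_e[0];
  }
  // max density per material actually present
  std::vector<double> dens_max(nmat, 0.0);
  for (R_xlen_t v = 0; v < nvox; ++v) {
    int m = mat[v] - 1;
    if (m >= 0 && m < nmat && dens[v] > dens_max[m]) dens_max[m] = dens[v];
  }
  // majorant mu(E) evaluator
  auto mu_majorant = [&](double e) {
    double mm = 0.0;
    for (int m = 0; m < nmat; ++m)
      if (dens_max[m] > 0) mm = std::max(mm, xs[m].mu_rho(e) * dens_max[m]);
    return mm;
  };

  // segments
  int nseg = seg_list.size();
  std::vector<Segment> segs(nseg);
  for (int s = 0; s < nseg; ++s) {
    List e = seg_list[s];
    NumericVector src = e["src"], xb = e["xb"], yb = e["yb"], iso = e["iso"],
      rect = e["rect"];
    for (int i = 0; i < 3; ++i) {
      segs[s].src[i] = src[i]; segs[s].xb[i] = xb[i];
      segs[s].yb[i] = yb[i]; segs[s].iso[i] = iso[i];
    }
    for (int i = 0; i < 4; ++i) segs[s].rect[i] = rect[i];
    segs[s].leaf_edges = as<std::vector<double>>(e["leaf_edges"]);
    segs[s].leaf_a = as<std::vector<double>>(e["leaf_a"]);
    segs[s].leaf_b = as<std::vector<double>>(e["leaf_b"]);
    segs[s].transmission = as<double>(e["transmission"]);
    segs[s].h_lo = as<double>(e["h_lo"]);
    segs[s].h_hi = as<double>(e["h_hi"]);
  }

  const int nspec = spec_e.size();
  uint64_t seed_u = (uint64_t)(int64_t)base_seed;

  double e_launched = 0.0, e_deposited = 0.0;
  double n_transmitted = 0.0, n_entered = 0.0;

  std::vector<std::pair<int, double>> hdep;
  hdep.reserve(64);
  std::vector<Photon> stack;
  stack.reserve(4);

  for (double hd = 0; hd < n_hist; hd += 1.0) {
    double h_global = hist_offset + hd;
    // find segment containing this global history index
    int si = -1;
    for (int s = 0; s < nseg; ++s)
      if (h_global >= segs[s].h_lo && h_global < segs[s].h_hi) { si = s; break; }
    if (si < 0) continue; // outside any segment (zero-MU tail)
    const Segment& sg = segs[si];

    Rng rng(mix_key(seed_u, (uint64_t)h_global));
    hdep.clear();

    // source sampling: energy then aim point on the iso-plane rectangle
    double u1 = rng.unif();
    int ie = 0;
    while (ie < nspec - 1 && u1 > spec_cdf[ie]) ++ie;
    double e0 = spec_e[ie];
    double ax = sg.rect[0] + rng.unif() * (sg.rect[1] - sg.rect[0]);
    double ay = sg.rect[2] + rng.unif() * (sg.rect[3] - sg.rect[2]);

    // ideal-aperture collimation at the iso plane
    double wt = 1.0;
    bool open = false;
    int np = (int)sg.leaf_a.size();
    if (np > 0 && ay >= sg.leaf_edges.front() && ay <= sg.leaf_edges.back()) {
      int p = (int)((ay - sg.leaf_edges.front()) /
                    (sg.leaf_edges.back() - sg.leaf_edges.front()) * np);
      if (p >= np) p = np - 1;
      // leaf edges may be non-uniform; correct by local search
      while (p > 0 && ay < sg.leaf_edges[p]) --p;
      while (p < np - 1 && ay > sg.leaf_edges[p + 1]) ++p;
      open = (ax >= sg.leaf_a[p] && ax <= sg.leaf_b[p]);
    }
    if (!open) wt *= sg.transmission;

    if (wt > 0 && e0 > 0) {
      // direction from source towards the aim point
      double aim[3], dir[3], pos[3], len = 0;
      for (int i = 0; i < 3; ++i) {
        aim[i] = sg.iso[i] + ax * sg.xb[i] + ay * sg.yb[i];
        dir[i] = aim[i] - sg.src[i];
        len += dir[i] * dir[i];
      }
      len = std::sqrt(len);
      for (int i = 0; i < 3; ++i) { dir[i] /= len; pos[i] = sg.src[i]; }
      e_launched += e0 * wt;

      stack.clear();
      Photon ph; for (int i = 0; i < 3; ++i) { ph.pos[i] = pos[i]; ph.dir[i] = dir[i]; }
      ph.e = e0; ph.wt = wt;
      stack.push_back(ph);
      bool primary = true, interacted = false, entered = false;

      while (!stack.empty()) {
        Photon p = stack.back(); stack.pop_back();
        // advance to phantom box
        double t0 = 0.0, t1 = 1e30;
        bool miss = false;
        for (int i = 0; i < 3; ++i) {
          if (std::fabs(p.dir[i]) < 1e-12) {
            if (p.pos[i] <= lo[i] || p.pos[i] >= hi[i]) { miss = true; break; }
          } else {
            double ta = (lo[i] - p.pos[i]) / p.dir[i];
            double tb = (hi[i] - p.pos[i]) / p.dir[i];
            if (ta > tb) std::swap(ta, tb);
            t0 = std::max(t0, ta); t1 = std::min(t1, tb);
          }
        }
        bool is_primary_here = primary; // only the first stack entry is primary
        primary = false;
        if (miss || t0 >= t1) continue;
        for (int i = 0; i < 3; ++i) p.pos[i] += (t0 + 1e-6) * p.dir[i];
        if (is_primary_here) entered = true;

        double mumax = mu_majorant(p.e); // cm^-1
        bool alive = true;
        while (alive) {
          double step_mm = -std::log(rng.unif()) / mumax * 10.0;
          for (int i = 0; i < 3; ++i) p.pos[i] += step_mm * p.dir[i];
          int ix = (int)std::floor((p.pos[0] - lo[0]) / spacing[0]);
          int iy = (int)std::floor((p.pos[1] - lo[1]) / spacing[1]);
          int iz = (int)std::floor((p.pos[2] - lo[2]) / spacing[2]);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
            if (is_primary_here && !interacted) n_transmitted += 1.0;
            break; // left the phantom
          }
          R_xlen_t v = (R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
          int m = mat[v] - 1;
          double mu_here = xs[m].mu_rho(p.e) * dens[v];
          if (rng.unif() * mumax >= mu_here) continue; // fictitious
          // real interaction
          if (is_primary_here) interacted = true;
          if (attenuation_only) break;
          double loge = std::log(p.e);
          double ppe = xs[m].interp(xs[m].p_pe, loge);
          double ppa = (p.e > 2 * MEC2) ? xs[m].interp(xs[m].p_pair, loge) : 0.0;
          double u = rng.unif();
          double dep = 0.0;
          if (u < ppe) {                       // photoelectric
            dep = p.e * p.wt; alive = false;
          } else if (u < ppe + ppa) {          // pair production
            dep = (p.e - 2 * MEC2) * p.wt;
            double d0[3];
            double ct = 2.0 * rng.unif() - 1.0, phi = 2 * M_PI * rng.unif();
            double st = std::sqrt(std::max(0.0, 1 - ct * ct));
            d0[0] = st * std::cos(phi); d0[1] = st * std::sin(phi); d0[2] = ct;
            Photon q;
            for (int i = 0; i < 3; ++i) { q.pos[i] = p.pos[i]; q.dir[i] = -d0[i]; }
            q.e = MEC2; q.wt = p.wt;
            stack.push_back(q);
            for (int i = 0; i < 3; ++i) p.dir[i] = d0[i];
            p.e = MEC2;
            mumax = mu_majorant(p.e);
          } else {                             // Compton
            double eprime, costh;
            sample_compton(p.e, rng, eprime, costh);
            dep = (p.e - eprime) * p.wt;
            rotate_dir(p.dir, costh, 2 * M_PI * rng.unif());
            p.e = eprime;
            if (p.e < E_CUTOFF) { dep += p.e * p.wt; alive = false; }
            else mumax = mu_majorant(p.e);
          }
          if (dep > 0) {
            double gy = dep * MEV_PER_G_TO_GY / (dens[v] * vol_cm3);
            hdep.push_back(std::make_pair((int)v, gy));
            e_deposited += dep;
          }
        }
      }
      if (entered) n_entered += 1.0;
    }

    // fold this history's deposits into sum / sum-of-squares
    if (!hdep.empty()) {
      std::sort(hdep.begin(), hdep.end());
      size_t i = 0;
      while (i < hdep.size()) {
        int v = hdep[i].first; double d = 0;
        while (i < hdep.size() && hdep[i].first == v) { d += hdep[i].second; ++i; }
        sum[v] += d; sumsq[v] += d * d;
      }
    }
  }

  return List::create(
    _["sum"] = NumericVector(sum.begin(), sum.end()),
    _["sumsq"] = NumericVector(sumsq.begin(), sumsq.end()),
    _["histories"] = n_hist,
    _["n_entered"] = n_entered,
    _["n_transmitted_primary"] = n_transmitted,
    _["energy_launched_mev"] = e_launched,
    _["energy_deposited_mev"] = e_deposited);
}

// Klein-Nishina sampler exposed for kinematics tests.
// [[Rcpp::export]]
NumericMatrix sample_compton_cpp(double e_mev, int n, double seed) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    Rng rng(mix_key((uint64_t)(int64_t)seed, (uint64_t)i));
    double ep, ct;
    sample_compton(e_mev, rng, ep, ct);
    out(i, 0) = ep; out(i, 1) = ct;
  }
  colnames(out) = CharacterVector::create("eprime", "costheta");
  return out;
}

// Package-internal deterministic uniform stream (seeded, independent of R's
// global RNG).
// [[Rcpp::export]]
NumericVector muv_runif_cpp(double seed, int n) {
  Rng rng(mix_key((uint64_t)(int64_t)seed, 0x6D75767266ULL));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.unif();
  return out;
}
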