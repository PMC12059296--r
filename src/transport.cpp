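// Analog Monte Carlo photon transport in an axis-aligned box geometry.
//
// Physics: free paths from the local total attenuation coefficient
// (photoelectric + incoherent, log-log interpolated per material);
// photoelectric absorption deposits the full photon energy locally;
// incoherent scattering samples the free-electron Klein-Nishina
// distribution, deposits the energy transferred locally (kerma
// approximation, no electron transport) and continues the scattered
// photon. Histories end below the energy cutoff (remaining energy is
// deposited locally) or on leaving the world (no re-entry).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// ---- RNG: splitmix64-seeded xoshiro256** ------------------------------
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// ---- material attenuation tables --------------------------------------
struct MatTable {
  std::vector<double> loge, lphoto, lincoh;  // log energy, log mu (1/cm)
  double photo_at(double e) const { return interp(e, lphoto); }
  double incoh_at(double e) const { return interp(e, lincoh); }
  double interp(double e, const std::vector<double>& ly) const {
    double le = std::log(e);
    size_t n = loge.size();
    if (le <= loge.front()) return std::exp(ly.front());
    if (le >= loge.back()) return std::exp(ly.back());
    size_t lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (loge[mid] <= le) lo = mid; else hi = mid;
    }
    double f = (le - loge[lo]) / (loge[hi] - loge[lo]);
    return std::exp(ly[lo] + f * (ly[hi] - ly[lo]));
  }
};

struct Box {
  double lo[3], hi[3];
  int mat;  // 0-based material index
  bool contains(const double* p) const {
    for (int a = 0; a < 3; ++a)
      if (p[a] < lo[a] || p[a] >= hi[a]) return false;
    return true;
  }
};

struct World {
  std::vector<Box> boxes;   // priority order: first containing wins
  Box bounds;               // world box, bounds.mat = background material
  std::vector<MatTable> mats;
  int material_at(const double* p) const {
    for (size_t i = 0; i < boxes.size(); ++i)
      if (boxes[i].contains(p)) return boxes[i].mat;
    if (bounds.contains(p)) return bounds.mat;
    return -1;  // outside
  }
  // nearest positive distance to any box plane along dir
  double dist_to_plane(const double* p, const double* d) const {
    double best = 1e30;
    auto consider = [&](double plane, int axis) {
      if (std::fabs(d[axis]) < 1e-12) return;
      double t = (plane - p[axis]) / d[axis];
      if (t > 1e-7 && t < best) best = t;
    };
    for (size_t i = 0; i < boxes.size(); ++i)
      for (int a = 0; a < 3; ++a) {
        consider(boxes[i].lo[a], a);
        consider(boxes[i].hi[a], a);
      }
    for (int a = 0; a < 3; ++a) {
      consider(bounds.lo[a], a);
      consider(bounds.hi[a], a);
    }
    return best;
  }
};

// ---- ROI scoring -------------------------------------------------------
// Voxels: plane_cm thick along the depth axis, lat_cm square laterally.
// A deposition counts when its voxel lies in depth planes {2,3} and the
// voxel centre falls inside the ROI circle.
struct Roi {
  int mode;          // 0 none, 1 depth along +z from zmin, 2 depth along -y from ymax
  double lo[3], hi[3];
  double plane_cm, lat_cm, radius_cm;
  double c1, c2;     // circle centre in lateral coordinates
  bool accept(const double* p) const {
    if (mode == 0) return false;
    for (int a = 0; a < 3; ++a)
      if (p[a] < lo[a] || p[a] >= hi[a]) return false;
    double depth, u1, u2, u1o, u2o;
    if (mode == 1) { depth = p[2] - lo[2]; u1 = p[0]; u2 = p[1]; u1o = lo[0]; u2o = lo[1]; }
    else           { depth = hi[1] - p[1]; u1 = p[0]; u2 = p[2]; u1o = lo[0]; u2o = lo[2]; }
    int plane = static_cast<int>(std::floor(depth / plane_cm));  // 0-based
    if (plane != 1 && plane != 2) return false;
    double v1 = u1o + (std::floor((u1 - u1o) / lat_cm) + 0.5) * lat_cm;
    double v2 = u2o + (std::floor((u2 - u2o) / lat_cm) + 0.5) * lat_cm;
    double dx = v1 - c1, dy = v2 - c2;
    return dx * dx + dy * dy <= radius_cm * radius_cm;
  }
};

const double MEC2 = 510.99895;  // keV

// Klein-Nishina sampling of x = E'/E by rejection with constant envelope 2
double sample_kn_ratio(double e_kev, Rng& rng) {
  double k = e_kev / MEC2;
  double xmin = 1.0 / (1.0 + 2.0 * k);
  for (int it = 0; it < 10000; ++it) {
    double x = xmin + (1.0 - xmin) * rng.unif();
    double cth = 1.0 - (1.0 / x - 1.0) / k;
    double f = x * x * (x + 1.0 / x - 1.0 + cth * cth);
    if (2.0 * rng.unif() <= f) return x;
  }
  return 1.0;  // unreachable in practice
}

void rotate_direction(double* d, double cth, double phi) {
  double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  double u = d[0], v = d[1], w = d[2];
  double sp = std::sin(phi), cp = std::cos(phi);
  double s = std::sqrt(std::max(1e-30, 1.0 - w * w));
  double nu, nv, nw;
  if (s > 1e-10) {
    nu = u * cth + sth * (u * w * cp - v * sp) / s;
    nv = v * cth + sth * (v * w * cp + u * sp) / s;
    nw = w * cth - sth * s * cp;
  } else {  // nearly along z
    nu = sth * cp;
    nv = sth * sp;
    nw = (w > 0 ? cth : -cth);
  }
  double norm = std::sqrt(nu * nu + nv * nv + nw * nw);
  d[0] = nu / norm; d[1] = nv / norm; d[2] = nw / norm;
}

struct HistoryResult {
  double roi_e;      // energy (keV) deposited in the ROI
  int n_interactions;
};

// transport one photon; optionally record every deposition
HistoryResult transport_one(const World& world, const Roi& roi,
                            double e_kev, const double* origin,
                            const double* dir0, double cutoff, Rng& rng,
                            std::vector<double>* record) {
  double p[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {dir0[0], dir0[1], dir0[2]};
  HistoryResult hr = {0.0, 0};
  double e = e_kev;
  auto deposit = [&](double de) {
    if (de <= 0) return;
    if (roi.accept(p)) hr.roi_e += de;
    if (record) {
      record->push_back(p[0]); record->push_back(p[1]);
      record->push_back(p[2]); record->push_back(de);
    }
  };
  while (true) {
    int mat = world.material_at(p);
    if (mat < 0) break;  // left the world: disappears
    double tau = -std::log(rng.unif());
    // walk segments until the sampled optical depth is consumed
    bool interacted = false;
    while (true) {
      const MatTable& mt = world.mats[mat];
      double mu_p = mt.photo_at(e), mu_i = mt.incoh_at(e);
      double mu = mu_p + mu_i;
      double seg = world.dist_to_plane(p, d);
      if (mu > 1e-30 && mu * seg >= tau) {
        double step = tau / mu;
        for (int a = 0; a < 3; ++a) p[a] += step * d[a];
        hr.n_interactions++;
        if (rng.unif() < mu_p / mu) {  // photoelectric: full local absorption
          deposit(e);
          return hr;
        }
        // incoherent scatter
        double x = sample_kn_ratio(e, rng);
        double cth = 1.0 - (1.0 / x - 1.0) / (e / MEC2);
        deposit(e * (1.0 - x));
        e *= x;
        if (e < cutoff) {  // residual photon absorbed locally
          deposit(e);
          return hr;
        }
        rotate_direction(d, cth, 2.0 * M_PI * rng.unif());
        interacted = true;
        break;
      }
      tau -= mu * seg;
      for (int a = 0; a < 3; ++a) p[a] += (seg + 1e-6) * d[a];
      mat = world.material_at(p);
      if (mat < 0) return hr;
    }
    if (!interacted) break;
  }
  return hr;
}

World build_world(List spec) {
  World w;
  NumericMatrix boxes = spec["boxes"];
  for (int i = 0; i < boxes.nrow(); ++i) {
    Box b;
    b.lo[0] = boxes(i, 0); b.hi[0] = boxes(i, 1);
    b.lo[1] = boxes(i, 2); b.hi[1] = boxes(i, 3);
    b.lo[2] = boxes(i, 4); b.hi[2] = boxes(i, 5);
    b.mat = static_cast<int>(boxes(i, 6)) - 1;
    w.boxes.push_back(b);
  }
  NumericVector wb = spec["world"];
  w.bounds.lo[0] = wb[0]; w.bounds.hi[0] = wb[1];
  w.bounds.lo[1] = wb[2]; w.bounds.hi[1] = wb[3];
  w.bounds.lo[2] = wb[4]; w.bounds.hi[2] = wb[5];
  w.bounds.mat = as<int>(spec["world_mat"]) - 1;
  List mats = spec["materials"];
  for (int i = 0; i < mats.size(); ++i) {
    List m = mats[i];
    NumericVector e = m["energy_keV"], mp = m["mu_photo"], mi = m["mu_incoh"];
    MatTable t;
    for (int j = 0; j < e.size(); ++j) {
      t.loge.push_back(std::log(e[j]));
      t.lphoto.push_back(std::log(std::max(mp[j], 1e-300)));
      t.lincoh.push_back(std::log(std::max(mi[j], 1e-300)));
    }
    w.mats.push_back(t);
  }
  return w;
}

Roi build_roi(List spec) {
  Roi r;
  r.mode = as<int>(spec["mode"]);
  if (r.mode != 0) {
    NumericVector b = spec["box"];
    r.lo[0] = b[0]; r.hi[0] = b[1];
    r.lo[1] = b[2]; r.hi[1] = b[3];
    r.lo[2] = b[4]; r.hi[2] = b[5];
    r.plane_cm = as<double>(spec["plane_cm"]);
    r.lat_cm = as<double>(spec["lat_cm"]);
    r.radius_cm = as<double>(spec["radius_cm"]);
    NumericVector c = spec["center"];
    r.c1 = c[0]; r.c2 = c[1];
  }
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(List world_spec, List roi_spec, NumericMatrix lines,
            NumericVector source, std::string emission,
            NumericVector fixed_dir, double n_histories,
            double seed, double cutoff, bool narrow_beam, bool record) {
  World world = build_world(world_spec);
  Roi roi = build_roi(roi_spec);
  Rng rng(static_cast<uint64_t>(seed));

  int nlines = lines.nrow();
  std::vector<double> cum(nlines);
  double tot = 0;
  for (int i = 0; i < nlines; ++i) { tot += lines(i, 1); cum[i] = tot; }
  for (int i = 0; i < nlines; ++i) cum[i] /= tot;

  double sum_e = 0.0, sum_e2 = 0.0;
  double n_transmitted = 0.0;
  long long n = static_cast<long long>(n_histories);
  std::vector<double> rec;
  std::vector<double>* recp = record ? &rec : nullptr;

  for (long long h = 0; h < n; ++h) {
    // sample emission line
    double u = rng.unif();
    int li = 0;
    while (li < nlines - 1 && u > cum[li]) ++li;
    double e = lines(li, 0);
    double d[3];
    if (emission == "pencil") {
      d[0] = fixed_dir[0]; d[1] = fixed_dir[1]; d[2] = fixed_dir[2];
    } else {  // uniform over the +z hemisphere (toward the barrier)
      double cz = rng.unif();           // cos(theta) uniform on (0,1)
      double phi = 2.0 * M_PI * rng.unif();
      double s = std::sqrt(std::max(0.0, 1.0 - cz * cz));
      d[0] = s * std::cos(phi); d[1] = s * std::sin(phi); d[2] = cz;
    }
    double org[3] = {source[0], source[1], source[2]};
    HistoryResult hr = transport_one(world, roi, e, org, d, cutoff, rng, recp);
    if (narrow_beam) {
      if (hr.n_interactions == 0) n_transmitted += 1.0;
    } else {
      sum_e += hr.roi_e;
      sum_e2 += hr.roi_e * hr.roi_e;
    }
  }

  List out = List::create(
    _["n"] = static_cast<double>(n),
    _["sum_e_keV"] = sum_e,
    _["sum_e2_keV2"] = sum_e2,
    _["n_transmitted"] = n_transmitted);
  if (record) {
    int nr = rec.size() / 4;
    NumericMatrix dep(nr, 4);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < 4; ++j) dep(i, j) = rec[4 * i + j];
    colnames(dep) = CharacterVector::create("x_cm", "y_cm", "z_cm", "edep_keV");
    out["depositions"] = dep;
  }
  return out;
}
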