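// Voxel-scored Monte Carlo photon transport under the kerma approximation.
//
// Geometry is a small set of homogeneous axis-aligned boxes (first match
// wins); free paths are sampled region-exactly via distance-to-boundary,
// which for piecewise-constant materials is equivalent to a per-voxel walk.
// Energy deposits are scored on the tumor voxel grid; deposits elsewhere
// and escaping energy are accumulated per batch so energy is conserved
// exactly per history.
//
// Physics: photoelectric absorption (optionally re-emitting one effective
// K-fluorescence line of a high-Z constituent, which is then transported),
// incoherent (Compton) scattering sampled from Klein-Nishina via Kahn's
// method with local deposit E - E', and coherent (Rayleigh) scattering with
// the Thomson angular law and no deposit.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double MEC2 = 510.99895; // keV

// --- xoshiro256++ seeded via splitmix64: fast, reproducible ---------------
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct MatTab {
  // linear coefficients (1/cm) on a uniform energy grid
  std::vector<double> pe, inc, coh;
  // K-fluorescence channels: emission coefficient (1/cm) per line
  std::vector<std::vector<double> > fl_mu;
  std::vector<double> fl_e;
};

struct Grid {
  double emin, estep;
  int n;
  inline double at(const std::vector<double>& v, double e) const {
    double t = (e - emin) / estep;
    if (t <= 0) return v[0];
    int i = (int)t;
    if (i >= n - 1) return v[n - 1];
    double w = t - i;
    return v[i] * (1 - w) + v[i + 1] * w;
  }
};

// distance along dir from p to exit of box (p assumed inside)
static inline double box_exit(const double* b, const double* p,
                              const double* d) {
  double t = 1e30;
  for (int a = 0; a < 3; a++) {
    if (d[a] > 1e-12) t = std::min(t, (b[2 * a + 1] - p[a]) / d[a]);
    else if (d[a] < -1e-12) t = std::min(t, (b[2 * a] - p[a]) / d[a]);
  }
  return t;
}

// distance to entry of box, or -1 if the ray misses it
static inline double box_entry(const double* b, const double* p,
                               const double* d) {
  double t0 = 0.0, t1 = 1e30;
  for (int a = 0; a < 3; a++) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p[a] < b[2 * a] || p[a] > b[2 * a + 1]) return -1.0;
    } else {
      double ta = (b[2 * a] - p[a]) / d[a];
      double tb = (b[2 * a + 1] - p[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  return (t1 >= t0 && t1 > 1e-12) ? std::max(t0, 1e-12) : -1.0;
}

static inline int region_at(const std::vector<std::array<double, 6> >& boxes,
                            const double* p) {
  for (size_t i = 0; i < boxes.size(); i++) {
    const double* b = boxes[i].data();
    if (p[0] >= b[0] && p[0] <= b[1] && p[1] >= b[2] && p[1] <= b[3] &&
        p[2] >= b[4] && p[2] <= b[5]) return (int)i;
  }
  return -1;
}

// Kahn's method for Klein-Nishina: returns eta = E/E'; cos = 1-(eta-1)/a
static inline double kahn_eta(double a, Rng& rng) {
  for (;;) {
    double r1 = rng.unif(), r2 = rng.unif(), r3 = rng.unif();
    if (r1 * (2 * a + 9) <= (2 * a + 1)) {
      double eta = 1 + 2 * a * r2;
      if (r3 <= 4 * (eta - 1) / (eta * eta)) return eta;
    } else {
      double eta = (1 + 2 * a) / (1 + 2 * a * r2);
      double mu = 1 - (eta - 1) / a;
      if (r3 <= 0.5 * (mu * mu + 1 / eta)) return eta;
    }
  }
}

static inline void rotate_dir(double* d, double cost, double phi, Rng& rng) {
  double sint = std::sqrt(std::max(0.0, 1 - cost * cost));
  double u = d[0], v = d[1], w = d[2];
  double sp = std::sin(phi), cp = std::cos(phi);
  double rho = std::sqrt(std::max(1e-30, 1 - w * w));
  double nu, nv, nw;
  if (rho > 1e-10) {
    nu = u * cost + sint * (u * w * cp - v * sp) / rho;
    nv = v * cost + sint * (v * w * cp + u * sp) / rho;
    nw = w * cost - rho * sint * cp;
  } else {
    nu = sint * cp; nv = sint * sp; nw = (w > 0 ? cost : -cost);
  }
  double norm = std::sqrt(nu * nu + nv * nv + nw * nw);
  d[0] = nu / norm; d[1] = nv / norm; d[2] = nw / norm;
}

// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(NumericMatrix region_boxes, IntegerVector region_mat,
                      List mat_tables, double grid_emin, double grid_estep,
                      NumericVector spec_e, NumericVector spec_cdf,
                      NumericVector field, double entry_z,
                      NumericVector tumor_box, IntegerVector tumor_n,
                      double n_photons, int n_batches, double seed,
                      bool coherent_on, bool incoherent_on, bool fluor_on,
                      int max_scatters, double cutoff, bool instrument) {
  const int nreg = region_boxes.nrow();
  std::vector<std::array<double, 6> > boxes(nreg);
  for (int i = 0; i < nreg; i++)
    for (int j = 0; j < 6; j++) boxes[i][j] = region_boxes(i, j);

  const int nmat = mat_tables.size();
  std::vector<MatTab> mats(nmat);
  Grid grid;
  grid.emin = grid_emin; grid.estep = grid_estep;
  for (int m = 0; m < nmat; m++) {
    List t = mat_tables[m];
    mats[m].pe = as<std::vector<double> >(t["pe"]);
    mats[m].inc = as<std::vector<double> >(t["inc"]);
    mats[m].coh = as<std::vector<double> >(t["coh"]);
    List fl = t["fluor"];
    NumericVector fe = fl["line_keV"];
    List fm = fl["mu_emit"];
    for (int k = 0; k < fe.size(); k++) {
      mats[m].fl_e.push_back(fe[k]);
      mats[m].fl_mu.push_back(as<std::vector<double> >(fm[k]));
    }
  }
  grid.n = (int)mats[0].pe.size();

  const int nvx = tumor_n[0], nvy = tumor_n[1], nvz = tumor_n[2];
  const int ntv = nvx * nvy * nvz;
  const double tvox_x = (tumor_box[1] - tumor_box[0]) / nvx;
  const double tvox_y = (tumor_box[3] - tumor_box[2]) / nvy;
  const double tvox_z = (tumor_box[5] - tumor_box[4]) / nvz;

  NumericMatrix edep(n_batches, ntv);
  NumericVector out_outside(n_batches), out_escaped(n_batches),
      out_emitted(n_batches);
  long long ntot = (long long)n_photons;
  long long per_batch = ntot / n_batches;
  NumericVector hist_dep, hist_esc, hist_emit;
  if (instrument) {
    hist_dep = NumericVector(ntot); hist_esc = NumericVector(ntot);
    hist_emit = NumericVector(ntot);
  }

  const int nspec = spec_e.size();

  for (int b = 0; b < n_batches; b++) {
    Rng rng(((uint64_t)seed) * 2654435761ULL + 0x9E3779B9ULL * (b + 1));
    double* ed = &edep(b, 0);
    long long n_this = (b == n_batches - 1) ? ntot - per_batch * (n_batches - 1)
                                            : per_batch;
    for (long long h = 0; h < n_this; h++) {
      // sample energy from the spectrum CDF
      double u = rng.unif();
      int lo = 0, hi = nspec - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (spec_cdf[mid] < u) lo = mid + 1; else hi = mid;
      }
      double E = spec_e[lo];
      double p[3] = {
        field[0] + rng.unif() * (field[1] - field[0]),
        field[2] + rng.unif() * (field[3] - field[2]),
        entry_z - 1e-9
      };
      double d[3] = {0.0, 0.0, -1.0};
      out_emitted[b] += E;
      double dep_h = 0.0, esc_h = 0.0, emit_h = E;

      int nsc = 0;
      bool alive = true;
      while (alive) {
        int reg = region_at(boxes, p);
        if (reg < 0) {
          // in vacuum: fly to the nearest region entry, or escape
          double tbest = 1e30;
          for (int i = 0; i < nreg; i++) {
            double t = box_entry(boxes[i].data(), p, d);
            if (t > 0 && t < tbest) tbest = t;
          }
          if (tbest > 1e29) { esc_h += E; break; }
          for (int a = 0; a < 3; a++) p[a] += (tbest + 1e-9) * d[a];
          continue;
        }
        int m = region_mat[reg] - 1;
        double mu_pe = grid.at(mats[m].pe, E);
        double mu_in = incoherent_on ? grid.at(mats[m].inc, E) : 0.0;
        double mu_co = coherent_on ? grid.at(mats[m].coh, E) : 0.0;
        double mu = mu_pe + mu_in + mu_co;
        double s_mm = (mu > 1e-30) ? -std::log(rng.unif()) / mu * 10.0 : 1e30;
        double dexit = box_exit(boxes[reg].data(), p, d);
        if (s_mm >= dexit) {
          for (int a = 0; a < 3; a++) p[a] += (dexit + 1e-9) * d[a];
          continue;
        }
        for (int a = 0; a < 3; a++) p[a] += s_mm * d[a];

        // score helper: deposit 'amt' at current p
        auto deposit = [&](double amt) {
          if (amt <= 0) return;
          dep_h += amt;
          if (p[0] > tumor_box[0] && p[0] < tumor_box[1] &&
              p[1] > tumor_box[2] && p[1] < tumor_box[3] &&
              p[2] > tumor_box[4] && p[2] < tumor_box[5]) {
            int ix = (int)((p[0] - tumor_box[0]) / tvox_x);
            int iy = (int)((p[1] - tumor_box[2]) / tvox_y);
            int iz = (int)((p[2] - tumor_box[4]) / tvox_z);
            if (ix >= nvx) ix = nvx - 1;
            if (iy >= nvy) iy = nvy - 1;
            if (iz >= nvz) iz = nvz - 1;
            ed[(size_t)(ix + nvx * (iy + (size_t)nvy * iz)) * n_batches] +=
                amt;
          } else {
            out_outside[b] += amt;
          }
        };

        double pick = rng.unif() * mu;
        if (pick < mu_pe) {
          // photoelectric; maybe emit one effective K-fluorescence line
          bool emitted = false;
          if (fluor_on && !mats[m].fl_e.empty()) {
            double r = rng.unif() * mu_pe;
            double cum = 0.0;
            for (size_t k = 0; k < mats[m].fl_e.size(); k++) {
              cum += grid.at(mats[m].fl_mu[k], E);
              if (r < cum && E > mats[m].fl_e[k]) {
                deposit(E - mats[m].fl_e[k]);
                E = mats[m].fl_e[k];
                double cost = 2 * rng.unif() - 1;
                double sint = std::sqrt(1 - cost * cost);
                double phi = 2 * M_PI * rng.unif();
                d[0] = sint * std::cos(phi);
                d[1] = sint * std::sin(phi);
                d[2] = cost;
                emitted = true;
                break;
              }
            }
          }
          if (!emitted) { deposit(E); alive = false; }
        } else if (pick < mu_pe + mu_in) {
          double a = E / MEC2;
          double eta = kahn_eta(a, rng);
          double Ep = E / eta;
          double cost = 1 - (eta - 1) / a;
          deposit(E - Ep);
          if (Ep < cutoff) { deposit(Ep); alive = false; }
          else {
            rotate_dir(d, cost, 2 * M_PI * rng.unif(), rng);
            E = Ep;
          }
        } else {
          // Rayleigh: Thomson angular law, no deposit
          double cost;
          do { cost = 2 * rng.unif() - 1; }
          while (rng.unif() > 0.5 * (1 + cost * cost));
          rotate_dir(d, cost, 2 * M_PI * rng.unif(), rng);
        }
        if (alive && ++nsc >= max_scatters) { esc_h += E; break; }
      }
      out_escaped[b] += esc_h;
      if (instrument) {
        long long gh = per_batch * b + h;
        hist_dep[gh] = dep_h; hist_esc[gh] = esc_h; hist_emit[gh] = emit_h;
      }
    }
  }

  List out = List::create(
      _["edep_batches"] = edep, _["outside"] = out_outside,
      _["escaped"] = out_escaped, _["emitted"] = out_emitted);
  if (instrument) {
    out["hist_deposited"] = hist_dep;
    out["hist_escaped"] = hist_esc;
    out["hist_emitted"] = hist_emit;
  }
  return out;
}

// [[Rcpp::export(name = ".kn_sample_cpp")]]
List kn_sample_cpp(double energy, int n, double seed) {
  Rng rng((uint64_t)seed * 0x9E3779B97f4A7C15ULL + 1ULL);
  NumericVector ep(n), ct(n);
  double a = energy / MEC2;
  for (int i = 0; i < n; i++) {
    double eta = kahn_eta(a, rng);
    ep[i] = energy / eta;
    ct[i] = 1 - (eta - 1) / a;
  }
  return List::create(_["energy"] = ep, _["cos_theta"] = ct);
}
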