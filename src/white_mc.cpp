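#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic, platform-independent uniform RNG (xoshiro256** seeded via
// splitmix64).  std::uniform_real_distribution is implementation-defined,
// which would break the bit-identical-for-a-seed contract across toolchains.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]: avoids log(0)
  inline double runif_pos() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  // uniform in [0, 1)
  inline double runif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Unpolarized Fresnel reflectance for a photon hitting the top boundary from
// inside a medium of refractive index n_rel (outside = 1).  ci = cos(theta_i),
// the angle measured from the surface normal.
inline double fresnel_internal(double ci, double n_rel) {
  if (n_rel == 1.0) return 0.0;
  double si2 = 1.0 - ci * ci;
  double st2 = n_rel * n_rel * si2;          // sin^2(theta_t), Snell
  if (st2 >= 1.0) return 1.0;                // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
  double rp = (n_rel * ct - ci) / (n_rel * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// Semi-infinite homogeneous medium, z >= 0, pencil beam entering at the
// origin along +z.  Scattering only (white Monte Carlo: absorption is applied
// afterwards by Beer-Lambert pathlength weighting).  Boundary interactions
// are sampled probabilistically, so the photon weight stays 1 and at most one
// exit record is produced per photon.
// [[Rcpp::export]]
List cpp_white_mc(double mus, double g, double n_rel, int n_photons,
                  double seed, double max_path) {
  if (mus <= 0) stop("mus must be > 0");
  if (n_rel < 1) stop("n must be >= 1");
  if (n_photons < 1) stop("n_photons must be >= 1");
  if (max_path <= 0) stop("max_path must be > 0");

  Xoshiro rng(static_cast<uint64_t>(seed));
  std::vector<double> out_r, out_L, out_w;
  out_r.reserve(n_photons);
  out_L.reserve(n_photons);
  out_w.reserve(n_photons);
  long n_terminated = 0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0, y = 0, z = 0;
    double ux = 0, uy = 0, uz = 1;
    double L = 0;
    bool alive = true, recorded = false;

    while (alive) {
      double s = -std::log(rng.runif_pos()) / mus;
      // propagate, handling (possibly repeated) boundary hits within a step
      while (s > 0) {
        double db = (uz < 0) ? (z / (-uz)) : HUGE_VAL;
        if (s < db) {
          x += ux * s; y += uy * s; z += uz * s;
          L += s;
          s = 0;
        } else {
          x += ux * db; y += uy * db; z = 0;
          L += db;
          s -= db;
          double R = fresnel_internal(-uz, n_rel);
          if (rng.runif() >= R) {  // escapes through the top surface
            out_r.push_back(std::sqrt(x * x + y * y));
            out_L.push_back(L);
            out_w.push_back(1.0);
            alive = false; recorded = true;
            break;
          }
          uz = -uz;  // internally reflected, continue the remaining step
        }
        if (L >= max_path) { alive = false; break; }
      }
      if (!alive) break;
      if (L >= max_path) break;

      // Henyey-Greenstein scattering
      double ct;
      if (g == 0.0) {
        ct = 2.0 * rng.runif() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.runif());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (ct > 1.0) ct = 1.0;
        if (ct < -1.0) ct = -1.0;
      }
      double st = std::sqrt(1.0 - ct * ct);
      // azimuth via rejection sampling of a unit 2-vector (no trig)
      double cp, sp;
      for (;;) {
        double a = 2.0 * rng.runif() - 1.0;
        double b = 2.0 * rng.runif() - 1.0;
        double r2 = a * a + b * b;
        if (r2 > 0.0 && r2 < 1.0) {
          double inv = 1.0 / std::sqrt(r2);
          cp = a * inv; sp = b * inv;
          break;
        }
      }
      double nux, nuy, nuz;
      if (std::fabs(uz) > 0.99999) {
        nux = st * cp;
        nuy = st * sp;
        nuz = (uz >= 0) ? ct : -ct;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        nuz = -st * cp * den + uz * ct;
      }
      ux = nux; uy = nuy; uz = nuz;
    }
    if (!recorded) ++n_terminated;
  }

  return List::create(
    _["exit_radius"] = NumericVector(out_r.begin(), out_r.end()),
    _["path_length"] = NumericVector(out_L.begin(), out_L.end()),
    _["weight"]      = NumericVector(out_w.begin(), out_w.end()),
    _["n_launched"]  = n_photons,
    _["n_terminated"] = (double)n_terminated);
}

namespace {

// bilinear interpolation in (log mua, log musp) on one fx-slice of the table
struct TableInterp {
  const double *la, *ls;     // log grids
  int na, ns, nf;
  const double *rd;          // array [na x ns x nf], column-major R layout

  inline int bracket(const double *grid, int n, double v) const {
    // index i with grid[i] <= v <= grid[i+1]; clamps assumed pre-checked
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (grid[mid] <= v) lo = mid; else hi = mid;
    }
    return lo;
  }

  inline double eval(double lmua, double lmusp, int kf) const {
    int i = bracket(la, na, lmua);
    int j = bracket(ls, ns, lmusp);
    double tx = (lmua - la[i]) / (la[i + 1] - la[i]);
    double ty = (lmusp - ls[j]) / (ls[j + 1] - ls[j]);
    const double *slice = rd + (size_t)kf * na * ns;
    double v00 = slice[i + (size_t)j * na];
    double v10 = slice[i + 1 + (size_t)j * na];
    double v01 = slice[i + (size_t)(j + 1) * na];
    double v11 = slice[i + 1 + (size_t)(j + 1) * na];
    return (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
           (1 - tx) * ty * v01 + tx * ty * v11;
  }
};

struct Objective {
  const TableInterp *tab;
  const double *meas;   // one pixel's Rd per fx
  int nf;
  double mua_lo, mua_hi, musp_lo, musp_hi;

  double operator()(double mua, double musp) const {
    // penalty keeps the simplex inside the table domain (finite, steep)
    if (mua < mua_lo || mua > mua_hi || musp < musp_lo || musp > musp_hi) {
      double d = 0;
      if (mua < mua_lo)  d += (mua_lo - mua) / mua_lo;
      if (mua > mua_hi)  d += (mua - mua_hi) / mua_hi;
      if (musp < musp_lo) d += (musp_lo - musp) / musp_lo;
      if (musp > musp_hi) d += (musp - musp_hi) / musp_hi;
      return 1e3 * (1.0 + d);
    }
    double lmua = std::log(mua), lmusp = std::log(musp);
    double ss = 0;
    for (int k = 0; k < nf; ++k) {
      double d = meas[k] - tab->eval(lmua, lmusp, k);
      ss += d * d;
    }
    return ss;
  }
};

// 2-D Nelder-Mead with standard coefficients; deterministic.
void nelder_mead(const Objective &f, double x0, double y0,
                 double ftol, double xtol, int maxit,
                 double &xb, double &yb, double &fb, bool &conv) {
  double px[3] = {x0, x0 * 1.05, x0};
  double py[3] = {y0, y0, y0 * 1.05};
  double pf[3];
  for (int i = 0; i < 3; ++i) pf[i] = f(px[i], py[i]);

  conv = false;
  for (int it = 0; it < maxit; ++it) {
    // order: 0 best, 2 worst
    int ord[3] = {0, 1, 2};
    for (int a = 0; a < 2; ++a)
      for (int b = a + 1; b < 3; ++b)
        if (pf[ord[b]] < pf[ord[a]]) std::swap(ord[a], ord[b]);
    int lo = ord[0], mi = ord[1], hi = ord[2];

    double sz = std::max(
      std::fabs(px[lo] - px[hi]) + std::fabs(py[lo] - py[hi]),
      std::fabs(px[lo] - px[mi]) + std::fabs(py[lo] - py[mi]));
    if (std::fabs(pf[hi] - pf[lo]) < ftol || sz < xtol) { conv = true; break; }

    double cx = 0.5 * (px[lo] + px[mi]);
    double cy = 0.5 * (py[lo] + py[mi]);
    double rx = cx + (cx - px[hi]), ry = cy + (cy - py[hi]);
    double fr = f(rx, ry);
    if (fr < pf[lo]) {
      double ex = cx + 2.0 * (cx - px[hi]), ey = cy + 2.0 * (cy - py[hi]);
      double fe = f(ex, ey);
      if (fe < fr) { px[hi] = ex; py[hi] = ey; pf[hi] = fe; }
      else         { px[hi] = rx; py[hi] = ry; pf[hi] = fr; }
    } else if (fr < pf[mi]) {
      px[hi] = rx; py[hi] = ry; pf[hi] = fr;
    } else {
      double kx, ky;
      if (fr < pf[hi]) { kx = cx + 0.5 * (rx - cx); ky = cy + 0.5 * (ry - cy); }
      else             { kx = cx + 0.5 * (px[hi] - cx); ky = cy + 0.5 * (py[hi] - cy); }
      double fk = f(kx, ky);
      if (fk < std::min(fr, pf[hi])) { px[hi] = kx; py[hi] = ky; pf[hi] = fk; }
      else {
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          px[i] = px[lo] + 0.5 * (px[i] - px[lo]);
          py[i] = py[lo] + 0.5 * (py[i] - py[lo]);
          pf[i] = f(px[i], py[i]);
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i < 3; ++i) if (pf[i] < pf[best]) best = i;
  xb = px[best]; yb = py[best]; fb = pf[best];
}

} // namespace

// Fit (mua, musp) for many pixels at once against an fx-sliced reflectance
// table.  rd_meas: [npix x nfx]; rd_tab: array [na x ns x nfx] flattened
// column-major; grids are the log10-free natural-log grids.
// Returns [npix x 4]: mua, musp, residual, converged(0/1).
// [[Rcpp::export]]
NumericMatrix cpp_fit_pixels(NumericMatrix rd_meas,
                             NumericVector log_mua_grid,
                             NumericVector log_musp_grid,
                             NumericVector rd_tab,
                             NumericVector init,
                             NumericVector bounds,  // mua_lo, mua_hi, musp_lo, musp_hi
                             double ftol, double xtol, int maxit) {
  int npix = rd_meas.nrow(), nf = rd_meas.ncol();
  TableInterp tab;
  tab.la = log_mua_grid.begin(); tab.na = log_mua_grid.size();
  tab.ls = log_musp_grid.begin(); tab.ns = log_musp_grid.size();
  tab.nf = nf;
  tab.rd = rd_tab.begin();
  if ((size_t)tab.na * tab.ns * nf != (size_t)rd_tab.size())
    stop("table dimensions do not match fx slice count");

  NumericMatrix out(npix, 4);
  std::vector<double> meas(nf);
  for (int p = 0; p < npix; ++p) {
    bool ok = true;
    for (int k = 0; k < nf; ++k) {
      meas[k] = rd_meas(p, k);
      if (!(meas[k] > 0) || !std::isfinite(meas[k])) ok = false;
    }
    if (!ok) {
      out(p, 0) = NA_REAL; out(p, 1) = NA_REAL;
      out(p, 2) = NA_REAL; out(p, 3) = 0;
      continue;
    }
    Objective f;
    f.tab = &tab; f.meas = meas.data(); f.nf = nf;
    f.mua_lo = bounds[0]; f.mua_hi = bounds[1];
    f.musp_lo = bounds[2]; f.musp_hi = bounds[3];
    double xb, yb, fb; bool conv;
    nelder_mead(f, init[0], init[1], ftol, xtol, maxit, xb, yb, fb, conv);
    out(p, 0) = xb; out(p, 1) = yb; out(p, 2) = fb; out(p, 3) = conv ? 1 : 0;
  }
  return out;
}
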