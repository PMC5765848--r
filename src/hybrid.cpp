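// Hybrid analytical-stochastic trajectory engine.
//
// Trajectories are injected on an artificial inner boundary (half-circle,
// circle, or strip cross-section) by exact sampling of the first-hitting
// (harmonic-measure) density, advanced by Euler steps inside the working
// region, re-injected through the same density whenever they cross the
// outer boundary, and terminated on absorption at a window. Absorption and
// reflection are resolved on the full step segment, not the endpoint.
//
// The time step is adaptive: the root-mean-square displacement per step is
// eps/3 near an absorbing window (resolving the window geometry) and grows
// proportionally to the distance from the nearest absorbing or curved
// reflecting structure away from it; reflections at straight lines are
// exact folds at any step size.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ seeded through splitmix64: fast, reproducible given the seed
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) {
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
    uint64_t res = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return res;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {  // standard normal, Marsaglia polar
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

// wrapped-Cauchy deviate on (-pi, pi], concentration q in (0, 1)
inline double wc_sample(Rng& rng, double q) {
  return 2.0 * std::atan(((1.0 - q) / (1.0 + q)) *
                         std::tan(M_PI * (rng.unif() - 0.5)));
}

// fold into [0, half] by reflection at 0 and half (period 2 * half)
inline double fold(double u, double half) {
  double period = 2.0 * half;
  u -= period * std::floor(u / period);
  return (u > half) ? period - u : u;
}

inline double ang_dist(double a, double b) {
  double d = std::fabs(a - b);
  d -= 2.0 * M_PI * std::floor(d / (2.0 * M_PI));
  return (d > M_PI) ? 2.0 * M_PI - d : d;
}

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// -------- half-plane helpers (canonical domain x > 0, windows on x = 0) ----

// distance from (x, z) to the nearest window interval on the boundary line
inline double hp_window_dist(double x, double z, const double* wz, int nw,
                             double half) {
  double best = R_PosInf;
  for (int i = 0; i < nw; ++i) {
    double dz = std::fabs(z - wz[i]) - half;
    if (dz < 0) dz = 0;
    double d2 = x * x + dz * dz;
    if (d2 < best) best = d2;
  }
  return std::sqrt(best);
}

// resolve one step; returns -1 (continue; nx, nz updated by fold) or the
// absorbing window index
inline int hp_resolve(double x, double z, double& nx, double& nz,
                      const double* wz, int nw, double half) {
  if (nx >= 0) return -1;
  double t = x / (x - nx);
  double zc = z + t * (nz - z);
  for (int i = 0; i < nw; ++i)
    if (std::fabs(zc - wz[i]) <= half) return i;
  nx = -nx;  // exact fold across the reflecting line
  return -1;
}

// sample injection angle (from the boundary axis) on the half-circle re,
// seen from a point at radius r, angle ths
inline double hp_inject_angle(Rng& rng, double r, double ths, double re) {
  return fold(ths + wc_sample(rng, re / r), M_PI);
}

// -------- disk helpers (obstacle radius R, window arcs) --------------------

// distance from p to the nearest window arc on the circle of radius R
inline double disk_window_dist(double px, double py, const double* wa, int nw,
                               double ha, double R) {
  double r = std::sqrt(px * px + py * py);
  double phi = std::atan2(py, px);
  double best = R_PosInf;
  for (int i = 0; i < nw; ++i) {
    double da = ang_dist(phi, wa[i]) - ha;
    double d;
    if (da <= 0) {
      d = std::fabs(r - R);
    } else {
      d = std::sqrt(r * r + R * R - 2.0 * r * R * std::cos(da));
    }
    if (d < best) best = d;
  }
  return best;
}

// earliest crossing parameter of segment p0 + t v with the circle |p| = R,
// for t in (tmin, 1]; returns -1 if none
inline double circle_hit(double p0x, double p0y, double vx, double vy,
                         double R, double tmin) {
  double a = vx * vx + vy * vy;
  if (a == 0) return -1.0;
  double b = 2.0 * (p0x * vx + p0y * vy);
  double c = p0x * p0x + p0y * p0y - R * R;
  double disc = b * b - 4.0 * a * c;
  if (disc < 0) return -1.0;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / (2.0 * a);
  double t2 = (-b + sq) / (2.0 * a);
  if (t1 > tmin && t1 <= 1.0) return t1;
  if (t2 > tmin && t2 <= 1.0) return t2;
  return -1.0;
}

// resolve a step against the obstacle circle (absorb at a window arc or
// specular reflection, iterated); returns -1 (continue) or window index
inline int disk_resolve(double& p0x, double& p0y, double& p1x, double& p1y,
                        const double* wa, int nw, double ha, double R) {
  for (int iter = 0; iter < 16; ++iter) {
    double vx = p1x - p0x, vy = p1y - p0y;
    double t = circle_hit(p0x, p0y, vx, vy, R, 1e-12);
    if (t < 0) return -1;
    double hx = p0x + t * vx, hy = p0y + t * vy;
    double phi = std::atan2(hy, hx);
    for (int i = 0; i < nw; ++i)
      if (ang_dist(phi, wa[i]) <= ha) return i;
    // specular reflection of the remaining sub-segment about the tangent
    double nxh = hx / R, nyh = hy / R;
    double rx = (1.0 - t) * vx, ry = (1.0 - t) * vy;
    double dot = rx * nxh + ry * nyh;
    rx -= 2.0 * dot * nxh; ry -= 2.0 * dot * nyh;
    p0x = hx * (1.0 + 1e-12); p0y = hy * (1.0 + 1e-12);
    p1x = p0x + rx; p1y = p0y + ry;
  }
  // pathological multi-reflection: stay at the boundary contact point
  p1x = p0x; p1y = p0y;
  return -1;
}

// strip cross-section injection: exit coordinate across the strip of full
// width W, source a distance y1 down the strip at cross-coordinate v
inline double strip_inject_u(Rng& rng, double y1, double v, double W) {
  double w = M_PI / W;
  return fold(v + wc_sample(rng, std::exp(-w * y1)) / w, W);
}

}  // namespace

// ---------------------------------------------------------------------------
// exported simulation drivers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gs_run_halfplane(NumericVector wz, double eps, double sx, double sz,
                      double re, double ro, double dt_fine, double D,
                      int n, int max_reinject, double seed) {
  const int nw = wz.size();
  const double half = eps / 2.0;
  const double rms_fine = std::sqrt(4.0 * D * dt_fine);
  const double rms_cap = ro;
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> counts(nw, 0);
  double total_steps = 0.0, total_reinj = 0.0;
  int max_reinj_seen = 0, capped = 0;

  const double src_r = std::sqrt(sx * sx + sz * sz);
  const double src_th = std::atan2(sx, sz);  // angle from the boundary axis

  for (int traj = 0; traj < n; ++traj) {
    double th = hp_inject_angle(rng, src_r, src_th, re);
    double x = re * std::sin(th), z = re * std::cos(th);
    int reinj = 0, win = -1;
    while (win < 0) {
      double dw = hp_window_dist(x, z, &wz[0], nw, half);
      double rms = clampd(dw / 3.0, rms_fine, rms_cap);
      double s = rms / std::sqrt(2.0);  // per-component sd
      double nx = x + s * rng.norm();
      double nz = z + s * rng.norm();
      total_steps += 1.0;
      win = hp_resolve(x, z, nx, nz, &wz[0], nw, half);
      if (win >= 0) break;
      if (nx * nx + nz * nz > ro * ro) {
        double r = std::sqrt(nx * nx + nz * nz);
        double tht = std::atan2(nx, nz);
        th = hp_inject_angle(rng, r, tht, re);
        x = re * std::sin(th); z = re * std::cos(th);
        ++reinj; total_reinj += 1.0;
        if (reinj > max_reinject) { ++capped; break; }
      } else {
        x = nx; z = nz;
      }
    }
    if (win >= 0) ++counts[win];
    if (reinj > max_reinj_seen) max_reinj_seen = reinj;
  }
  return List::create(_["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["steps"] = total_steps,
                      _["reinjections"] = total_reinj,
                      _["max_reinjections"] = max_reinj_seen,
                      _["capped"] = capped);
}

// [[Rcpp::export]]
List gs_run_disk(NumericVector wa, double ha, double R, double sx, double sy,
                 double re, double ro, double dt_fine, double D,
                 int n, int max_reinject, double seed) {
  const int nw = wa.size();
  const double rms_fine = std::sqrt(4.0 * D * dt_fine);
  const double rms_cap = ro;
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> counts(nw, 0);
  double total_steps = 0.0, total_reinj = 0.0;
  int max_reinj_seen = 0, capped = 0;

  const double src_r = std::sqrt(sx * sx + sy * sy);
  const double src_th = std::atan2(sy, sx);

  for (int traj = 0; traj < n; ++traj) {
    double th = src_th + wc_sample(rng, re / src_r);
    double x = re * std::cos(th), y = re * std::sin(th);
    int reinj = 0, win = -1;
    while (win < 0) {
      double r = std::sqrt(x * x + y * y);
      double dw = disk_window_dist(x, y, &wa[0], nw, ha, R);
      double dobs = r - R; if (dobs < 0) dobs = 0;
      double lim = dw < dobs ? dw : dobs;
      double rms = clampd(lim / 3.0, rms_fine, rms_cap);
      double s = rms / std::sqrt(2.0);
      double p0x = x, p0y = y;
      double p1x = x + s * rng.norm();
      double p1y = y + s * rng.norm();
      total_steps += 1.0;
      win = disk_resolve(p0x, p0y, p1x, p1y, &wa[0], nw, ha, R);
      if (win >= 0) break;
      if (p1x * p1x + p1y * p1y > ro * ro) {
        double rr = std::sqrt(p1x * p1x + p1y * p1y);
        double tht = std::atan2(p1y, p1x);
        th = tht + wc_sample(rng, re / rr);
        x = re * std::cos(th); y = re * std::sin(th);
        ++reinj; total_reinj += 1.0;
        if (reinj > max_reinject) { ++capped; break; }
      } else {
        x = p1x; y = p1y;
      }
    }
    if (win >= 0) ++counts[win];
    if (reinj > max_reinj_seen) max_reinj_seen = reinj;
  }
  return List::create(_["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["steps"] = total_steps,
                      _["reinjections"] = total_reinj,
                      _["max_reinjections"] = max_reinj_seen,
                      _["capped"] = capped);
}

// [[Rcpp::export]]
List gs_run_strip(NumericVector wa, double ha, double R, double a_half,
                  double sx, double sy, double de, double d_out,
                  double dt_fine, double D, int n, int max_reinject,
                  double seed) {
  const int nw = wa.size();
  const double rms_fine = std::sqrt(4.0 * D * dt_fine);
  const double rms_cap = d_out;
  const double W = 2.0 * a_half;  // full strip width for the exit density
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> counts(nw, 0);
  double total_steps = 0.0, total_reinj = 0.0;
  int max_reinj_seen = 0, capped = 0;

  for (int traj = 0; traj < n; ++traj) {
    double side = (sx >= 0) ? 1.0 : -1.0;
    double u = strip_inject_u(rng, std::fabs(sx) - de, sy + a_half, W);
    double x = side * de, y = u - a_half;
    int reinj = 0, win = -1;
    while (win < 0) {
      double r = std::sqrt(x * x + y * y);
      double dw = disk_window_dist(x, y, &wa[0], nw, ha, R);
      double dobs = r - R; if (dobs < 0) dobs = 0;
      double lim = dw < dobs ? dw : dobs;
      double rms = clampd(lim / 3.0, rms_fine, rms_cap);
      double s = rms / std::sqrt(2.0);
      double p0x = x, p0y = y;
      double p1x = x + s * rng.norm();
      double p1y = y + s * rng.norm();
      total_steps += 1.0;
      // resolve wall folds and obstacle hits along the segment, iterated
      for (int iter = 0; iter < 32 && win < 0; ++iter) {
        double vx = p1x - p0x, vy = p1y - p0y;
        double tc = circle_hit(p0x, p0y, vx, vy, R, 1e-12);
        double tw = -1.0; int wall = 0;
        if (vy > 0 && p1y > a_half) { tw = (a_half - p0y) / vy; wall = 1; }
        else if (vy < 0 && p1y < -a_half) { tw = (-a_half - p0y) / vy; wall = -1; }
        if (tc >= 0 && (tw < 0 || tc <= tw)) {
          double hx = p0x + tc * vx, hy = p0y + tc * vy;
          double phi = std::atan2(hy, hx);
          for (int i = 0; i < nw; ++i)
            if (ang_dist(phi, wa[i]) <= ha) { win = i; break; }
          if (win >= 0) break;
          double nxh = hx / R, nyh = hy / R;
          double rx = (1.0 - tc) * vx, ry = (1.0 - tc) * vy;
          double dot = rx * nxh + ry * nyh;
          rx -= 2.0 * dot * nxh; ry -= 2.0 * dot * nyh;
          p0x = hx * (1.0 + 1e-12); p0y = hy * (1.0 + 1e-12);
          p1x = p0x + rx; p1y = p0y + ry;
        } else if (tw >= 0) {
          // exact fold of the endpoint across the straight wall
          double wy = wall > 0 ? a_half : -a_half;
          p0x = p0x + tw * vx; p0y = wy;
          p1y = 2.0 * wy - p1y;
        } else {
          break;
        }
      }
      if (win >= 0) break;
      if (std::fabs(p1x) > d_out) {
        side = (p1x >= 0) ? 1.0 : -1.0;
        u = strip_inject_u(rng, std::fabs(p1x) - de, p1y + a_half, W);
        x = side * de; y = u - a_half;
        ++reinj; total_reinj += 1.0;
        if (reinj > max_reinject) { ++capped; break; }
      } else {
        x = p1x; y = p1y;
      }
    }
    if (win >= 0) ++counts[win];
    if (reinj > max_reinj_seen) max_reinj_seen = reinj;
  }
  return List::create(_["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["steps"] = total_steps,
                      _["reinjections"] = total_reinj,
                      _["max_reinjections"] = max_reinj_seen,
                      _["capped"] = capped);
}

// ---------------------------------------------------------------------------
// exported building blocks (module-boundary tests)
// ---------------------------------------------------------------------------

// injection points used by the simulator, for distributional checks
// [[Rcpp::export]]
NumericMatrix gs_inject_halfplane(double sx, double sz, double re, int n,
                                  double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  double r = std::sqrt(sx * sx + sz * sz);
  double ths = std::atan2(sx, sz);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double th = hp_inject_angle(rng, r, ths, re);
    out(i, 0) = re * std::sin(th);
    out(i, 1) = re * std::cos(th);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix gs_inject_disk(double sx, double sy, double re, int n,
                             double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  double r = std::sqrt(sx * sx + sy * sy);
  double ths = std::atan2(sy, sx);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double th = ths + wc_sample(rng, re / r);
    out(i, 0) = re * std::cos(th);
    out(i, 1) = re * std::sin(th);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix gs_inject_strip(double sx, double sy, double a_half, double de,
                              int n, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  double W = 2.0 * a_half;
  double side = (sx >= 0) ? 1.0 : -1.0;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double u = strip_inject_u(rng, std::fabs(sx) - de, sy + a_half, W);
    out(i, 0) = side * de;
    out(i, 1) = u - a_half;
  }
  return out;
}

// classify a single Euler move (geometric unit tests); status 0 = continue,
// 1 = absorbed, 2 = escaped
// [[Rcpp::export]]
List gs_step_halfplane(NumericVector wz, double eps, NumericVector from,
                       NumericVector to, double ro) {
  double x = from[0], z = from[1], nx = to[0], nz = to[1];
  int win = hp_resolve(x, z, nx, nz, &wz[0], wz.size(), eps / 2.0);
  if (win >= 0)
    return List::create(_["status"] = 1, _["window"] = win + 1);
  if (nx * nx + nz * nz > ro * ro)
    return List::create(_["status"] = 2, _["window"] = NA_INTEGER,
                        _["position"] = NumericVector::create(nx, nz));
  return List::create(_["status"] = 0, _["window"] = NA_INTEGER,
                      _["position"] = NumericVector::create(nx, nz));
}

// [[Rcpp::export]]
List gs_step_disk(NumericVector wa, double ha, double R, NumericVector from,
                  NumericVector to, double ro) {
  double p0x = from[0], p0y = from[1], p1x = to[0], p1y = to[1];
  int win = disk_resolve(p0x, p0y, p1x, p1y, &wa[0], wa.size(), ha, R);
  if (win >= 0)
    return List::create(_["status"] = 1, _["window"] = win + 1);
  if (p1x * p1x + p1y * p1y > ro * ro)
    return List::create(_["status"] = 2, _["window"] = NA_INTEGER,
                        _["position"] = NumericVector::create(p1x, p1y));
  return List::create(_["status"] = 0, _["window"] = NA_INTEGER,
                      _["position"] = NumericVector::create(p1x, p1y));
}
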