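// Coarse-grained Langevin / metadynamics engine for the four-domain pincer
// model.  BAOAB splitting; bias is accumulated on a (d, phi) grid (value and
// analytic gradient) so the per-step cost is independent of the number of
// deposited Gaussians.  Units: Angstrom, Dalton, kcal/mol; the time unit is
// sqrt(Da A^2 / (kcal/mol)) ~ 48.9 fs.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64 + xoshiro256** : fully specified generator, identical output on
// every platform, so fixed-seed runs are bit-reproducible.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
    have_spare = false;
    spare = 0.0;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double uniform() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare;
  double spare;
  double normal() {   // Box-Muller, explicit for cross-platform determinism
    if (have_spare) { have_spare = false; return spare; }
    double u1 = uniform(), u2 = uniform();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

inline double wrap_angle(double x) {
  double y = x - 2.0 * M_PI * std::floor((x + M_PI) / (2.0 * M_PI));
  if (y > M_PI) y -= 2.0 * M_PI;     // guards the open/closed boundary
  return y;
}

struct Vec3 { double x, y, z; };
inline Vec3 operator-(const Vec3 &a, const Vec3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// regular-grid table with bilinear interpolation (phi periodic optional)
struct Table {
  int nd, np;
  double d0, dd, p0, dp;
  bool periodic;
  std::vector<double> V, Gd, Gp;
  double lookup(const std::vector<double> &M, double d, double phi) const {
    double fd = (d - d0) / dd;
    if (fd < 0) fd = 0;
    if (fd > nd - 1.000001) fd = nd - 1.000001;
    int id = (int)fd; double wd = fd - id;
    double fp = (wrap_angle(phi) - p0) / dp;
    int ip; double wp;
    if (periodic) {
      if (fp < 0) fp += np;          // grid covers one period
      ip = (int)fp; wp = fp - ip;
      if (ip >= np) { ip -= np; }
    } else {
      if (fp < 0) fp = 0;
      if (fp > np - 1.000001) fp = np - 1.000001;
      ip = (int)fp; wp = fp - ip;
    }
    int ip1 = periodic ? (ip + 1) % np : ip + 1;
    const double *m = M.data();
    double v00 = m[id + nd * ip],     v10 = m[id + 1 + nd * ip];
    double v01 = m[id + nd * ip1],    v11 = m[id + 1 + nd * ip1];
    return (1-wd)*(1-wp)*v00 + wd*(1-wp)*v10 + (1-wd)*wp*v01 + wd*wp*v11;
  }
};

} // namespace

// [[Rcpp::export(name = ".run_cg_dynamics")]]
List run_cg_dynamics(NumericMatrix x0, NumericVector mass, IntegerVector dom,
                     NumericMatrix bonds, double arm, double k_link,
                     NumericMatrix wells, List walls, List comp, List metad,
                     int n_steps, double dt, double kT, double friction,
                     double seed, int cv_stride, int frame_stride) {
  const int N = x0.nrow();
  const int ndom = dom.size() ? *std::max_element(dom.begin(), dom.end()) : 0;
  std::vector<double> x(3 * N), v(3 * N, 0.0), f(3 * N, 0.0);
  for (int i = 0; i < N; ++i) {
    x[3*i] = x0(i, 0); x[3*i+1] = x0(i, 1); x[3*i+2] = x0(i, 2);
  }
  std::vector<double> Mdom(ndom, 0.0), frac(N, 0.0);
  for (int i = 0; i < N; ++i) Mdom[dom[i] - 1] += mass[i];
  for (int i = 0; i < N; ++i) frac[i] = mass[i] / Mdom[dom[i] - 1];

  const int nb = bonds.nrow();
  std::vector<int> bi(nb), bj(nb);
  std::vector<double> br0(nb), bk(nb);
  for (int b = 0; b < nb; ++b) {
    bi[b] = (int)bonds(b, 0) - 1; bj[b] = (int)bonds(b, 1) - 1;
    br0[b] = bonds(b, 2); bk[b] = bonds(b, 3);
  }

  const int nw = wells.nrow();
  bool have_walls = walls.size() > 0;
  double wall_lo = 0, wall_hi = 0, wall_k = 0; int wall_p = 2;
  if (have_walls) {
    wall_lo = as<double>(walls["lower"]); wall_hi = as<double>(walls["upper"]);
    wall_k = as<double>(walls["k"]); wall_p = as<int>(walls["power"]);
  }

  Table ctab; bool have_comp = comp.size() > 0;
  std::vector<double> cV, cGd, cGp;
  if (have_comp) {
    NumericVector dg = comp["d_grid"], pg = comp["phi_grid"];
    NumericMatrix V = comp["V"], Gd = comp["dVd"], Gp = comp["dVphi"];
    ctab.nd = dg.size(); ctab.np = pg.size();
    ctab.d0 = dg[0]; ctab.dd = dg[1] - dg[0];
    ctab.p0 = pg[0]; ctab.dp = pg[1] - pg[0];
    ctab.periodic = false;
    ctab.V.assign(V.begin(), V.end());   // column-major: id + nd*ip
    ctab.Gd.assign(Gd.begin(), Gd.end());
    ctab.Gp.assign(Gp.begin(), Gp.end());
  }

  bool metad_on = as<bool>(metad["enabled"]);
  double mh = 0, msd = 1, msp = 1; int mstride = 1;
  Table btab;
  std::vector<double> hills;   // t, d, phi, sd, sphi, h
  if (metad_on) {
    mh = as<double>(metad["height"]);
    msd = as<double>(metad["sigma_d"]);
    msp = as<double>(metad["sigma_phi"]);
    mstride = as<int>(metad["stride"]);
    btab.nd = as<int>(metad["grid_nd"]); btab.np = as<int>(metad["grid_nphi"]);
    btab.d0 = as<double>(metad["grid_dmin"]);
    btab.dd = (as<double>(metad["grid_dmax"]) - btab.d0) / (btab.nd - 1);
    btab.p0 = -M_PI; btab.dp = 2.0 * M_PI / btab.np;
    btab.periodic = true;
    btab.V.assign((size_t)btab.nd * btab.np, 0.0);
    btab.Gd.assign((size_t)btab.nd * btab.np, 0.0);
    btab.Gp.assign((size_t)btab.nd * btab.np, 0.0);
    hills.reserve(6 * (n_steps / mstride + 1));
  }

  const bool use_cv = ndom >= 4 && (nw > 0 || have_walls || have_comp || metad_on);

  Rng rng((uint64_t)seed);
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);

  double cur_d = 0, cur_phi = 0;

  auto compute_forces = [&](void) {
    std::fill(f.begin(), f.end(), 0.0);
    // intra-domain network
    for (int b = 0; b < nb; ++b) {
      int i = bi[b], j = bj[b];
      double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < 1e-12) continue;
      double g = bk[b] * (r - br0[b]) / r;
      f[3*i] -= g*dx; f[3*i+1] -= g*dy; f[3*i+2] -= g*dz;
      f[3*j] += g*dx; f[3*j+1] += g*dy; f[3*j+2] += g*dz;
    }
    // domain COMs
    std::vector<Vec3> com(ndom, {0, 0, 0});
    for (int i = 0; i < N; ++i) {
      com[dom[i]-1].x += frac[i] * x[3*i];
      com[dom[i]-1].y += frac[i] * x[3*i+1];
      com[dom[i]-1].z += frac[i] * x[3*i+2];
    }
    std::vector<Vec3> fcom(ndom, {0, 0, 0});
    // harmonic linker bonds between consecutive COMs
    for (int a = 0; a + 1 < ndom; ++a) {
      Vec3 dr = com[a] - com[a+1];
      double r = norm(dr);
      if (r < 1e-12) continue;
      double g = k_link * (r - arm) / r;
      fcom[a].x -= g*dr.x; fcom[a].y -= g*dr.y; fcom[a].z -= g*dr.z;
      fcom[a+1].x += g*dr.x; fcom[a+1].y += g*dr.y; fcom[a+1].z += g*dr.z;
    }
    if (use_cv) {
      Vec3 u = com[0] - com[3];
      double d = norm(u);
      // torsion of the four COMs (IUPAC), with COM-level gradient
      Vec3 b1 = com[1] - com[0], b2 = com[2] - com[1], b3 = com[3] - com[2];
      Vec3 uu = cross(b1, b2), vv = cross(b2, b3);
      double nu2 = dot(uu, uu), nv2 = dot(vv, vv), nb2 = norm(b2);
      double phi = 0; bool phi_ok = nu2 > 1e-12 && nv2 > 1e-12 && nb2 > 1e-12;
      Vec3 g1{0,0,0}, g2{0,0,0}, g3{0,0,0}, g4{0,0,0};
      if (phi_ok) {
        phi = std::atan2(dot(cross(uu, vv), b2) / nb2, dot(uu, vv));
        double a1 = -nb2 / nu2, a4 = nb2 / nv2;
        g1 = {a1*uu.x, a1*uu.y, a1*uu.z};
        g4 = {a4*vv.x, a4*vv.y, a4*vv.z};
        double s1 = -dot(b1, b2) / (nb2*nb2), s2 = -dot(b3, b2) / (nb2*nb2);
        g2 = {(s1-1)*g1.x - s2*g4.x, (s1-1)*g1.y - s2*g4.y, (s1-1)*g1.z - s2*g4.z};
        g3 = {(s2-1)*g4.x - s1*g1.x, (s2-1)*g4.y - s1*g1.y, (s2-1)*g4.z - s1*g1.z};
        // the torsion gradient diverges near collinear COM triples; clamp
        // its magnitude so rare near-degenerate passages cannot kick the
        // system ballistically over the walls
        double gmax = std::sqrt(std::max(std::max(dot(g1, g1), dot(g2, g2)),
                                         std::max(dot(g3, g3), dot(g4, g4))));
        const double gcap = 0.5;   // rad/Angstrom, ~25x the typical value
        if (gmax > gcap) {
          double sc = gcap / gmax;
          g1 = {sc*g1.x, sc*g1.y, sc*g1.z}; g2 = {sc*g2.x, sc*g2.y, sc*g2.z};
          g3 = {sc*g3.x, sc*g3.y, sc*g3.z}; g4 = {sc*g4.x, sc*g4.y, sc*g4.z};
        }
      }
      cur_d = d; cur_phi = phi;
      double dU_dd = 0, dU_dphi = 0;
      for (int w = 0; w < nw; ++w) {
        double ddw = d - wells(w, 0);
        double dpw = wrap_angle(phi - wells(w, 1));
        double sd = wells(w, 3), sp = wells(w, 4);
        double e = -wells(w, 2) *
          std::exp(-ddw*ddw / (2*sd*sd) - dpw*dpw / (2*sp*sp));
        dU_dd += e * (-ddw / (sd*sd));
        dU_dphi += e * (-dpw / (sp*sp));
      }
      if (have_walls) {
        if (d < wall_lo) dU_dd -= wall_k * wall_p * std::pow(wall_lo - d, wall_p - 1);
        if (d > wall_hi) dU_dd += wall_k * wall_p * std::pow(d - wall_hi, wall_p - 1);
      }
      if (have_comp) {
        dU_dd += ctab.lookup(ctab.Gd, d, phi);
        dU_dphi += ctab.lookup(ctab.Gp, d, phi);
      }
      if (metad_on && d >= btab.d0 && d <= btab.d0 + btab.dd * (btab.nd - 1)) {
        // the bias exists only on its grid; outside, walls act alone
        dU_dd += btab.lookup(btab.Gd, d, phi);
        dU_dphi += btab.lookup(btab.Gp, d, phi);
      }
      if (d > 1e-9) {
        double gd = dU_dd / d;
        fcom[0].x -= gd*u.x; fcom[0].y -= gd*u.y; fcom[0].z -= gd*u.z;
        fcom[3].x += gd*u.x; fcom[3].y += gd*u.y; fcom[3].z += gd*u.z;
      }
      if (phi_ok && dU_dphi != 0) {
        fcom[0].x -= dU_dphi*g1.x; fcom[0].y -= dU_dphi*g1.y; fcom[0].z -= dU_dphi*g1.z;
        fcom[1].x -= dU_dphi*g2.x; fcom[1].y -= dU_dphi*g2.y; fcom[1].z -= dU_dphi*g2.z;
        fcom[2].x -= dU_dphi*g3.x; fcom[2].y -= dU_dphi*g3.y; fcom[2].z -= dU_dphi*g3.z;
        fcom[3].x -= dU_dphi*g4.x; fcom[3].y -= dU_dphi*g4.y; fcom[3].z -= dU_dphi*g4.z;
      }
    } else if (ndom >= 4) {
      Vec3 u = com[0] - com[3];
      cur_d = norm(u);
    }
    // distribute COM forces to beads by mass fraction
    for (int i = 0; i < N; ++i) {
      const Vec3 &fc = fcom[dom[i]-1];
      f[3*i] += frac[i] * fc.x; f[3*i+1] += frac[i] * fc.y; f[3*i+2] += frac[i] * fc.z;
    }
  };

  auto deposit = [&](double t) {
    int reach_d = (int)std::ceil(5.0 * msd / btab.dd);
    int reach_p = (int)std::ceil(5.0 * msp / btab.dp);
    if (reach_p > btab.np / 2) reach_p = btab.np / 2;
    double fd = (cur_d - btab.d0) / btab.dd;
    int id0 = (int)std::floor(fd);
    double fp = (wrap_angle(cur_phi) - btab.p0) / btab.dp;
    int ip0 = (int)std::floor(fp);
    for (int di = id0 - reach_d; di <= id0 + reach_d + 1; ++di) {
      if (di < 0 || di >= btab.nd) continue;
      double gd = btab.d0 + di * btab.dd;
      double ddw = gd - cur_d;
      double ed = std::exp(-ddw*ddw / (2*msd*msd));
      for (int pj = ip0 - reach_p; pj <= ip0 + reach_p + 1; ++pj) {
        int jw = ((pj % btab.np) + btab.np) % btab.np;
        double gp = btab.p0 + pj * btab.dp;
        double dpw = wrap_angle(gp - cur_phi);
        double ep = std::exp(-dpw*dpw / (2*msp*msp));
        double val = mh * ed * ep;
        size_t idx = di + (size_t)btab.nd * jw;
        btab.V[idx] += val;
        btab.Gd[idx] += val * (-ddw / (msd*msd));
        btab.Gp[idx] += val * (-dpw / (msp*msp));
      }
    }
    hills.push_back(t); hills.push_back(cur_d); hills.push_back(cur_phi);
    hills.push_back(msd); hills.push_back(msp); hills.push_back(mh);
  };

  // outputs
  int n_cv = n_steps / cv_stride;
  NumericMatrix cv_out(n_cv, 3);
  int n_fr = frame_stride > 0 ? n_steps / frame_stride : 0;
  NumericMatrix frames(n_fr, frame_stride > 0 ? 3 * N : 0);
  std::vector<int> frame_step(n_fr);

  compute_forces();
  int cvrow = 0, frrow = 0;
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < N; ++i) {
      double im = dt / (2.0 * mass[i]);
      v[3*i]   += im * f[3*i];
      v[3*i+1] += im * f[3*i+1];
      v[3*i+2] += im * f[3*i+2];
    }
    for (int k = 0; k < 3 * N; ++k) x[k] += 0.5 * dt * v[k];
    if (friction > 0) {
      for (int i = 0; i < N; ++i) {
        double sig = std::sqrt(kT / mass[i]);
        v[3*i]   = c1 * v[3*i]   + c2 * sig * rng.normal();
        v[3*i+1] = c1 * v[3*i+1] + c2 * sig * rng.normal();
        v[3*i+2] = c1 * v[3*i+2] + c2 * sig * rng.normal();
      }
    }
    for (int k = 0; k < 3 * N; ++k) x[k] += 0.5 * dt * v[k];
    compute_forces();
    for (int i = 0; i < N; ++i) {
      double im = dt / (2.0 * mass[i]);
      v[3*i]   += im * f[3*i];
      v[3*i+1] += im * f[3*i+1];
      v[3*i+2] += im * f[3*i+2];
    }
    if (metad_on && ((step + 1) % mstride == 0)) deposit((step + 1) * dt);
    if ((step + 1) % cv_stride == 0) {
      cv_out(cvrow, 0) = (step + 1) * dt;
      cv_out(cvrow, 1) = cur_d;
      cv_out(cvrow, 2) = cur_phi;
      ++cvrow;
    }
    if (frame_stride > 0 && ((step + 1) % frame_stride == 0)) {
      for (int k = 0; k < 3 * N; ++k) frames(frrow, k) = x[k];
      frame_step[frrow] = step + 1;
      ++frrow;
    }
    if ((step & 1023) == 0) {
      if (!std::isfinite(x[0]) || !std::isfinite(cur_d))
        stop("non-finite coordinates at step %d; reduce dt", step);
      if ((step & 262143) == 0) Rcpp::checkUserInterrupt();
    }
  }
  if (!std::isfinite(x[0]) || !std::isfinite(v[0]))
    stop("non-finite state at end of run; reduce dt");

  NumericMatrix xf(N, 3), vf(N, 3);
  for (int i = 0; i < N; ++i) {
    xf(i, 0) = x[3*i]; xf(i, 1) = x[3*i+1]; xf(i, 2) = x[3*i+2];
    vf(i, 0) = v[3*i]; vf(i, 1) = v[3*i+1]; vf(i, 2) = v[3*i+2];
  }
  NumericMatrix hm(hills.size() / 6, 6);
  for (size_t r = 0; r < hills.size() / 6; ++r)
    for (int c = 0; c < 6; ++c) hm(r, c) = hills[6 * r + c];
  List bias_grid = R_NilValue;
  if (metad_on) {
    NumericVector bv(btab.V.begin(), btab.V.end());
    bias_grid = List::create(_["V"] = bv, _["nd"] = btab.nd, _["nphi"] = btab.np,
                             _["dmin"] = btab.d0,
                             _["dmax"] = btab.d0 + btab.dd * (btab.nd - 1));
  }
  return List::create(
    _["cv"] = cv_out, _["hills"] = hm, _["frames"] = frames,
    _["frame_step"] = IntegerVector(frame_step.begin(), frame_step.end()),
    _["x_final"] = xf, _["v_final"] = vf, _["bias_grid"] = bias_grid,
    _["n_steps"] = n_steps, _["dt"] = dt);
}
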