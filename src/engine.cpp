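// Lattice engine for the hybrid multiscale myeloma model.
//
// The R layer defines the science (ODE readout tables, behavior
// constants, configuration); this file advances the 2-h simulation steps:
// cytokine secretion + explicit diffusion sub-stepping, BMSC stiffness
// updates from the local SDF-1 field, and the shuffled per-agent
// stochastic rule phase. All randomness goes through R's RNG so set.seed
// governs the whole run.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- diffusion -----------------------------------------------------------

static void diffuse_inplace(std::vector<double> &f, std::vector<double> &buf,
                            int nx, int ny, int nz, double D, double h,
                            int nsteps, double boundary) {
  const double a = D * h;  // dx = 1 site
  const int sy = nx, sz = nx * ny;
  for (int s = 0; s < nsteps; ++s) {
    const double *__restrict src = f.data();
    double *__restrict dst = buf.data();
    for (int z = 0; z < nz; ++z) {
      const bool zedge = (z == 0 || z == nz - 1);
      for (int y = 0; y < ny; ++y) {
        const int base = y * sy + z * sz;
        if (!zedge && y > 0 && y < ny - 1) {
          // branch-free interior row (x = 1 .. nx-2)
          const double *row = src + base;
          for (int x = 1; x < nx - 1; ++x) {
            double c = row[x];
            dst[base + x] = c + a * (row[x - 1] + row[x + 1] +
                                     row[x - sy] + row[x + sy] +
                                     row[x - sz] + row[x + sz] - 6.0 * c);
          }
          {  // x = 0 and x = nx-1 of this row
            int i = base;
            double c = src[i];
            dst[i] = c + a * (boundary + src[i + 1] + src[i - sy] +
                              src[i + sy] + src[i - sz] + src[i + sz] -
                              6.0 * c);
            i = base + nx - 1;
            c = src[i];
            dst[i] = c + a * (src[i - 1] + boundary + src[i - sy] +
                              src[i + sy] + src[i - sz] + src[i + sz] -
                              6.0 * c);
          }
        } else {
          for (int x = 0; x < nx; ++x) {
            int i = base + x;
            double c = src[i];
            double xm = (x > 0) ? src[i - 1] : boundary;
            double xp = (x < nx - 1) ? src[i + 1] : boundary;
            double ym = (y > 0) ? src[i - sy] : boundary;
            double yp = (y < ny - 1) ? src[i + sy] : boundary;
            double zm = (z > 0) ? src[i - sz] : boundary;
            double zp = (z < nz - 1) ? src[i + sz] : boundary;
            dst[i] = c + a * (xm + xp + ym + yp + zm + zp - 6.0 * c);
          }
        }
      }
    }
    f.swap(buf);
  }
}

// [[Rcpp::export]]
NumericVector diffuse_steps_cpp(NumericVector field, int nx, int ny, int nz,
                                double D, double dt, int nsteps,
                                double boundary) {
  std::vector<double> f(field.begin(), field.end());
  std::vector<double> buf(f.size());
  diffuse_inplace(f, buf, nx, ny, nz, D, dt, nsteps, boundary);
  NumericVector out(f.begin(), f.end());
  return out;
}

// ---- helpers -------------------------------------------------------------

static inline double runif1() { return unif_rand(); }

static inline int rint_below(int n) {  // uniform in 0..n-1
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static inline double hilln(double x, double pmax, double H, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n), Hn = std::pow(H, n);
  return pmax * xn / (Hn + xn);
}

// piecewise-linear interpolation on an increasing grid, clamped at ends
static double interp1(const std::vector<double> &gx,
                      const std::vector<double> &gy, double x) {
  int n = gx.size();
  if (x <= gx[0]) return gy[0];
  if (x >= gx[n - 1]) return gy[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int m = (lo + hi) / 2; if (gx[m] <= x) lo = m; else hi = m; }
  double w = (x - gx[lo]) / (gx[hi] - gx[lo]);
  return gy[lo] + w * (gy[hi] - gy[lo]);
}

// bilinear interpolation on grids (clamped)
static double interp2(const std::vector<double> &gx,
                      const std::vector<double> &gy,
                      const std::vector<double> &gz,  // length gx*gy, x fastest
                      double x, double y) {
  int nx = gx.size(), ny = gy.size();
  auto clampfind = [](const std::vector<double> &g, double v, double &w) {
    int n = g.size();
    if (v <= g[0]) { w = 0.0; return 0; }
    if (v >= g[n - 1]) { w = 1.0; return n - 2; }
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int m = (lo + hi) / 2; if (g[m] <= v) lo = m; else hi = m; }
    w = (v - g[lo]) / (g[lo + 1] - g[lo]);
    return lo;
  };
  double wx, wy;
  int ix = clampfind(gx, x, wx);
  int iy = clampfind(gy, y, wy);
  double v00 = gz[ix + nx * iy], v10 = gz[ix + 1 + nx * iy];
  double v01 = gz[ix + nx * (iy + 1)], v11 = gz[ix + 1 + nx * (iy + 1)];
  return (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
         (1 - wx) * wy * v01 + wx * wy * v11;
}

struct Agent {
  int kind;      // 1 MIC, 2 MM, 3 CD8, 4 TREG
  int site;      // 0-based linear lattice index
  double clock;  // hours since last division opportunity reset
  int passage;   // MM generation count
  bool attached; // MIC adhered to a BMSC
  bool arrested; // CD8 cycle arrest pending
  bool alive;
};

// ---- engine --------------------------------------------------------------

// [[Rcpp::export]]
List run_habm_cpp(List cfg) {
  const int nx = as<int>(cfg["nx"]), ny = as<int>(cfg["ny"]),
            nz = as<int>(cfg["nz"]);
  const int nsite = nx * ny * nz;
  const int sx = 1, sy = nx, sz = nx * ny;
  LogicalVector mask_r = cfg["mask"];
  std::vector<char> mask(mask_r.begin(), mask_r.end());

  const int n_steps = as<int>(cfg["n_steps"]);
  const double dt = as<double>(cfg["dt"]);

  // fields
  const double D = as<double>(cfg["D"]);
  const double boundary = as<double>(cfg["boundary"]);
  const double sdf1_rate = as<double>(cfg["sdf1_rate"]);
  const double tgfb_rate_mm = as<double>(cfg["tgfb_rate_mm"]);
  const double tgfb_rate_bmsc = as<double>(cfg["tgfb_rate_bmsc"]);
  const int nsub = std::max(1, (int)std::ceil(6.0 * D * dt));
  const double hsub = dt / nsub;

  // regimen
  const double btz_dose = as<double>(cfg["btz_nM"]);
  const double len_dose = as<double>(cfg["len_uM"]);
  const double thal_dose = as<double>(cfg["thal_uM"]);
  const double trt_start = as<double>(cfg["start_h"]);
  const double trt_dur = as<double>(cfg["duration_h"]);

  // lookup tables from the ODE layer
  std::vector<double> stiff_x = as<std::vector<double> >(cfg["stiff_x"]);
  std::vector<double> stiff_y = as<std::vector<double> >(cfg["stiff_y"]);
  std::vector<double> micd_s = as<std::vector<double> >(cfg["micd_stiff"]);
  std::vector<double> micd_b = as<std::vector<double> >(cfg["micd_btz"]);
  std::vector<double> micd_p = as<std::vector<double> >(cfg["micd_p"]);
  std::vector<double> adh_x = as<std::vector<double> >(cfg["adh_x"]);
  std::vector<double> adh_y = as<std::vector<double> >(cfg["adh_y"]);

  // behavior constants
  List R = cfg["rules"];
  List Rmic = R["mic"], Rmm = R["mm"], Rcd8 = R["cd8"], Rtr = R["treg"],
       Rb = R["bmsc"];
  const double mic_p_apop0 = as<double>(Rmic["p_apop0"]);
  const double mic_div_pmax = as<double>(Rmic["div_pmax"]);
  const double mic_div_H = as<double>(Rmic["div_H"]);
  const double mic_div_n = as<double>(Rmic["div_n"]);
  const double mic_sr_pmax = as<double>(Rmic["selfrenew_pmax"]);
  const double mic_sr_H = as<double>(Rmic["selfrenew_H"]);
  const double mic_sr_n = as<double>(Rmic["selfrenew_n"]);
  const double mic_p_mig = as<double>(Rmic["p_mig"]);
  const double mic_Tc = as<double>(Rmic["cycle_h"]);
  const double mm_p_apop0 = as<double>(Rmm["p_apop0"]);
  const double mm_btz_pmax = as<double>(Rmm["btz_pmax"]);
  const double mm_btz_H = as<double>(Rmm["btz_H"]);
  const double mm_div_pmax = as<double>(Rmm["div_pmax"]);
  const double mm_div_H = as<double>(Rmm["div_H"]);
  const double mm_div_n = as<double>(Rmm["div_n"]);
  const double mm_p_mig = as<double>(Rmm["p_mig"]);
  const double mm_Tc = as<double>(Rmm["cycle_h"]);
  const int LGN = as<int>(Rmm["lgn"]);
  const double cd8_p_div0 = as<double>(Rcd8["p_div0"]);
  const double cd8_tgfb_H = as<double>(Rcd8["tgfb_H"]);
  const double cd8_tgfb_n = as<double>(Rcd8["tgfb_n"]);
  const double cd8_treg_K = as<double>(Rcd8["treg_K"]);
  const double cd8_len_pmax = as<double>(Rcd8["len_pmax"]);
  const double cd8_len_H = as<double>(Rcd8["len_H"]);
  const double cd8_p_die = as<double>(Rcd8["p_die"]);
  const double cd8_p_lysis = as<double>(Rcd8["p_lysis"]);
  const double cd8_protect = as<double>(Rcd8["attach_protection"]);
  const double cd8_p_mig = as<double>(Rcd8["p_mig"]);
  const double cd8_Tc = as<double>(Rcd8["cycle_h"]);
  const int cd8_rad = as<int>(Rcd8["sense_radius"]);
  const double tr_p_div_pmax = as<double>(Rtr["p_div_pmax"]);
  const double tr_tgfb_H = as<double>(Rtr["tgfb_H"]);
  const double tr_tgfb_n = as<double>(Rtr["tgfb_n"]);
  const double tr_len_smax = as<double>(Rtr["len_supp_max"]);
  const double tr_len_sH = as<double>(Rtr["len_supp_H"]);
  const double tr_p_die = as<double>(Rtr["p_die"]);
  const double tr_p_supp = as<double>(Rtr["p_suppress"]);
  const double tr_arrest = as<double>(Rtr["arrest_frac"]);
  const double tr_p_mig = as<double>(Rtr["p_mig"]);
  const double tr_Tc = as<double>(Rtr["cycle_h"]);
  const int tr_rad = as<int>(Rtr["sense_radius"]);
  const double thal_emax = as<double>(Rb["thal_emax"]);
  const double thal_H = as<double>(Rb["thal_H"]);
  const double ecm_floor = as<double>(Rb["ecm_floor_pa"]);

  const bool return_fields = as<bool>(cfg["return_fields"]);
  const bool return_agents = as<bool>(cfg["return_agents"]);

  // Moore offsets
  int off[26], k = 0;
  int offx[26], offy[26], offz[26];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx || dy || dz) {
          off[k] = dx * sx + dy * sy + dz * sz;
          offx[k] = dx; offy[k] = dy; offz[k] = dz;
          ++k;
        }
  auto coords = [&](int i, int &x, int &y, int &z) {
    z = i / sz; int r = i - z * sz; y = r / sy; x = r - y * sy;
  };
  auto inbounds = [&](int x, int y, int z) {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  };

  // BMSC scaffold
  IntegerVector bmsc_idx_r = cfg["bmsc_sites"];  // 1-based
  const int nbmsc = bmsc_idx_r.size();
  std::vector<int> bmsc_site(nbmsc);
  std::vector<double> bmsc_stiff(nbmsc, interp1(stiff_x, stiff_y, 0.0));
  for (int i = 0; i < nbmsc; ++i) bmsc_site[i] = bmsc_idx_r[i] - 1;

  // fields
  std::vector<double> sdf1(nsite, boundary), tgfb(nsite, boundary), fbuf(nsite);
  std::vector<double> localstiff(nsite, ecm_floor);

  // agents
  std::vector<Agent> ag;
  std::vector<int> occ(nsite, -1);
  int counts[5] = {0, 0, 0, 0, 0};  // index by kind

  // initial placement: tumor + immune mixed uniformly in the central sphere
  {
    IntegerVector sph_r = cfg["sphere_sites"];  // 1-based candidates
    std::vector<int> sph(sph_r.begin(), sph_r.end());
    int n_mic = as<int>(cfg["n_mic"]), n_mm = as<int>(cfg["n_mm"]),
        n_cd8 = as<int>(cfg["n_cd8"]), n_treg = as<int>(cfg["n_treg"]);
    int total = n_mic + n_mm + n_cd8 + n_treg;
    if ((int)sph.size() < total)
      stop("central sphere too small for the initial cell counts");
    // partial Fisher-Yates
    for (int i = 0; i < total; ++i) {
      int j = i + rint_below(sph.size() - i);
      std::swap(sph[i], sph[j]);
    }
    int pos = 0;
    int kinds[4] = {1, 2, 3, 4};
    int nk[4] = {n_mic, n_mm, n_cd8, n_treg};
    double tcs[4] = {mic_Tc, mm_Tc, cd8_Tc, tr_Tc};
    for (int kk = 0; kk < 4; ++kk)
      for (int i = 0; i < nk[kk]; ++i) {
        Agent a;
        a.kind = kinds[kk];
        a.site = sph[pos++] - 1;
        a.clock = runif1() * tcs[kk];  // desynchronised cycles
        a.passage = 0;
        a.attached = false;
        a.arrested = false;
        a.alive = true;
        occ[a.site] = ag.size();
        ag.push_back(a);
        counts[a.kind]++;
      }
  }

  NumericMatrix pop(n_steps + 1, 4), births(n_steps, 4), deaths(n_steps, 4);
  NumericVector stiff_mean(n_steps + 1);
  for (int kk = 1; kk <= 4; ++kk) pop(0, kk - 1) = counts[kk];
  {
    double s = 0; for (int i = 0; i < nbmsc; ++i) s += bmsc_stiff[i];
    stiff_mean[0] = nbmsc ? s / nbmsc : ecm_floor;
  }

  std::vector<int> order;
  std::vector<int> freenb(26), targets(26);

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    bool on = (t >= trt_start && t < trt_start + trt_dur);
    double btz = on ? btz_dose : 0.0;
    double len = on ? len_dose : 0.0;
    double thal = on ? thal_dose : 0.0;
    double thal_f = 1.0 - thal_emax * thal / (thal_H + thal);

    // (1) secretion then diffusion over the step
    for (size_t i = 0; i < ag.size(); ++i) {
      if (!ag[i].alive) continue;
      if (ag[i].kind == 1) sdf1[ag[i].site] += sdf1_rate * dt;
      else if (ag[i].kind == 2) tgfb[ag[i].site] += tgfb_rate_mm * dt;
    }
    for (int i = 0; i < nbmsc; ++i)
      tgfb[bmsc_site[i]] += tgfb_rate_bmsc * thal_f * dt;
    diffuse_inplace(sdf1, fbuf, nx, ny, nz, D, hsub, nsub, boundary);
    diffuse_inplace(tgfb, fbuf, nx, ny, nz, D, hsub, nsub, boundary);

    // (2) BMSC stiffness from local SDF-1 (thalidomide-attenuated input)
    for (int i = 0; i < nbmsc; ++i)
      bmsc_stiff[i] = interp1(stiff_x, stiff_y, sdf1[bmsc_site[i]] * thal_f);
    std::fill(localstiff.begin(), localstiff.end(), ecm_floor);
    for (int i = 0; i < nbmsc; ++i) {
      int x, y, z; coords(bmsc_site[i], x, y, z);
      double s = bmsc_stiff[i];
      if (localstiff[bmsc_site[i]] < s) localstiff[bmsc_site[i]] = s;
      for (int m = 0; m < 26; ++m) {
        int xx = x + offx[m], yy = y + offy[m], zzi = z + offz[m];
        if (!inbounds(xx, yy, zzi)) continue;
        int j = bmsc_site[i] + off[m];
        if (localstiff[j] < s) localstiff[j] = s;
      }
    }

    // (3) shuffled agent phase
    order.clear();
    for (size_t i = 0; i < ag.size(); ++i)
      if (ag[i].alive) order.push_back(i);
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = rint_below(i + 1);
      std::swap(order[i], order[j]);
    }

    double *B = &births(step, 0), *Dd = &deaths(step, 0);
    int brow = births.nrow();
    auto birth = [&](int kind) { B[(kind - 1) * brow] += 1; counts[kind]++; };
    auto death = [&](int idx) {
      Agent &a = ag[idx];
      Dd[(a.kind - 1) * brow] += 1;
      counts[a.kind]--;
      a.alive = false;
      occ[a.site] = -1;
    };
    auto free_neighbors = [&](int site, int &nfree) {
      int x, y, z; coords(site, x, y, z);
      nfree = 0;
      for (int m = 0; m < 26; ++m) {
        int xx = x + offx[m], yy = y + offy[m], zzi = z + offz[m];
        if (!inbounds(xx, yy, zzi)) continue;
        int j = site + off[m];
        if (mask[j] && occ[j] < 0) freenb[nfree++] = j;
      }
    };
    auto spawn = [&](int kind, int site, int passage) {
      Agent a;
      a.kind = kind; a.site = site; a.clock = 0.0; a.passage = passage;
      a.attached = false; a.arrested = false; a.alive = true;
      occ[site] = ag.size();
      ag.push_back(a);
      birth(kind);
    };
    // nearest agent of a kind-class within Chebyshev radius; returns site or -1
    auto nearest_of = [&](int site, int rad, bool tumor_class, int want_kind) {
      int x, y, z; coords(site, x, y, z);
      int best = -1; double bestd = 1e18; int nties = 0;
      for (int dz = -rad; dz <= rad; ++dz)
        for (int dy = -rad; dy <= rad; ++dy)
          for (int dx = -rad; dx <= rad; ++dx) {
            if (!(dx || dy || dz)) continue;
            int xx = x + dx, yy = y + dy, zzi = z + dz;
            if (!inbounds(xx, yy, zzi)) continue;
            int j = site + dx * sx + dy * sy + dz * sz;
            int o = occ[j];
            if (o < 0) continue;
            int kk = ag[o].kind;
            bool hit = tumor_class ? (kk == 1 || kk == 2) : (kk == want_kind);
            if (!hit) continue;
            double d2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
            if (d2 < bestd - 1e-9) { bestd = d2; best = j; nties = 1; }
            else if (d2 < bestd + 1e-9) {  // reservoir tie-break
              ++nties;
              if (runif1() < 1.0 / nties) best = j;
            }
          }
      return best;
    };
    auto move_agent = [&](int idx, int to) {
      occ[ag[idx].site] = -1;
      ag[idx].site = to;
      occ[to] = idx;
    };
    auto migrate_toward = [&](int idx, int target_site) {
      int nfree; free_neighbors(ag[idx].site, nfree);
      if (!nfree) return;
      if (target_site < 0) { move_agent(idx, freenb[rint_below(nfree)]); return; }
      int tx, ty, tz; coords(target_site, tx, ty, tz);
      double best = 1e18; int chosen = -1, nties = 0;
      for (int m = 0; m < nfree; ++m) {
        int x, y, z; coords(freenb[m], x, y, z);
        double d2 = (double)(x - tx) * (x - tx) + (double)(y - ty) * (y - ty) +
                    (double)(z - tz) * (z - tz);
        if (d2 < best - 1e-9) { best = d2; chosen = freenb[m]; nties = 1; }
        else if (d2 < best + 1e-9) {
          ++nties;
          if (runif1() < 1.0 / nties) chosen = freenb[m];
        }
      }
      move_agent(idx, chosen);
    };

    for (size_t oi = 0; oi < order.size(); ++oi) {
      int idx = order[oi];
      Agent &a = ag[idx];
      if (!a.alive) continue;  // killed earlier this step

      if (a.kind == 1) {  // ---- MIC ----
        double s = localstiff[a.site];
        double p_die = mic_p_apop0 +
          (btz > 0 ? interp2(micd_s, micd_b, micd_p, s, btz) : 0.0);
        if (runif1() < p_die) { death(idx); continue; }
        bool bmsc_near = s > ecm_floor + 1e-9;
        if (!a.attached && bmsc_near) {
          if (runif1() < interp1(adh_x, adh_y, s)) a.attached = true;
        }
        if (!bmsc_near) a.attached = false;
        a.clock += dt;
        bool divided = false;
        if (a.clock >= mic_Tc &&
            runif1() < hilln(s, mic_div_pmax, mic_div_H, mic_div_n)) {
          int nfree; free_neighbors(a.site, nfree);
          if (nfree) {  // no space -> stay in M-phase, retry next step
            int dsite = freenb[rint_below(nfree)];
            double q = hilln(s, mic_sr_pmax, mic_sr_H, mic_sr_n);
            if (runif1() < q) {  // self-renewal: two MIC daughters
              a.clock = 0.0;
              spawn(1, dsite, 0);
            } else {             // differentiation: two MM daughters
              Dd[(1 - 1) * brow] += 1; counts[1]--;
              a.kind = 2; a.passage = 1; a.clock = 0.0; a.attached = false;
              counts[2]++; B[(2 - 1) * brow] += 1;
              spawn(2, dsite, 1);
            }
            divided = true;
          }
        }
        if (!divided && !ag[idx].attached && runif1() < mic_p_mig) {
          // climb the local stiffness gradient
          int nfree; free_neighbors(ag[idx].site, nfree);
          if (nfree) {
            double best = -1e18; int chosen = -1, nties = 0;
            for (int m = 0; m < nfree; ++m) {
              double v = localstiff[freenb[m]];
              if (v > best + 1e-9) { best = v; chosen = freenb[m]; nties = 1; }
              else if (v > best - 1e-9) {
                ++nties;
                if (runif1() < 1.0 / nties) chosen = freenb[m];
              }
            }
            move_agent(idx, chosen);
          }
        }

      } else if (a.kind == 2) {  // ---- MM ----
        if (a.passage >= LGN) { death(idx); continue; }
        double p_die = mm_p_apop0 + hilln(btz, mm_btz_pmax, mm_btz_H, 1.0);
        if (runif1() < p_die) { death(idx); continue; }
        double s = localstiff[a.site];
        a.clock += dt;
        bool divided = false;
        if (a.clock >= mm_Tc &&
            runif1() < hilln(s, mm_div_pmax, mm_div_H, mm_div_n)) {
          int nfree; free_neighbors(a.site, nfree);
          if (nfree) {
            int dsite = freenb[rint_below(nfree)];
            a.clock = 0.0; a.passage += 1;
            spawn(2, dsite, ag[idx].passage);
            divided = true;
          }
        }
        if (!divided && runif1() < mm_p_mig) {
          int nfree; free_neighbors(ag[idx].site, nfree);
          if (nfree) move_agent(idx, freenb[rint_below(nfree)]);
        }

      } else if (a.kind == 3) {  // ---- CD8 ----
        if (runif1() < cd8_p_die) { death(idx); continue; }
        // lysis of an adjacent myeloma cell
        int tgt = nearest_of(a.site, 1, true, 0);
        if (tgt >= 0) {
          int o = occ[tgt];
          double p = cd8_p_lysis * (ag[o].attached ? cd8_protect : 1.0);
          if (runif1() < p) death(o);
        }
        a.clock += dt;
        if (a.clock >= cd8_Tc) {
          if (a.arrested) {  // suppression pauses one opportunity
            a.arrested = false;
            a.clock = 0.0;
          } else {
            int x, y, z; coords(a.site, x, y, z);
            int ntreg = 0;
            for (int m = 0; m < 26; ++m) {
              int xx = x + offx[m], yy = y + offy[m], zzi = z + offz[m];
              if (!inbounds(xx, yy, zzi)) continue;
              int o2 = occ[a.site + off[m]];
              if (o2 >= 0 && ag[o2].kind == 4) ++ntreg;
            }
            double tg = tgfb[a.site];
            double p = cd8_p_div0 /
                         (1.0 + std::pow(tg / cd8_tgfb_H, cd8_tgfb_n)) /
                         (1.0 + ntreg / cd8_treg_K) +
                       cd8_len_pmax * len / (cd8_len_H + len);
            if (p > 1.0) p = 1.0;
            if (runif1() < p) {
              int nfree; free_neighbors(a.site, nfree);
              if (nfree) {
                ag[idx].clock = 0.0;
                spawn(3, freenb[rint_below(nfree)], 0);
              }
            }
          }
        }
        if (ag[idx].alive && runif1() < cd8_p_mig) {
          int t2 = nearest_of(ag[idx].site, cd8_rad, true, 0);
          migrate_toward(idx, t2);
        }

      } else {  // ---- TREG ----
        if (runif1() < tr_p_die) { death(idx); continue; }
        int cd8nb = nearest_of(a.site, 1, false, 3);
        if (cd8nb >= 0 && runif1() < tr_p_supp) {
          int o = occ[cd8nb];
          if (runif1() < tr_arrest) ag[o].arrested = true;
          else death(o);
        }
        a.clock += dt;
        if (a.clock >= tr_Tc) {
          double p = hilln(tgfb[a.site], tr_p_div_pmax, tr_tgfb_H, tr_tgfb_n) *
                     (1.0 - tr_len_smax * len / (tr_len_sH + len));
          if (p < 0) p = 0;
          if (runif1() < p) {
            int nfree; free_neighbors(a.site, nfree);
            if (nfree) {
              ag[idx].clock = 0.0;
              spawn(4, freenb[rint_below(nfree)], 0);
            }
          }
        }
        if (ag[idx].alive && runif1() < tr_p_mig) {
          int t2 = nearest_of(ag[idx].site, tr_rad, false, 3);
          migrate_toward(idx, t2);
        }
      }
    }

    for (int kk = 1; kk <= 4; ++kk) pop(step + 1, kk - 1) = counts[kk];
    double ssum = 0;
    for (int i = 0; i < nbmsc; ++i) ssum += bmsc_stiff[i];
    stiff_mean[step + 1] = nbmsc ? ssum / nbmsc : ecm_floor;

    // compact the agent vector when mostly dead
    if (ag.size() > 512 && ag.size() > 2u * (counts[1] + counts[2] +
                                             counts[3] + counts[4])) {
      std::vector<Agent> keep;
      keep.reserve(counts[1] + counts[2] + counts[3] + counts[4]);
      for (size_t i = 0; i < ag.size(); ++i)
        if (ag[i].alive) keep.push_back(ag[i]);
      ag.swap(keep);
      std::fill(occ.begin(), occ.end(), -1);
      for (size_t i = 0; i < ag.size(); ++i) occ[ag[i].site] = i;
    }
  }

  List out = List::create(
    _["pop"] = pop, _["births"] = births, _["deaths"] = deaths,
    _["stiff_mean"] = stiff_mean);
  if (return_fields) {
    out["sdf1"] = NumericVector(sdf1.begin(), sdf1.end());
    out["tgfb"] = NumericVector(tgfb.begin(), tgfb.end());
  }
  if (return_agents) {
    int n_alive = counts[1] + counts[2] + counts[3] + counts[4];
    IntegerVector kind(n_alive), xx(n_alive), yy(n_alive), zz(n_alive),
        passage(n_alive);
    LogicalVector att(n_alive), arr(n_alive);
    NumericVector clk(n_alive);
    int j = 0;
    for (size_t i = 0; i < ag.size(); ++i) {
      if (!ag[i].alive) continue;
      int x, y, z; coords(ag[i].site, x, y, z);
      kind[j] = ag[i].kind; xx[j] = x + 1; yy[j] = y + 1; zz[j] = z + 1;
      passage[j] = ag[i].passage; att[j] = ag[i].attached;
      arr[j] = ag[i].arrested; clk[j] = ag[i].clock;
      ++j;
    }
    out["agents"] = DataFrame::create(
      _["kind"] = kind, _["x"] = xx, _["y"] = yy, _["z"] = zz,
      _["passage"] = passage, _["attached"] = att, _["arrested"] = arr,
      _["clock_h"] = clk);
  }
  return out;
}
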