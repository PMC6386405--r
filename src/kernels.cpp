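// Compiled kernels: Metropolis division dynamics, interface meshing,
// distance transforms, geodesic propagation, convex hull volume.
// Grids are passed as flat integer vectors with explicit dims,
// 0-based linear index i = x + nx*(y + ny*z). Label 0 = background.
// Hot loops assume occupied sites sit >= 1 voxel away from the grid
// border; R-side constructors guarantee that margin.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double hv_term(double v1, double N, double rho) {
  const double t1 = v1 - rho * N;
  const double t2 = (N - v1) - (1.0 - rho) * N;
  return std::cbrt(t1 * t1 + t2 * t2);
}

// 26-neighborhood offsets (3D) for a grid with strides (1, nx, nx*ny)
static void offsets26(int nx, int nxy, std::vector<int> &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        off.push_back(dx + nx * dy + nxy * dz);
      }
}

// 8-neighborhood offsets (2D)
static void offsets8(int nx, std::vector<int> &off) {
  off.clear();
  for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (dx == 0 && dy == 0) continue;
      off.push_back(dx + nx * dy);
    }
}

// Half-space direction offsets so each unordered pair is visited once.
static void half_offsets(const IntegerVector &dims, std::vector<int> &off) {
  off.clear();
  if (dims.size() == 3) {
    int nx = dims[0], nxy = dims[0] * dims[1];
    const int dirs[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},
      {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
      {1,1,1},{1,1,-1},{1,-1,1},{-1,1,1}};
    for (int k = 0; k < 13; ++k)
      off.push_back(dirs[k][0] + nx * dirs[k][1] + nxy * dirs[k][2]);
  } else {
    int nx = dims[0];
    const int dirs[4][2] = {{1,0},{0,1},{1,1},{1,-1}};
    for (int k = 0; k < 4; ++k)
      off.push_back(dirs[k][0] + nx * dirs[k][1]);
  }
}

// [[Rcpp::export]]
double cpp_count_discordant_pairs(IntegerVector labels, IntegerVector dims) {
  std::vector<int> off;
  half_offsets(dims, off);
  const int *lab = INTEGER(labels);
  const R_xlen_t n = labels.size();
  // margin guarantee: for any occupied site, site + off stays in range
  long long count = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const int li = lab[i];
    if (li == 0) continue;
    for (size_t k = 0; k < off.size(); ++k) {
      const R_xlen_t j = i + off[k];
      const int lj = lab[j];
      if (lj != 0 && lj != li) ++count;
    }
  }
  return (double)count;
}

// Change in discordant-pair count if `site` (0-based) were toggled 1<->2.
// [[Rcpp::export]]
int cpp_toggle_delta_pairs(IntegerVector labels, IntegerVector dims, int site) {
  std::vector<int> off;
  if (dims.size() == 3) offsets26(dims[0], dims[0] * dims[1], off);
  else offsets8(dims[0], off);
  const int *lab = INTEGER(labels);
  const int l = lab[site];
  if (l == 0) stop("site is not inside the mask");
  const int o = 3 - l;
  int same = 0, other = 0;
  for (size_t k = 0; k < off.size(); ++k) {
    const int lj = lab[site + off[k]];
    if (lj == l) ++same; else if (lj == o) ++other;
  }
  return same - other;
}

// Metropolis toggle dynamics on a 3D partition.
// labels: 0/1/2 grid; occ: 0-based linear indices of occupied sites.
// alpha_a2: energy per discordant neighbor pair (alpha * facet area), in kT.
// Uses R's RNG (seed set on the R side).
// [[Rcpp::export]]
List cpp_metropolis3d(IntegerVector labels, IntegerVector dims,
                      IntegerVector occ, double rho_star, double alpha_a2,
                      int n_cycles, bool early_stop, double early_tol,
                      int quench_max_cycles, int quench_ratio_band,
                      double hv_scale, double sched_start_frac,
                      double sched_end_frac, double rho_init_target) {
  const int nx = dims[0], nxy = dims[0] * dims[1];
  std::vector<int> off;
  offsets26(nx, nxy, off);
  std::vector<int8_t> lab(labels.size());
  for (R_xlen_t i = 0; i < labels.size(); ++i) lab[i] = (int8_t)labels[i];
  const int N = occ.size();
  const int *occp = INTEGER(occ);

  long long v1 = 0;
  for (int i = 0; i < N; ++i) if (lab[occp[i]] == 1) ++v1;
  // initial discordant count
  long long D = 0;
  {
    std::vector<int> hoff;
    half_offsets(dims, hoff);
    for (int i = 0; i < N; ++i) {
      const int s = occp[i];
      const int ls = lab[s];
      for (size_t k = 0; k < hoff.size(); ++k) {
        const int lj = lab[s + hoff[k]];
        if (lj != 0 && lj != ls) ++D;
      }
    }
  }

  std::vector<double> tr_hv, tr_ha;
  tr_hv.reserve(n_cycles + 1); tr_ha.reserve(n_cycles + 1);
  tr_hv.push_back(hv_scale * hv_term((double)v1, (double)N, rho_star));
  tr_ha.push_back(alpha_a2 * (double)D);

  long long n_down = 0, n_up_acc = 0, n_up_rej = 0;
  int cycles_run = 0;
  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    // target-ratio continuation: hold rho_init_target while the random
    // initial state coarsens into a compact two-domain configuration,
    // then slide the target linearly to rho_star; prevents the minority
    // phase from fragmenting into evaporating droplets at asymmetric
    // targets. sched_start_frac == sched_end_frac == 0 disables it.
    double rho_t = rho_star;
    if (sched_end_frac > 0.0) {
      const double prog = (double)cyc / (double)n_cycles;
      double u = (prog - sched_start_frac) /
        std::max(sched_end_frac - sched_start_frac, 1e-9);
      if (u < 0.0) u = 0.0;
      if (u > 1.0) u = 1.0;
      rho_t = rho_init_target + (rho_star - rho_init_target) * u;
    }
    for (int t = 0; t < N; ++t) {
      int idx = (int)(unif_rand() * N);
      if (idx >= N) idx = N - 1;
      const int s = occp[idx];
      const int l = lab[s];
      const int o = 3 - l;
      int same = 0, other = 0;
      for (int k = 0; k < 26; ++k) {
        const int lj = lab[s + off[k]];
        if (lj == l) ++same; else if (lj == o) ++other;
      }
      const int dD = same - other;
      const long long nv1 = (l == 1) ? v1 - 1 : v1 + 1;
      const double dH = alpha_a2 * (double)dD + hv_scale *
        (hv_term((double)nv1, (double)N, rho_t) -
         hv_term((double)v1, (double)N, rho_t));
      bool accept;
      if (dH <= 0.0) { accept = true; ++n_down; }
      else {
        accept = unif_rand() < std::exp(-dH);
        if (accept) ++n_up_acc; else ++n_up_rej;
      }
      if (accept) {
        lab[s] = (int8_t)o;
        v1 = nv1;
        D += dD;
      }
    }
    tr_hv.push_back(hv_scale * hv_term((double)v1, (double)N, rho_t));
    tr_ha.push_back(alpha_a2 * (double)D);
    cycles_run = cyc + 1;
    if (early_stop && cycles_run >= 200 && cycles_run % 100 == 0) {
      double m1 = 0, m0 = 0;
      for (int k = 0; k < 100; ++k) {
        m1 += tr_hv[cycles_run - k] + tr_ha[cycles_run - k];
        m0 += tr_hv[cycles_run - 100 - k] + tr_ha[cycles_run - 100 - k];
      }
      m1 /= 100.0; m0 /= 100.0;
      const double scale = std::max(std::abs(m0), 1e-12);
      if (std::abs(m1 - m0) / scale < early_tol) break;
    }
  }

  // zero-temperature descent: accept only strictly energy-lowering
  // toggles, with the realized volume-ratio held inside a band of
  // +/- quench_ratio_band sites around its value at descent start.
  // Removes thermal roughness and interface-detached bubbles without
  // letting the interface-curvature force erode an asymmetric cap.
  int quench_cycles = 0;
  const long long v1_q0 = v1;
  for (int qc = 0; qc < quench_max_cycles; ++qc) {
    bool moved = false;
    for (int t = 0; t < N; ++t) {
      const int s = occp[t];  // deterministic sweep
      const int l = lab[s];
      const int o = 3 - l;
      int same = 0, other = 0;
      for (int k = 0; k < 26; ++k) {
        const int lj = lab[s + off[k]];
        if (lj == l) ++same; else if (lj == o) ++other;
      }
      const int dD = same - other;
      const long long nv1 = (l == 1) ? v1 - 1 : v1 + 1;
      if (std::llabs(nv1 - v1_q0) > (long long)quench_ratio_band) continue;
      const double dH = alpha_a2 * (double)dD + hv_scale *
        (hv_term((double)nv1, (double)N, rho_star) -
         hv_term((double)v1, (double)N, rho_star));
      if (dH < 0.0) {
        lab[s] = (int8_t)o; v1 = nv1; D += dD; moved = true;
      }
    }
    quench_cycles = qc + 1;
    if (!moved) break;
  }

  IntegerVector out(labels.size());
  for (R_xlen_t i = 0; i < labels.size(); ++i) out[i] = lab[i];
  out.attr("dim") = dims;
  return List::create(
    _["labels"] = out, _["v1"] = (double)v1, _["v2"] = (double)(N - v1),
    _["n_sites"] = N, _["discordant_pairs"] = (double)D,
    _["trace_hv"] = tr_hv, _["trace_ha"] = tr_ha,
    _["cycles_run"] = cycles_run,
    _["quench_cycles"] = quench_cycles,
    _["n_down_moves"] = (double)n_down,
    _["n_up_accepted"] = (double)n_up_acc,
    _["n_up_rejected"] = (double)n_up_rej);
}

// Kawasaki exchange dynamics on a 2D partition: one site from each
// daughter swaps labels per attempt, so daughter areas are invariant.
// Energy: interface term only.
// [[Rcpp::export]]
List cpp_metropolis2d_exchange(IntegerVector labels, IntegerVector dims,
                               IntegerVector occ, double alpha_a2,
                               int n_cycles, int quench_max_cycles) {
  const int nx = dims[0];
  std::vector<int> off;
  offsets8(nx, off);
  std::vector<int8_t> lab(labels.size());
  for (R_xlen_t i = 0; i < labels.size(); ++i) lab[i] = (int8_t)labels[i];
  const int N = occ.size();
  const int *occp = INTEGER(occ);

  std::vector<int> list1, list2;
  std::vector<int> pos(labels.size(), -1);
  for (int i = 0; i < N; ++i) {
    const int s = occp[i];
    if (lab[s] == 1) { pos[s] = list1.size(); list1.push_back(s); }
    else             { pos[s] = list2.size(); list2.push_back(s); }
  }
  if (list1.empty() || list2.empty())
    stop("both daughters must be nonempty for exchange dynamics");

  long long D = 0;
  {
    std::vector<int> hoff;
    half_offsets(dims, hoff);
    for (int i = 0; i < N; ++i) {
      const int s = occp[i];
      const int ls = lab[s];
      for (size_t k = 0; k < hoff.size(); ++k) {
        const int lj = lab[s + hoff[k]];
        if (lj != 0 && lj != ls) ++D;
      }
    }
  }

  auto delta_toggle = [&](int s) {
    const int l = lab[s], o = 3 - l;
    int same = 0, other = 0;
    for (int k = 0; k < 8; ++k) {
      const int lj = lab[s + off[k]];
      if (lj == l) ++same; else if (lj == o) ++other;
    }
    return same - other;
  };

  std::vector<double> tr_ha;
  tr_ha.reserve(n_cycles + 1);
  tr_ha.push_back(alpha_a2 * (double)D);
  const long long v1_init = (long long)list1.size();

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    for (int t = 0; t < N; ++t) {
      int i1 = (int)(unif_rand() * list1.size());
      if (i1 >= (int)list1.size()) i1 = list1.size() - 1;
      int i2 = (int)(unif_rand() * list2.size());
      if (i2 >= (int)list2.size()) i2 = list2.size() - 1;
      const int a = list1[i1], b = list2[i2];
      // toggle a, then b, accumulating exact local deltas
      const int d1 = delta_toggle(a);
      lab[a] = 2;
      const int d2 = delta_toggle(b);
      lab[b] = 1;
      const double dH = alpha_a2 * (double)(d1 + d2);
      bool accept = (dH <= 0.0) || (unif_rand() < std::exp(-dH));
      if (accept) {
        D += d1 + d2;
        // swap list membership, positions preserved
        list1[i1] = b; pos[b] = i1;
        list2[i2] = a; pos[a] = i2;
      } else {
        lab[a] = 1; lab[b] = 2;
      }
    }
    tr_ha.push_back(alpha_a2 * (double)D);
  }

  // zero-temperature descent: random exchange proposals, accepted only
  // when strictly energy-lowering, until a full cycle makes no progress
  for (int qc = 0; qc < quench_max_cycles; ++qc) {
    bool moved = false;
    for (int t = 0; t < N; ++t) {
      int i1 = (int)(unif_rand() * list1.size());
      if (i1 >= (int)list1.size()) i1 = list1.size() - 1;
      int i2 = (int)(unif_rand() * list2.size());
      if (i2 >= (int)list2.size()) i2 = list2.size() - 1;
      const int a = list1[i1], b = list2[i2];
      const int d1 = delta_toggle(a);
      lab[a] = 2;
      const int d2 = delta_toggle(b);
      lab[b] = 1;
      if (alpha_a2 * (double)(d1 + d2) < 0.0) {
        D += d1 + d2;
        list1[i1] = b; pos[b] = i1;
        list2[i2] = a; pos[a] = i2;
        moved = true;
      } else {
        lab[a] = 1; lab[b] = 2;
      }
    }
    if (!moved) break;
  }

  if ((long long)list1.size() != v1_init)
    stop("internal error: exchange dynamics changed the daughter areas");

  IntegerVector out(labels.size());
  for (R_xlen_t i = 0; i < labels.size(); ++i) out[i] = lab[i];
  out.attr("dim") = dims;
  return List::create(
    _["labels"] = out, _["v1"] = (double)list1.size(),
    _["v2"] = (double)list2.size(), _["n_sites"] = N,
    _["discordant_pairs"] = (double)D, _["trace_ha"] = tr_ha);
}

// Count face-connected components among sites with label == target.
// [[Rcpp::export]]
int cpp_count_components(IntegerVector labels, IntegerVector dims, int target) {
  const bool is3d = dims.size() == 3;
  const int nx = dims[0];
  const int nxy = is3d ? dims[0] * dims[1] : 0;
  std::vector<int> off;
  if (is3d) { off = {1, -1, nx, -nx, nxy, -nxy}; }
  else      { off = {1, -1, nx, -nx}; }
  const int *lab = INTEGER(labels);
  const R_xlen_t n = labels.size();
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  int ncomp = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (lab[i] != target || seen[i]) continue;
    ++ncomp;
    seen[i] = 1;
    stack.push_back((int)i);
    while (!stack.empty()) {
      const int s = stack.back(); stack.pop_back();
      for (size_t k = 0; k < off.size(); ++k) {
        const int j = s + off[k];
        if (j < 0 || j >= (int)n) continue;
        if (lab[j] == target && !seen[j]) { seen[j] = 1; stack.push_back(j); }
      }
    }
  }
  return ncomp;
}

// Propagate labels into the background by multi-source BFS (face
// connectivity), so the 0.5-level interface surface continues smoothly
// past the mother-cell wall before being clipped back to the mask.
// [[Rcpp::export]]
IntegerVector cpp_extend_labels(IntegerVector labels, IntegerVector dims) {
  const bool is3d = dims.size() == 3;
  const int nx = dims[0];
  const int nxy = is3d ? dims[0] * dims[1] : 0;
  std::vector<int> off;
  if (is3d) { off = {1, -1, nx, -nx, nxy, -nxy}; }
  else      { off = {1, -1, nx, -nx}; }
  IntegerVector out = clone(labels);
  const R_xlen_t n = out.size();
  std::queue<int> q;
  for (R_xlen_t i = 0; i < n; ++i) if (out[i] != 0) q.push((int)i);
  // coordinates needed to avoid wrap-around at grid faces
  const int ny = dims[1];
  const int nz = is3d ? dims[2] : 1;
  auto inb = [&](int s, int k) {
    const int x = s % nx, y = (s / nx) % ny, z = is3d ? s / nxy : 0;
    switch (k) {
      case 0: return x + 1 < nx;
      case 1: return x - 1 >= 0;
      case 2: return y + 1 < ny;
      case 3: return y - 1 >= 0;
      case 4: return z + 1 < nz;
      default: return z - 1 >= 0;
    }
  };
  while (!q.empty()) {
    const int s = q.front(); q.pop();
    for (size_t k = 0; k < off.size(); ++k) {
      if (!inb(s, (int)k)) continue;
      const int j = s + off[k];
      if (out[j] == 0) { out[j] = out[s]; q.push(j); }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// --- marching tetrahedra over a scalar daughter-1 indicator field ---
// field: daughter-1 indicator (possibly box-smoothed) defined on the
// whole grid with background pre-extended; occ: 0/1 mother occupancy
// used to clip the surface back to the cell interior; level: isovalue.
// Returns an ntri x 9 matrix of physical triangle coordinates, oriented
// with normals pointing from daughter 1 toward daughter 2.
// [[Rcpp::export]]
NumericMatrix cpp_march_interface(NumericVector field, IntegerVector occ,
                                  IntegerVector dims, NumericVector vsz,
                                  NumericVector origin, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny;
  const double *fv = REAL(field);
  const int *om = INTEGER(occ);
  // cube corner offsets in grid coords
  const int cx[8] = {0,1,1,0,0,1,1,0};
  const int cy[8] = {0,0,1,1,0,0,1,1};
  const int cz[8] = {0,0,0,0,1,1,1,1};
  // 6 tetrahedra sharing diagonal 0-6
  const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  std::vector<double> tri;  // flat: 9 per triangle

  double P[8][3]; double F[8];
  auto emit = [&](const double *a, const double *b, const double *c,
                  const double *din, const double *dout) {
    // normal orientation: from daughter 1 (inside) toward daughter 2
    const double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    const double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    double nrm[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2],
                     u[0]*v[1]-u[1]*v[0]};
    const double a2 = nrm[0]*nrm[0] + nrm[1]*nrm[1] + nrm[2]*nrm[2];
    if (a2 < 1e-24) return;  // degenerate
    const double dir[3] = {dout[0]-din[0], dout[1]-din[1], dout[2]-din[2]};
    const bool flip = nrm[0]*dir[0] + nrm[1]*dir[1] + nrm[2]*dir[2] < 0;
    // clip: triangle centroid must fall in an occupied voxel
    const double gx = (a[0]+b[0]+c[0])/3.0, gy = (a[1]+b[1]+c[1])/3.0,
                 gz = (a[2]+b[2]+c[2])/3.0;
    const int ix = (int)std::lround(gx), iy = (int)std::lround(gy),
              iz = (int)std::lround(gz);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
      return;
    if (!om[ix + nx*iy + nxy*iz]) return;
    const double *v1 = flip ? c : b;
    const double *v2 = flip ? b : c;
    tri.push_back(a[0]); tri.push_back(a[1]); tri.push_back(a[2]);
    tri.push_back(v1[0]); tri.push_back(v1[1]); tri.push_back(v1[2]);
    tri.push_back(v2[0]); tri.push_back(v2[1]); tri.push_back(v2[2]);
  };

  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool anyin = false, anyout = false;
        for (int k = 0; k < 8; ++k) {
          const double f = fv[(x+cx[k]) + nx*(y+cy[k]) + nxy*(z+cz[k])];
          F[k] = f;
          if (f > level) anyin = true; else anyout = true;
          P[k][0] = x + cx[k]; P[k][1] = y + cy[k]; P[k][2] = z + cz[k];
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (F[T[k]] > level) in[nin++] = T[k]; else out[nout++] = T[k];
          }
          if (nin == 0 || nin == 4) continue;
          double M[4][3];  // interpolated crossings on in/out edges
          double cin[3] = {0,0,0}, cout[3] = {0,0,0};
          for (int k = 0; k < nin; ++k)
            for (int d = 0; d < 3; ++d) cin[d] += P[in[k]][d] / nin;
          for (int k = 0; k < nout; ++k)
            for (int d = 0; d < 3; ++d) cout[d] += P[out[k]][d] / nout;
          // linear interpolation along an edge from corner a (inside)
          // to corner b (outside)
          #define CROSS(Mrow, a, b) do { \
            const double fa = F[a], fb = F[b]; \
            double tt = (fa == fb) ? 0.5 : (fa - level) / (fa - fb); \
            if (tt < 0.0) tt = 0.0; if (tt > 1.0) tt = 1.0; \
            for (int d = 0; d < 3; ++d) \
              Mrow[d] = P[a][d] + tt * (P[b][d] - P[a][d]); \
          } while (0)
          if (nin == 1 || nin == 3) {
            if (nin == 1) {
              CROSS(M[0], in[0], out[0]);
              CROSS(M[1], in[0], out[1]);
              CROSS(M[2], in[0], out[2]);
            } else {
              CROSS(M[0], in[0], out[0]);
              CROSS(M[1], in[1], out[0]);
              CROSS(M[2], in[2], out[0]);
            }
            emit(M[0], M[1], M[2], cin, cout);
          } else {  // nin == 2: quad from the 4 crossing edges
            CROSS(M[0], in[0], out[0]);
            CROSS(M[1], in[0], out[1]);
            CROSS(M[2], in[1], out[1]);
            CROSS(M[3], in[1], out[0]);
            emit(M[0], M[1], M[2], cin, cout);
            emit(M[0], M[2], M[3], cin, cout);
          }
          #undef CROSS
        }
      }

  const int ntri = tri.size() / 9;
  NumericMatrix outm(ntri, 9);
  for (int i = 0; i < ntri; ++i)
    for (int j = 0; j < 9; ++j) {
      const int d = j % 3;
      outm(i, j) = origin[d] + tri[9*i + j] * vsz[d];
    }
  return outm;
}

// --- exact squared Euclidean distance transform (Felzenszwalb) ---
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double step) {
  const double INF = 1e30;
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    const double fq = f[q] ;
    double s;
    while (true) {
      const int p = v[k];
      s = ((fq + (double)q*q*step*step) - (f[p] + (double)p*p*step*step)) /
          (2.0 * step * step * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k+1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k+1] < (double)q) ++k;
    const int p = v[k];
    const double dq = (double)(q - p) * step;
    d[q] = dq * dq + f[p];
  }
}

// Squared distance (um^2) from each foreground voxel to the nearest
// background voxel center; background voxels get 0. Assumes a
// background margin (the array border is not treated as background).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims,
                         NumericVector vsz) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() == 3 ? dims[2] : 1;
  const int nxy = nx * ny;
  const double INF = 1e30;
  std::vector<double> g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    g[i] = mask[i] ? INF : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      const int base = nx*y + nxy*zz;
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, v, z, nx, vsz[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // y pass
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      const int base = x + nxy*zz;
      for (int y = 0; y < ny; ++y) f[y] = g[base + nx*y];
      dt1d(f, d, v, z, ny, vsz[1]);
      for (int y = 0; y < ny; ++y) g[base + nx*y] = d[y];
    }
  // z pass
  if (nz > 1)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int base = x + nx*y;
        for (int zz = 0; zz < nz; ++zz) f[zz] = g[base + nxy*zz];
        dt1d(f, d, v, z, nz, vsz[2]);
        for (int zz = 0; zz < nz; ++zz) g[base + nxy*zz] = d[zz];
      }
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = g[i];
  out.attr("dim") = dims;
  return out;
}

// Single-source geodesic distances inside the mask (26-neighbor graph,
// Euclidean step weights). Returns distances (um) and the farthest voxel.
// [[Rcpp::export]]
List cpp_geodesic_sweep(IntegerVector mask, IntegerVector dims,
                        NumericVector vsz, int start) {
  const int nx = dims[0], ny = dims[1], nz = dims.size() == 3 ? dims[2] : 1;
  const int nxy = nx * ny;
  const bool is3d = dims.size() == 3;
  std::vector<int> off; std::vector<double> w;
  for (int dz = (is3d ? -1 : 0); dz <= (is3d ? 1 : 0); ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        off.push_back(dx + nx*dy + nxy*dz);
        const double ex = dx*vsz[0], ey = dy*vsz[1],
                     ez = is3d ? dz*vsz[2] : 0.0;
        w.push_back(std::sqrt(ex*ex + ey*ey + ez*ez));
      }
  const double INF = 1e30;
  std::vector<double> dist(mask.size(), INF);
  typedef std::pair<double,int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[start] = 0.0;
  pq.push(QE(0.0, start));
  const int *m = INTEGER(mask);
  while (!pq.empty()) {
    const QE top = pq.top(); pq.pop();
    const int s = top.second;
    if (top.first > dist[s]) continue;
    const int x = s % nx, y = (s / nx) % ny, zz = is3d ? s / nxy : 0;
    for (size_t k = 0; k < off.size(); ++k) {
      // reject wrap-around
      const int j = s + off[k];
      if (j < 0 || j >= (int)mask.size()) continue;
      const int jx = j % nx, jy = (j / nx) % ny, jz = is3d ? j / nxy : 0;
      if (std::abs(jx - x) > 1 || std::abs(jy - y) > 1 ||
          std::abs(jz - zz) > 1) continue;
      if (!m[j]) continue;
      const double nd = dist[s] + w[k];
      if (nd < dist[j]) { dist[j] = nd; pq.push(QE(nd, j)); }
    }
  }
  double dmax = 0.0; int amax = start;
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    if (m[i] && dist[i] < INF && dist[i] > dmax) {
      dmax = dist[i]; amax = (int)i;
    }
  return List::create(_["max_dist"] = dmax, _["argmax"] = amax + 1);
}

// Exact point-to-triangle closest point (Ericson, Real-Time Collision
// Detection). Returns squared distance; cp receives the closest point.
static double pt_tri_sq(const double *p, const double *a, const double *b,
                        const double *c, double *cp) {
  double ab[3], ac[3], ap[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d]-a[d]; ac[d] = c[d]-a[d]; ap[d] = p[d]-a[d];
  }
  const double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  const double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  auto finish = [&](double u, double v) {
    double sq = 0.0;
    for (int d = 0; d < 3; ++d) {
      cp[d] = a[d] + u*ab[d] + v*ac[d];
      const double t = p[d]-cp[d];
      sq += t*t;
    }
    return sq;
  };
  if (d1 <= 0 && d2 <= 0) return finish(0, 0);
  double bp[3], cpv[3];
  for (int d = 0; d < 3; ++d) { bp[d] = p[d]-b[d]; cpv[d] = p[d]-c[d]; }
  const double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  const double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return finish(1, 0);
  const double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return finish(d1/(d1-d3), 0);
  const double d5 = ab[0]*cpv[0]+ab[1]*cpv[1]+ab[2]*cpv[2];
  const double d6 = ac[0]*cpv[0]+ac[1]*cpv[1]+ac[2]*cpv[2];
  if (d6 >= 0 && d5 <= d6) return finish(0, 1);
  const double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return finish(0, d2/(d2-d6));
  const double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4-d3) >= 0 && (d5-d6) >= 0) {
    const double w = (d4-d3)/((d4-d3)+(d5-d6));
    return finish(1-w, w);
  }
  const double den = 1.0/(va+vb+vc);
  return finish(vb*den, vc*den);
}

// Minimum distance from a point to a triangle soup (ntri x 9 matrix).
// [[Rcpp::export]]
List cpp_point_mesh_distance(NumericVector p, NumericMatrix tri) {
  const int n = tri.nrow();
  if (n == 0) stop("mesh has no triangles");
  double best = R_PosInf, bcp[3] = {0,0,0};
  double pp[3] = {p[0], p[1], p[2]};
  for (int i = 0; i < n; ++i) {
    double a[3] = {tri(i,0), tri(i,1), tri(i,2)};
    double b[3] = {tri(i,3), tri(i,4), tri(i,5)};
    double c[3] = {tri(i,6), tri(i,7), tri(i,8)};
    double cp[3];
    const double sq = pt_tri_sq(pp, a, b, c, cp);
    if (sq < best) {
      best = sq;
      bcp[0] = cp[0]; bcp[1] = cp[1]; bcp[2] = cp[2];
    }
  }
  return List::create(_["distance"] = std::sqrt(best),
                      _["closest"] = NumericVector::create(
                        bcp[0], bcp[1], bcp[2]));
}

// Discrete convex closure: iteratively fill, along each of the 13
// lattice direction families, every gap between the first and last
// occupied voxel of each line, until a fixpoint. The result contains
// the input and approximates the voxelized convex hull from inside;
// used for the convexity morphometric (volume / closure volume <= 1).
// [[Rcpp::export]]
IntegerVector cpp_convex_closure(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int dirs[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},
    {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
    {1,1,1},{1,1,-1},{1,-1,1},{-1,1,1}};
  IntegerVector occ = clone(mask);
  auto at = [&](int x, int y, int z) -> int& {
    return occ[x + nx * (y + ny * (long long)z)];
  };
  bool changed = true;
  int pass = 0;
  while (changed && pass < 20) {
    changed = false;
    ++pass;
    for (int k = 0; k < 13; ++k) {
      const int dx = dirs[k][0], dy = dirs[k][1], dz = dirs[k][2];
      for (int z0 = 0; z0 < nz; ++z0)
        for (int y0 = 0; y0 < ny; ++y0)
          for (int x0 = 0; x0 < nx; ++x0) {
            // only line start points (predecessor out of grid)
            const int px = x0 - dx, py = y0 - dy, pz = z0 - dz;
            if (px >= 0 && px < nx && py >= 0 && py < ny &&
                pz >= 0 && pz < nz) continue;
            int x = x0, y = y0, z = z0;
            int first = -1, last = -1, pos = 0;
            while (x >= 0 && x < nx && y >= 0 && y < ny &&
                   z >= 0 && z < nz) {
              if (at(x, y, z)) { if (first < 0) first = pos; last = pos; }
              x += dx; y += dy; z += dz; ++pos;
            }
            if (first < 0 || last <= first + 1) continue;
            x = x0 + dx * first; y = y0 + dy * first; z = z0 + dz * first;
            for (int p = first; p <= last; ++p) {
              if (!at(x, y, z)) { at(x, y, z) = 1; changed = true; }
              x += dx; y += dy; z += dz;
            }
          }
    }
  }
  occ.attr("dim") = dims;
  return occ;
}
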