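#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Supercover rasterization: mark every grid cell a continuous segment touches.
// Coordinates are continuous, in cell units; cell (i,j) covers [i,i+1)x[j,j+1).
// Amanatides & Woo style traversal; at (near-)corner crossings both adjacent
// cells are marked so thin objects stay connected.
// ---------------------------------------------------------------------------

static inline void mark2(std::vector<int> &img, int nrow, int ncol,
                         int row, int col) {
  if (row >= 0 && row < nrow && col >= 0 && col < ncol)
    img[row + (size_t)nrow * col] = 1;
}

static void traverse2d(std::vector<int> &img, int nrow, int ncol,
                       double c0, double r0, double c1, double r1) {
  const double eps = 1e-9;
  int ic = (int)std::floor(c0), ir = (int)std::floor(r0);
  double dc = c1 - c0, dr = r1 - r0;
  int sc = dc > 0 ? 1 : -1, sr = dr > 0 ? 1 : -1;
  double tMaxC, tMaxR, tDeltaC, tDeltaR;
  const double INF = 1e300;
  if (dc == 0) { tMaxC = INF; tDeltaC = INF; }
  else {
    double b = sc > 0 ? ic + 1.0 : (double)ic;
    tMaxC = (b - c0) / dc; tDeltaC = sc / dc;
  }
  if (dr == 0) { tMaxR = INF; tDeltaR = INF; }
  else {
    double b = sr > 0 ? ir + 1.0 : (double)ir;
    tMaxR = (b - r0) / dr; tDeltaR = sr / dr;
  }
  mark2(img, nrow, ncol, ir, ic);
  long guard = 4 * ((long)std::fabs(dc) + (long)std::fabs(dr) + 8);
  while ((tMaxC <= 1.0 + eps || tMaxR <= 1.0 + eps) && guard-- > 0) {
    if (tMaxC > 1.0 + eps && tMaxR > 1.0 + eps) break;
    if (std::fabs(tMaxC - tMaxR) < eps) {
      // corner crossing: supercover keeps both side cells
      mark2(img, nrow, ncol, ir, ic + sc);
      mark2(img, nrow, ncol, ir + sr, ic);
      ic += sc; ir += sr; tMaxC += tDeltaC; tMaxR += tDeltaR;
    } else if (tMaxC < tMaxR) {
      ic += sc; tMaxC += tDeltaC;
    } else {
      ir += sr; tMaxR += tDeltaR;
    }
    mark2(img, nrow, ncol, ir, ic);
  }
}

// [[Rcpp::export(name = ".raster_edges_2d")]]
LogicalMatrix raster_edges_2d(NumericVector col0, NumericVector row0,
                              NumericVector col1, NumericVector row1,
                              int nrow, int ncol) {
  std::vector<int> img((size_t)nrow * ncol, 0);
  for (R_xlen_t i = 0; i < col0.size(); ++i)
    traverse2d(img, nrow, ncol, col0[i], row0[i], col1[i], row1[i]);
  LogicalMatrix out(nrow, ncol);
  for (size_t k = 0; k < img.size(); ++k) out[k] = img[k];
  return out;
}

static inline void mark3(std::vector<int> &vol, const int *d,
                         int x, int y, int z) {
  if (x >= 0 && x < d[0] && y >= 0 && y < d[1] && z >= 0 && z < d[2])
    vol[(size_t)x + (size_t)d[0] * (y + (size_t)d[1] * z)] = 1;
}

static void traverse3d(std::vector<int> &vol, const int *d,
                       double x0, double y0, double z0,
                       double x1, double y1, double z1) {
  const double eps = 1e-9, INF = 1e300;
  double p0[3] = { x0, y0, z0 }, p1[3] = { x1, y1, z1 };
  int ic[3], st[3];
  double tMax[3], tDelta[3];
  for (int a = 0; a < 3; ++a) {
    ic[a] = (int)std::floor(p0[a]);
    double dd = p1[a] - p0[a];
    st[a] = dd > 0 ? 1 : -1;
    if (dd == 0) { tMax[a] = INF; tDelta[a] = INF; }
    else {
      double b = st[a] > 0 ? ic[a] + 1.0 : (double)ic[a];
      tMax[a] = (b - p0[a]) / dd; tDelta[a] = st[a] / dd;
    }
  }
  mark3(vol, d, ic[0], ic[1], ic[2]);
  long guard = 4 * ((long)std::fabs(p1[0]-p0[0]) + (long)std::fabs(p1[1]-p0[1]) +
                    (long)std::fabs(p1[2]-p0[2]) + 8);
  for (;;) {
    double m = std::min(tMax[0], std::min(tMax[1], tMax[2]));
    if (m > 1.0 + eps || guard-- <= 0) break;
    // step every axis within eps of the minimum; mark single-axis
    // intermediates first so corner/edge crossings remain connected
    for (int a = 0; a < 3; ++a)
      if (std::fabs(tMax[a] - m) < eps) {
        int t[3] = { ic[0], ic[1], ic[2] };
        t[a] += st[a];
        mark3(vol, d, t[0], t[1], t[2]);
      }
    for (int a = 0; a < 3; ++a)
      if (std::fabs(tMax[a] - m) < eps) {
        ic[a] += st[a]; tMax[a] += tDelta[a];
      }
    mark3(vol, d, ic[0], ic[1], ic[2]);
  }
}

// [[Rcpp::export(name = ".raster_edges_3d")]]
LogicalVector raster_edges_3d(NumericVector x0, NumericVector y0, NumericVector z0,
                              NumericVector x1, NumericVector y1, NumericVector z1,
                              IntegerVector dims) {
  int d[3] = { dims[0], dims[1], dims[2] };
  std::vector<int> vol((size_t)d[0] * d[1] * d[2], 0);
  for (R_xlen_t i = 0; i < x0.size(); ++i)
    traverse3d(vol, d, x0[i], y0[i], z0[i], x1[i], y1[i], z1[i]);
  LogicalVector out(vol.size());
  for (size_t k = 0; k < vol.size(); ++k) out[k] = vol[k];
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point tests. A foreground cell is "simple" when its deletion leaves
// both the foreground and background topology of its neighborhood unchanged:
// 2-D: 8-connected foreground / 4-connected background;
// 3-D: 26-connected foreground / 6-connected background (the background test
// runs inside the 18-neighborhood, seeded from background face neighbors).
// ---------------------------------------------------------------------------

static bool simple_point_2d(const int nb[3][3]) {
  // nb[dr+1][dc+1]; center nb[1][1] assumed foreground
  int pos[8][2]; int fg[8]; int n = 0;
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc) {
      if (dr == 0 && dc == 0) continue;
      pos[n][0] = dr; pos[n][1] = dc; fg[n] = nb[dr + 1][dc + 1]; ++n;
    }
  // foreground 8-components in the punctured neighborhood
  int comp[8]; for (int i = 0; i < 8; ++i) comp[i] = -1;
  int ncomp = 0;
  for (int i = 0; i < 8; ++i) {
    if (!fg[i] || comp[i] >= 0) continue;
    int stack[8], top = 0; stack[top++] = i; comp[i] = ncomp;
    while (top > 0) {
      int u = stack[--top];
      for (int j = 0; j < 8; ++j) {
        if (!fg[j] || comp[j] >= 0) continue;
        if (std::abs(pos[u][0] - pos[j][0]) <= 1 &&
            std::abs(pos[u][1] - pos[j][1]) <= 1) {
          comp[j] = ncomp; stack[top++] = j;
        }
      }
    }
    ++ncomp;
  }
  if (ncomp != 1) return false;
  // background 4-components 4-adjacent to the center
  int seen[8]; for (int i = 0; i < 8; ++i) seen[i] = 0;
  int nbg = 0;
  for (int i = 0; i < 8; ++i) {
    if (fg[i] || seen[i]) continue;
    if (std::abs(pos[i][0]) + std::abs(pos[i][1]) != 1) continue; // seed: face nb
    ++nbg;
    int stack[8], top = 0; stack[top++] = i; seen[i] = 1;
    while (top > 0) {
      int u = stack[--top];
      for (int j = 0; j < 8; ++j) {
        if (fg[j] || seen[j]) continue;
        if (std::abs(pos[u][0] - pos[j][0]) +
            std::abs(pos[u][1] - pos[j][1]) == 1) {
          seen[j] = 1; stack[top++] = j;
        }
      }
    }
  }
  return nbg == 1;
}

static bool simple_point_3d(const int nb[3][3][3]) {
  int pos[26][3]; int fg[26]; int n = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        pos[n][0] = dx; pos[n][1] = dy; pos[n][2] = dz;
        fg[n] = nb[dx + 1][dy + 1][dz + 1]; ++n;
      }
  int comp[26]; for (int i = 0; i < 26; ++i) comp[i] = -1;
  int ncomp = 0;
  for (int i = 0; i < 26; ++i) {
    if (!fg[i] || comp[i] >= 0) continue;
    int stack[26], top = 0; stack[top++] = i; comp[i] = ncomp;
    while (top > 0) {
      int u = stack[--top];
      for (int j = 0; j < 26; ++j) {
        if (!fg[j] || comp[j] >= 0) continue;
        if (std::abs(pos[u][0] - pos[j][0]) <= 1 &&
            std::abs(pos[u][1] - pos[j][1]) <= 1 &&
            std::abs(pos[u][2] - pos[j][2]) <= 1) {
          comp[j] = ncomp; stack[top++] = j;
        }
      }
    }
    ++ncomp;
  }
  if (ncomp != 1) return false;
  // background 6-components inside N18, seeded from background face neighbors
  int in18[26], seen[26];
  for (int i = 0; i < 26; ++i) {
    int s = std::abs(pos[i][0]) + std::abs(pos[i][1]) + std::abs(pos[i][2]);
    in18[i] = (s <= 2); seen[i] = 0;
  }
  int nbg = 0;
  for (int i = 0; i < 26; ++i) {
    if (fg[i] || seen[i] || !in18[i]) continue;
    int s = std::abs(pos[i][0]) + std::abs(pos[i][1]) + std::abs(pos[i][2]);
    if (s != 1) continue; // seed only from face neighbors
    ++nbg;
    int stack[26], top = 0; stack[top++] = i; seen[i] = 1;
    while (top > 0) {
      int u = stack[--top];
      for (int j = 0; j < 26; ++j) {
        if (fg[j] || seen[j] || !in18[j]) continue;
        int d = std::abs(pos[u][0] - pos[j][0]) +
                std::abs(pos[u][1] - pos[j][1]) +
                std::abs(pos[u][2] - pos[j][2]);
        if (d == 1) { seen[j] = 1; stack[top++] = j; }
      }
    }
  }
  return nbg == 1;
}

// ---------------------------------------------------------------------------
// Sequential topology-preserving thinning with directional subiterations.
// Curve endpoints (exactly one foreground neighbor) and isolated cells are
// never deleted; each deletion re-checks simplicity at deletion time.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".thin_2d")]]
LogicalMatrix thin_2d(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> m((size_t)nr * nc);
  for (size_t k = 0; k < m.size(); ++k) m[k] = img[k] ? 1 : 0;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return m[r + (size_t)nr * c];
  };
  const int dir[4][2] = { {-1,0}, {1,0}, {0,-1}, {0,1} };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      std::vector<std::pair<int,int>> cand;
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r)
          if (at(r, c) && !at(r + dir[d][0], c + dir[d][1]))
            cand.push_back(std::make_pair(r, c));
      for (size_t k = 0; k < cand.size(); ++k) {
        int r = cand[k].first, c = cand[k].second;
        if (!at(r, c)) continue;
        int nb[3][3], cnt = 0;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            nb[dr + 1][dc + 1] = at(r + dr, c + dc);
            if (!(dr == 0 && dc == 0)) cnt += nb[dr + 1][dc + 1];
          }
        if (cnt <= 1) continue;              // endpoint or isolated
        if (!simple_point_2d(nb)) continue;
        m[r + (size_t)nr * c] = 0;
        changed = true;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (size_t k = 0; k < m.size(); ++k) out[k] = m[k];
  return out;
}

// [[Rcpp::export(name = ".thin_3d")]]
LogicalVector thin_3d(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> m((size_t)nx * ny * nz);
  for (size_t k = 0; k < m.size(); ++k) m[k] = mask[k] ? 1 : 0;
  auto at = [&](int x, int y, int z) -> int {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return m[(size_t)x + (size_t)nx * (y + (size_t)ny * z)];
  };
  // keep a foreground index list to avoid rescanning empty space
  std::vector<int> fgidx;
  for (size_t k = 0; k < m.size(); ++k) if (m[k]) fgidx.push_back((int)k);
  const int dir[6][3] = { {0,0,-1}, {0,0,1}, {0,-1,0}, {0,1,0}, {-1,0,0}, {1,0,0} };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<int> cand;
      for (size_t k = 0; k < fgidx.size(); ++k) {
        int idx = fgidx[k];
        if (!m[idx]) continue;
        int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
        if (!at(x + dir[d][0], y + dir[d][1], z + dir[d][2]))
          cand.push_back(idx);
      }
      for (size_t k = 0; k < cand.size(); ++k) {
        int idx = cand[k];
        if (!m[idx]) continue;
        int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
        int nb[3][3][3], cnt = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              nb[dx + 1][dy + 1][dz + 1] = at(x + dx, y + dy, z + dz);
              if (!(dx == 0 && dy == 0 && dz == 0))
                cnt += nb[dx + 1][dy + 1][dz + 1];
            }
        if (cnt <= 1) continue;              // endpoint or isolated
        if (!simple_point_3d(nb)) continue;
        m[idx] = 0;
        changed = true;
      }
    }
    if (changed) {
      std::vector<int> keep;
      for (size_t k = 0; k < fgidx.size(); ++k)
        if (m[fgidx[k]]) keep.push_back(fgidx[k]);
      fgidx.swap(keep);
    }
  }
  LogicalVector out(m.size());
  for (size_t k = 0; k < m.size(); ++k) out[k] = m[k];
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling on a 2-D or 3-D logical raster.
// connectivity: 8 or 4 (2-D, pass nz = 1), 26 or 6 (3-D).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  std::vector<int> offx, offy, offz;
  bool diag = (connectivity == 8 || connectivity == 26);
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = (nz > 1 ? -1 : 0); dz <= (nz > 1 ? 1 : 0); ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (!diag && s != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  int next = 0;
  std::vector<int> stack;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next; stack.push_back((int)i);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      int x = u % nx, y = (u / nx) % ny, z = u / (nx * ny);
      for (size_t o = 0; o < offx.size(); ++o) {
        int xx = x + offx[o], yy = y + offy[o], zz = z + offz[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        size_t v = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (mask[v] && !lab[v]) { lab[v] = next; stack.push_back((int)v); }
      }
    }
  }
  IntegerVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = lab[i];
  return out;
}
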