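// Compiled kernels for 3-D digital topology, morphology and image filtering.
// Arrays follow the package convention: dim = (nx, ny, nz), x fastest
// (R column-major), linear index = i + nx*(j + ny*k), all 0-based here.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

typedef long long ll;

static inline ll lin(int i, int j, int k, int nx, int ny) {
  return (ll)i + (ll)nx * ((ll)j + (ll)ny * (ll)k);
}

// ---------------------------------------------------------------- labeling

// Connected-component labeling, connectivity 6 or 26. Components are numbered
// in raster-scan order of their first (= minimum linear index) voxel, so
// label 1's minimum index precedes label 2's: ties between equal-sized
// components can be broken deterministically by label id.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const ll n = (ll)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
          continue;
        nb.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::vector<ll> stack;
  for (ll s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      ll v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      ll r = v / nx;
      int j = (int)(r % ny), k = (int)(r / ny);
      for (const auto& o : nb) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        ll w = lin(ii, jj, kk, nx, ny);
        if (mask[w] && !lab[w]) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// ------------------------------------------------------------------- Euler

// Cell counts (V, E, F, C) of the union of closed unit cubes centred on the
// foreground voxels. That union has the connectivity of the (26, 6) adjacency
// pair, so V - E + F - C is the Euler characteristic under that pair.
// [[Rcpp::export]]
NumericVector cpp_cell_counts(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return mask[lin(i, j, k, nx, ny)];
  };
  double C = 0, F = 0, E = 0, V = 0;
  const ll n = (ll)nx * ny * nz;
  for (ll s = 0; s < n; ++s)
    if (mask[s]) C += 1;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i)
        if (at(i - 1, j, k) || at(i, j, k)) F += 1;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (at(i, j - 1, k) || at(i, j, k)) F += 1;
  for (int k = 0; k <= nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (at(i, j, k - 1) || at(i, j, k)) F += 1;
  // edges along x, y, z
  for (int k = 0; k <= nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (at(i, j - 1, k - 1) || at(i, j, k - 1) || at(i, j - 1, k) || at(i, j, k))
          E += 1;
  for (int k = 0; k <= nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i)
        if (at(i - 1, j, k - 1) || at(i, j, k - 1) || at(i - 1, j, k) || at(i, j, k))
          E += 1;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i <= nx; ++i)
        if (at(i - 1, j - 1, k) || at(i, j - 1, k) || at(i - 1, j, k) || at(i, j, k))
          E += 1;
  for (int k = 0; k <= nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        bool c = false;
        for (int dz = -1; dz <= 0 && !c; ++dz)
          for (int dy = -1; dy <= 0 && !c; ++dy)
            for (int dx = -1; dx <= 0 && !c; ++dx)
              if (at(i + dx, j + dy, k + dz)) c = true;
        if (c) V += 1;
      }
  return NumericVector::create(V, E, F, C);
}

// ------------------------------------------------------------ simple point

// Bertrand-Malandain characterization under the (26, 6) pair: a voxel is
// simple iff T26 (number of 26-components of the foreground within the 26
// neighbours) and T6 (number of 6-components of the background within the
// 18-neighbourhood that are 6-adjacent to the centre) are both 1. The centre
// value itself does not enter.
static bool simple26_patch(const int* nb) {
  auto pos = [](int idx, int& x, int& y, int& z) {
    x = idx % 3 - 1;
    y = (idx / 3) % 3 - 1;
    z = idx / 9 - 1;
  };
  int labs[27];
  int stack[27], sp;
  for (int a = 0; a < 27; ++a) labs[a] = -1;
  int t26 = 0;
  for (int a = 0; a < 27; ++a) {
    if (a == 13 || !nb[a] || labs[a] >= 0) continue;
    ++t26;
    labs[a] = t26;
    sp = 0;
    stack[sp++] = a;
    while (sp) {
      int b = stack[--sp];
      int bx, by, bz;
      pos(b, bx, by, bz);
      for (int c = 0; c < 27; ++c) {
        if (c == 13 || !nb[c] || labs[c] >= 0) continue;
        int cx, cy, cz;
        pos(c, cx, cy, cz);
        if (std::abs(bx - cx) <= 1 && std::abs(by - cy) <= 1 &&
            std::abs(bz - cz) <= 1) {
          labs[c] = t26;
          stack[sp++] = c;
        }
      }
    }
  }
  if (t26 != 1) return false;
  auto in18 = [&](int idx) -> bool {
    if (idx == 13) return false;
    int x, y, z;
    pos(idx, x, y, z);
    return std::abs(x) + std::abs(y) + std::abs(z) <= 2;
  };
  int labs2[27];
  for (int a = 0; a < 27; ++a) labs2[a] = -1;
  int t6 = 0;
  for (int a = 0; a < 27; ++a) {
    int ax, ay, az;
    pos(a, ax, ay, az);
    if (!in18(a) || nb[a] || labs2[a] >= 0) continue;
    if (std::abs(ax) + std::abs(ay) + std::abs(az) != 1) continue;  // seed at face nbrs
    ++t6;
    labs2[a] = t6;
    sp = 0;
    stack[sp++] = a;
    while (sp) {
      int b = stack[--sp];
      int bx, by, bz;
      pos(b, bx, by, bz);
      for (int c = 0; c < 27; ++c) {
        if (!in18(c) || nb[c] || labs2[c] >= 0) continue;
        int cx, cy, cz;
        pos(c, cx, cy, cz);
        if (std::abs(bx - cx) + std::abs(by - cy) + std::abs(bz - cz) == 1) {
          labs2[c] = t6;
          stack[sp++] = c;
        }
      }
    }
  }
  return t6 == 1;
}

// patches: n x 27 matrix of 0/1, columns in x-fastest order of the 3x3x3 patch.
// [[Rcpp::export]]
LogicalVector cpp_is_simple_batch(IntegerMatrix patches) {
  const int n = patches.nrow();
  LogicalVector out(n);
  int nb[27];
  for (int r = 0; r < n; ++r) {
    for (int c = 0; c < 27; ++c) nb[c] = patches(r, c);
    out[r] = simple26_patch(nb);
  }
  return out;
}

// --------------------------------------------------------------- inflation

// Topologically constrained inflation of a trace. Growth is by rounds; each
// round's candidate shell is the 6-neighbourhood dilation of the current
// volume minus the volume, and shell voxels lying in the target are flipped
// on, one at a time in raster order, only if simple. The inner sweep repeats
// until the count of remaining difference voxels stabilizes. With
// stale_copy = true the simple tests read a per-round snapshot of the volume
// instead of the live volume.
// [[Rcpp::export]]
LogicalVector cpp_inflate(LogicalVector trace, LogicalVector target,
                          IntegerVector dim, int rounds, bool stale_copy,
                          int sweep_cap) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const ll n = (ll)nx * ny * nz;
  std::vector<char> vol(n), tgt(n);
  for (ll s = 0; s < n; ++s) {
    vol[s] = trace[s] ? 1 : 0;
    tgt[s] = target[s] ? 1 : 0;
  }
  std::vector<char> volCopy;
  std::vector<ll> shell, diff;
  int patch[27];
  auto fill_patch = [&](const std::vector<char>& src, int i, int j, int k) {
    int t = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx, ++t) {
          int ii = i + dx, jj = j + dy, kk = k + dz;
          patch[t] = (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                      kk >= nz)
                         ? 0
                         : src[lin(ii, jj, kk, nx, ny)];
        }
  };
  const int d6[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                        {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  for (int round = 0; round < rounds; ++round) {
    shell.clear();
    for (ll s = 0; s < n; ++s) {
      if (vol[s]) continue;
      int i = (int)(s % nx);
      ll r = s / nx;
      int j = (int)(r % ny), k = (int)(r / ny);
      bool adj = false;
      for (int q = 0; q < 6 && !adj; ++q) {
        int ii = i + d6[q][0], jj = j + d6[q][1], kk = k + d6[q][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        if (vol[lin(ii, jj, kk, nx, ny)]) adj = true;
      }
      if (adj) shell.push_back(s);  // ascending s = raster order, x fastest
    }
    if (shell.empty()) break;
    if (stale_copy) volCopy = vol;  // one snapshot per round
    long prev = -1, curr = 0;
    int sweeps = 0;
    while (curr != prev && sweeps < sweep_cap) {
      ++sweeps;
      diff.clear();
      for (ll s : shell)
        if (vol[s] != tgt[s]) diff.push_back(s);
      for (ll s : diff) {
        int i = (int)(s % nx);
        ll r = s / nx;
        int j = (int)(r % ny), k = (int)(r / ny);
        fill_patch(stale_copy ? volCopy : vol, i, j, k);
        if (simple26_patch(patch)) vol[s] = !vol[s];
      }
      prev = curr;
      curr = (long)diff.size();
    }
  }
  LogicalVector out(n);
  for (ll s = 0; s < n; ++s) out[s] = vol[s] != 0;
  return out;
}

// --------------------------------------------------- distance transform

// 1-D squared distance transform (lower envelope of parabolas) with sample
// spacing w; f/d are scratch of length n.
static void dt1d(std::vector<double>& f, std::vector<double>& d, double w,
                 int n, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = w * q, xv = w * v[k];
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = w * q;
    while (z[k + 1] < xq) ++k;
    double dx = xq - w * v[k];
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (in physical units given by spacing) from every
// voxel to the nearest foreground voxel of mask.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const ll n = (ll)nx * ny * nz;
  NumericVector out(n);
  for (ll s = 0; s < n; ++s) out[s] = mask[s] ? 0.0 : 1e200;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      ll base = lin(0, j, k, nx, ny);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, spacing[0], nx, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = out[lin(i, j, k, nx, ny)];
      dt1d(f, d, spacing[1], ny, v, z);
      for (int j = 0; j < ny; ++j) out[lin(i, j, k, nx, ny)] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = out[lin(i, j, k, nx, ny)];
      dt1d(f, d, spacing[2], nz, v, z);
      for (int k = 0; k < nz; ++k) out[lin(i, j, k, nx, ny)] = d[k];
    }
  return out;
}

// ------------------------------------------------------------------ blur

// Separable Gaussian blur, sigma per axis in voxel units, mirror boundary.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector a, IntegerVector dim,
                             NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const ll n = (ll)nx * ny * nz;
  std::vector<double> cur(a.begin(), a.end()), nxt(n);
  auto reflect = [](int i, int len) {
    while (i < 0 || i >= len) {
      if (i < 0) i = -i;
      if (i >= len) i = 2 * len - 2 - i;
    }
    return i;
  };
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * rad + 1);
    double tot = 0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t + rad] = std::exp(-0.5 * t * t / (s * s));
      tot += ker[t + rad];
    }
    for (auto& w : ker) w /= tot;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii = reflect(i + t, nx);
            if (axis == 1) jj = reflect(j + t, ny);
            if (axis == 2) kk = reflect(k + t, nz);
            acc += ker[t + rad] * cur[lin(ii, jj, kk, nx, ny)];
          }
          nxt[lin(i, j, k, nx, ny)] = acc;
        }
    std::swap(cur, nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}

// ----------------------------------------------------------- convolution

// One convolutional layer: dense cross-correlation with mirror padding so the
// spatial output shape equals the input shape. input dim (nx,ny,nz,cin),
// weights dim (kx,ky,kz,cin,cout), odd kernel sizes.
// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector input, IntegerVector dim, int cin,
                         NumericVector w, IntegerVector kdim, int cout,
                         NumericVector bias) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int rx = kx / 2, ry = ky / 2, rz = kz / 2;
  const ll nvox = (ll)nx * ny * nz;
  NumericVector out((ll)nvox * cout);
  auto reflect = [](int i, int len) {
    while (i < 0 || i >= len) {
      if (i < 0) i = -i;
      if (i >= len) i = 2 * len - 2 - i;
    }
    return i;
  };
  for (int co = 0; co < cout; ++co)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = bias[co];
          for (int ci = 0; ci < cin; ++ci)
            for (int dz = -rz; dz <= rz; ++dz)
              for (int dy = -ry; dy <= ry; ++dy)
                for (int dx = -rx; dx <= rx; ++dx) {
                  int ii = reflect(i + dx, nx);
                  int jj = reflect(j + dy, ny);
                  int kk = reflect(k + dz, nz);
                  ll widx = (ll)(dx + rx) +
                            (ll)kx * ((ll)(dy + ry) +
                                      (ll)ky * ((ll)(dz + rz) +
                                                (ll)kz * ((ll)ci + (ll)cin * co)));
                  acc += w[widx] * input[lin(ii, jj, kk, nx, ny) + nvox * ci];
                }
          out[lin(i, j, k, nx, ny) + nvox * co] = acc;
        }
  return out;
}

// --------------------------------------------------------- rasterization

// Draw 26-connected digital segments. Endpoints are 0-based voxel indices;
// interpolated coordinates are rounded with ties toward the smaller index.
// [[Rcpp::export]]
LogicalVector cpp_draw_segments(IntegerMatrix a, IntegerMatrix b,
                                IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const ll n = (ll)nx * ny * nz;
  LogicalVector out(n, false);
  auto rnd = [](double v) { return (int)std::ceil(v - 0.5); };
  for (int r = 0; r < a.nrow(); ++r) {
    int steps = std::max(
        {std::abs(a(r, 0) - b(r, 0)), std::abs(a(r, 1) - b(r, 1)),
         std::abs(a(r, 2) - b(r, 2))});
    for (int t = 0; t <= steps; ++t) {
      double fr = steps == 0 ? 0.0 : (double)t / steps;
      int i = rnd(a(r, 0) + fr * (b(r, 0) - a(r, 0)));
      int j = rnd(a(r, 1) + fr * (b(r, 1) - a(r, 1)));
      int k = rnd(a(r, 2) + fr * (b(r, 2) - a(r, 2)));
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
        stop("segment voxel outside grid");
      out[lin(i, j, k, nx, ny)] = true;
    }
  }
  return out;
}

// Paint solid balls (physical-unit radii) into a mask.
// [[Rcpp::export]]
LogicalVector cpp_paint_balls(LogicalVector mask, IntegerVector dim,
                              IntegerMatrix centers, NumericVector radius_um,
                              NumericVector pitch) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(mask);
  for (int c = 0; c < centers.nrow(); ++c) {
    double r = radius_um[c];
    int ri = (int)std::ceil(r / pitch[0]), rj = (int)std::ceil(r / pitch[1]),
        rk = (int)std::ceil(r / pitch[2]);
    double r2 = r * r;
    for (int dk = -rk; dk <= rk; ++dk)
      for (int dj = -rj; dj <= rj; ++dj)
        for (int di = -ri; di <= ri; ++di) {
          double d2 = di * pitch[0] * di * pitch[0] +
                      dj * pitch[1] * dj * pitch[1] +
                      dk * pitch[2] * dk * pitch[2];
          if (d2 > r2 + 1e-12) continue;
          int i = centers(c, 0) + di, j = centers(c, 1) + dj,
              k = centers(c, 2) + dk;
          if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
            continue;
          out[lin(i, j, k, nx, ny)] = true;
        }
  }
  return out;
}

// ------------------------------------------------------------ column peaks

// Per (x, y) column: the two strongest interior local maxima along z at least
// min_sep slices apart, with 3-point parabolic sub-voxel refinement.
// Returns slice positions (NaN where absent) and peak values.
// [[Rcpp::export]]
List cpp_column_peaks(NumericVector a, IntegerVector dim, int min_sep) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix z1(nx, ny), z2(nx, ny), v1(nx, ny), v2(nx, ny);
  std::vector<std::pair<double, int>> cand;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      cand.clear();
      for (int k = 1; k < nz - 1; ++k) {
        double vm = a[lin(i, j, k - 1, nx, ny)], vc = a[lin(i, j, k, nx, ny)],
               vp = a[lin(i, j, k + 1, nx, ny)];
        if (vc > vm && vc >= vp) cand.push_back({vc, k});
      }
      std::sort(cand.begin(), cand.end(),
                [](const std::pair<double, int>& p,
                   const std::pair<double, int>& q) { return p.first > q.first; });
      auto refine = [&](int k) {
        double vm = a[lin(i, j, k - 1, nx, ny)], vc = a[lin(i, j, k, nx, ny)],
               vp = a[lin(i, j, k + 1, nx, ny)];
        double den = vm - 2 * vc + vp;
        double del = std::abs(den) < 1e-300 ? 0.0 : 0.5 * (vm - vp) / den;
        if (del > 0.5) del = 0.5;
        if (del < -0.5) del = -0.5;
        return k + del;
      };
      z1(i, j) = NA_REAL;
      z2(i, j) = NA_REAL;
      v1(i, j) = 0;
      v2(i, j) = 0;
      if (!cand.empty()) {
        int k1 = cand[0].second;
        z1(i, j) = refine(k1);
        v1(i, j) = cand[0].first;
        for (size_t q = 1; q < cand.size(); ++q) {
          if (std::abs(cand[q].second - k1) >= min_sep) {
            z2(i, j) = refine(cand[q].second);
            v2(i, j) = cand[q].first;
            break;
          }
        }
      }
    }
  return List::create(_["z1"] = z1, _["z2"] = z2, _["v1"] = v1, _["v2"] = v2);
}

// ------------------------------------------------------------- med filter

// [[Rcpp::export]]
NumericMatrix cpp_medfilt2(NumericMatrix h, int halfwin) {
  const int nx = h.nrow(), ny = h.ncol();
  NumericMatrix out(nx, ny);
  std::vector<double> win;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      win.clear();
      for (int dj = -halfwin; dj <= halfwin; ++dj)
        for (int di = -halfwin; di <= halfwin; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
          double v = h(ii, jj);
          if (!ISNAN(v)) win.push_back(v);
        }
      if (win.empty()) {
        out(i, j) = NA_REAL;
        continue;
      }
      size_t m = win.size() / 2;
      std::nth_element(win.begin(), win.begin() + m, win.end());
      double med = win[m];
      if (win.size() % 2 == 0) {
        double lo = *std::max_element(win.begin(), win.begin() + m);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  return out;
}
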