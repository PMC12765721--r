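#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Closest point on a single triangle (a,b,c) to point p.
// Ericson, "Real-Time Collision Detection", section 5.1.5.
static inline void closestPtTriangle(const double *p, const double *a,
                                     const double *b, const double *c,
                                     double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

struct TriGrid {
  double lo[3];
  double cell;
  int nx, ny, nz;
  std::vector< std::vector<int> > bins;

  int idx(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }
  int clampi(int v, int hi) const { return v < 0 ? 0 : (v >= hi ? hi - 1 : v); }
};

static void buildGrid(const NumericMatrix &V, const IntegerMatrix &F,
                      TriGrid &g) {
  const int nf = F.nrow();
  double hi[3];
  for (int i = 0; i < 3; ++i) {
    g.lo[i] = std::numeric_limits<double>::infinity();
    hi[i] = -std::numeric_limits<double>::infinity();
  }
  const int nv = V.nrow();
  for (int v = 0; v < nv; ++v)
    for (int i = 0; i < 3; ++i) {
      double x = V(v, i);
      if (x < g.lo[i]) g.lo[i] = x;
      if (x > hi[i]) hi[i] = x;
    }
  // target ~ 2 triangles per occupied cell along a surface
  double ext = std::max(hi[0] - g.lo[0], std::max(hi[1] - g.lo[1], hi[2] - g.lo[2]));
  double target = ext / std::max(4.0, std::cbrt((double)nf) * 2.0);
  if (!(target > 0) || !std::isfinite(target)) target = 1.0;
  g.cell = target;
  g.nx = std::max(1, (int)std::floor((hi[0] - g.lo[0]) / g.cell) + 1);
  g.ny = std::max(1, (int)std::floor((hi[1] - g.lo[1]) / g.cell) + 1);
  g.nz = std::max(1, (int)std::floor((hi[2] - g.lo[2]) / g.cell) + 1);
  g.bins.assign((size_t)g.nx * g.ny * g.nz, std::vector<int>());
  for (int f = 0; f < nf; ++f) {
    double blo[3], bhi[3];
    for (int i = 0; i < 3; ++i) {
      double x0 = V(F(f, 0), i), x1 = V(F(f, 1), i), x2 = V(F(f, 2), i);
      blo[i] = std::min(x0, std::min(x1, x2));
      bhi[i] = std::max(x0, std::max(x1, x2));
    }
    int i0 = g.clampi((int)std::floor((blo[0] - g.lo[0]) / g.cell), g.nx);
    int i1 = g.clampi((int)std::floor((bhi[0] - g.lo[0]) / g.cell), g.nx);
    int j0 = g.clampi((int)std::floor((blo[1] - g.lo[1]) / g.cell), g.ny);
    int j1 = g.clampi((int)std::floor((bhi[1] - g.lo[1]) / g.cell), g.ny);
    int k0 = g.clampi((int)std::floor((blo[2] - g.lo[2]) / g.cell), g.nz);
    int k1 = g.clampi((int)std::floor((bhi[2] - g.lo[2]) / g.cell), g.nz);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          g.bins[g.idx(i, j, k)].push_back(f);
  }
}

// Exact closest point on a triangle mesh for each query point.
// V: nv x 3 vertices, F: nf x 3 zero-based face indices, P: np x 3 queries.
// Returns list(dist, point (np x 3), face (1-based)).
// [[Rcpp::export(name = ".cpp_closest_on_mesh")]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriGrid g;
  buildGrid(V, F, g);
  const int np = P.nrow();
  NumericVector dist(np);
  NumericMatrix cp(np, 3);
  IntegerVector face(np);

  int maxdim = std::max(g.nx, std::max(g.ny, g.nz));
  for (int q = 0; q < np; ++q) {
    double p[3] = { P(q, 0), P(q, 1), P(q, 2) };
    int ci = g.clampi((int)std::floor((p[0] - g.lo[0]) / g.cell), g.nx);
    int cj = g.clampi((int)std::floor((p[1] - g.lo[1]) / g.cell), g.ny);
    int ck = g.clampi((int)std::floor((p[2] - g.lo[2]) / g.cell), g.nz);
    double best = std::numeric_limits<double>::infinity();
    double bestpt[3] = {0, 0, 0};
    int bestf = -1;
    // expanding shells of cells; safe to stop once the nearest unvisited
    // shell is farther than the best distance found
    auto scanCell = [&](int i, int j, int k) {
      if (i < 0 || i >= g.nx || j < 0 || j >= g.ny || k < 0 || k >= g.nz)
        return;
      const std::vector<int> &bin = g.bins[g.idx(i, j, k)];
      for (size_t t = 0; t < bin.size(); ++t) {
        int f = bin[t];
        double a[3] = { V(F(f, 0), 0), V(F(f, 0), 1), V(F(f, 0), 2) };
        double b[3] = { V(F(f, 1), 0), V(F(f, 1), 1), V(F(f, 1), 2) };
        double c[3] = { V(F(f, 2), 0), V(F(f, 2), 1), V(F(f, 2), 2) };
        double out[3];
        closestPtTriangle(p, a, b, c, out);
        double dx = out[0] - p[0], dy = out[1] - p[1], dz = out[2] - p[2];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < best) {
          best = d;
          bestf = f;
          bestpt[0] = out[0]; bestpt[1] = out[1]; bestpt[2] = out[2];
        }
      }
    };
    for (int r = 0; r <= 2 * maxdim; ++r) {
      double shellmin = (r - 1) * g.cell; // lower bound to any cell in shell r
      if (bestf >= 0 && shellmin > best) break;
      int i0 = ci - r, i1 = ci + r, j0 = cj - r, j1 = cj + r,
          k0 = ck - r, k1 = ck + r;
      if (r == 0) { scanCell(ci, cj, ck); continue; }
      // top and bottom plates
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          scanCell(i, j, k0);
          scanCell(i, j, k1);
        }
      // side walls of the remaining ring
      for (int k = k0 + 1; k <= k1 - 1; ++k) {
        for (int i = i0; i <= i1; ++i) { scanCell(i, j0, k); scanCell(i, j1, k); }
        for (int j = j0 + 1; j <= j1 - 1; ++j) { scanCell(i0, j, k); scanCell(i1, j, k); }
      }
    }
    dist[q] = best;
    face[q] = bestf + 1;
    cp(q, 0) = bestpt[0]; cp(q, 1) = bestpt[1]; cp(q, 2) = bestpt[2];
  }
  return List::create(_["dist"] = dist, _["point"] = cp, _["face"] = face);
}

// Orthographic rasterization with z-buffer.
// P2: nv x 3 projected vertices (x, y in mm in view plane, z = depth toward
// viewer, larger = closer); F: nf x 3 zero-based faces; VAL: nv x nc
// per-vertex attributes, barycentrically interpolated; W,H raster size;
// x0,y0 view-plane coordinates of the centre of pixel (1,1); px pixel size.
// Returns list(value = W*H x nc, depth, covered) in column-major (x fastest).
// [[Rcpp::export(name = ".cpp_rasterize")]]
List cpp_rasterize(NumericMatrix P2, IntegerMatrix F, NumericMatrix VAL,
                   int W, int H, double x0, double y0, double px) {
  const int nf = F.nrow(), nc = VAL.ncol();
  NumericMatrix value((size_t)W * H, nc);
  std::fill(value.begin(), value.end(), NA_REAL);
  NumericVector depth((size_t)W * H, -std::numeric_limits<double>::infinity());
  LogicalVector covered((size_t)W * H, false);
  IntegerVector fhit((size_t)W * H, NA_INTEGER);

  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
    double ax = P2(ia, 0), ay = P2(ia, 1), az = P2(ia, 2);
    double bx = P2(ib, 0), by = P2(ib, 1), bz = P2(ib, 2);
    double cx = P2(ic, 0), cy = P2(ic, 1), cz = P2(ic, 2);
    double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(det) < 1e-14) continue; // edge-on triangle
    double xmin = std::min(ax, std::min(bx, cx)), xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::ceil((xmin - x0) / px - 1e-9));
    int i1 = std::min(W - 1, (int)std::floor((xmax - x0) / px + 1e-9));
    int j0 = std::max(0, (int)std::ceil((ymin - y0) / px - 1e-9));
    int j1 = std::min(H - 1, (int)std::floor((ymax - y0) / px + 1e-9));
    for (int j = j0; j <= j1; ++j) {
      double pyc = y0 + j * px;
      for (int i = i0; i <= i1; ++i) {
        double pxc = x0 + i * px;
        double l1 = ((pxc - ax) * (cy - ay) - (pyc - ay) * (cx - ax)) / det;
        double l2 = ((bx - ax) * (pyc - ay) - (by - ay) * (pxc - ax)) / det;
        double l0 = 1.0 - l1 - l2;
        if (l0 < -1e-9 || l1 < -1e-9 || l2 < -1e-9) continue;
        double z = l0 * az + l1 * bz + l2 * cz;
        size_t pix = (size_t)j * W + i;
        if (z > depth[pix]) {
          depth[pix] = z;
          covered[pix] = true;
          fhit[pix] = f + 1;
          for (int c = 0; c < nc; ++c)
            value(pix, c) = l0 * VAL(ia, c) + l1 * VAL(ib, c) + l2 * VAL(ic, c);
        }
      }
    }
  }
  return List::create(_["value"] = value, _["depth"] = depth,
                      _["covered"] = covered, _["face"] = fhit);
}
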