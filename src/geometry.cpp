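#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Clip a convex polygon (vertex arrays vx, vy; lab[k] labels the edge from
// vertex k to vertex k+1) by the half-plane a1*x + a2*y <= b. Edges created
// on the clip line receive label `newlab`.
static void clip_halfplane(std::vector<double> &vx, std::vector<double> &vy,
                           std::vector<int> &lab, double a1, double a2,
                           double b, int newlab) {
  const int m = (int)vx.size();
  if (m == 0)
    return;
  std::vector<double> s(m);
  bool any_out = false, any_in = false;
  for (int k = 0; k < m; ++k) {
    s[k] = b - (a1 * vx[k] + a2 * vy[k]);
    if (s[k] < 0)
      any_out = true;
    else
      any_in = true;
  }
  if (!any_out)
    return; // fully inside, nothing to do
  if (!any_in) {
    vx.clear();
    vy.clear();
    lab.clear();
    return;
  }
  std::vector<double> nx, ny;
  std::vector<int> nl;
  nx.reserve(m + 2);
  ny.reserve(m + 2);
  nl.reserve(m + 2);
  for (int k = 0; k < m; ++k) {
    const int k2 = (k + 1) % m;
    const bool in1 = s[k] >= 0, in2 = s[k2] >= 0;
    if (in1 && in2) {
      nx.push_back(vx[k]);
      ny.push_back(vy[k]);
      nl.push_back(lab[k]);
    } else if (in1 && !in2) {
      nx.push_back(vx[k]);
      ny.push_back(vy[k]);
      nl.push_back(lab[k]);
      const double t = s[k] / (s[k] - s[k2]);
      nx.push_back(vx[k] + t * (vx[k2] - vx[k]));
      ny.push_back(vy[k] + t * (vy[k2] - vy[k]));
      nl.push_back(newlab);
    } else if (!in1 && in2) {
      const double t = s[k] / (s[k] - s[k2]);
      nx.push_back(vx[k] + t * (vx[k2] - vx[k]));
      ny.push_back(vy[k] + t * (vy[k2] - vy[k]));
      nl.push_back(lab[k]);
    }
  }
  vx.swap(nx);
  vy.swap(ny);
  lab.swap(nl);
}

// Drop zero-length edges and merge collinear consecutive edges that carry the
// same neighbor label (clip-order artifacts).
static void tidy_polygon(std::vector<double> &vx, std::vector<double> &vy,
                         std::vector<int> &lab, double tol) {
  bool changed = true;
  while (changed && vx.size() >= 3) {
    changed = false;
    const int m = (int)vx.size();
    for (int k = 0; k < m; ++k) {
      const int kp = (k + m - 1) % m, kn = (k + 1) % m;
      const double dx1 = vx[k] - vx[kp], dy1 = vy[k] - vy[kp];
      const double dx2 = vx[kn] - vx[k], dy2 = vy[kn] - vy[k];
      const double l2 = dx2 * dx2 + dy2 * dy2;
      const double cross = dx1 * dy2 - dy1 * dx2;
      const bool dup = l2 < tol * tol;
      const bool collin =
          (lab[kp] == lab[k]) && std::fabs(cross) < tol * (1.0 + l2);
      if (dup || collin) {
        // removing vertex k merges edge k into edge k-1
        vx.erase(vx.begin() + k);
        vy.erase(vy.begin() + k);
        lab.erase(lab.begin() + k);
        changed = true;
        break;
      }
    }
  }
}

//' @title Bounded power diagram (internal)
//' @description Computes the power diagram (weighted Voronoi tessellation) of
//'   seed points inside the rectangle [0, W] x [0, H] by half-plane clipping.
//' @noRd
// [[Rcpp::export(name = ".power_diagram_cpp")]]
List power_diagram_cpp(NumericMatrix pts, NumericVector w, double W,
                       double H) {
  const int n = pts.nrow();
  if (n < 1)
    stop("need at least one seed point");
  double wmin = w[0], wmax = w[0];
  for (int i = 1; i < n; ++i) {
    wmin = std::min(wmin, w[i]);
    wmax = std::max(wmax, w[i]);
  }
  const double wrange = wmax - wmin;
  const double tol = 1e-9 * std::max(W, H);

  List out(n);
  std::vector<int> ord(n);
  std::vector<double> d2(n);

  for (int i = 0; i < n; ++i) {
    const double xi = pts(i, 0), yi = pts(i, 1), wi = w[i];
    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi;
      d2[j] = dx * dx + dy * dy;
      ord[j] = j;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d2[a] < d2[b]; });

    // start from the bounding rectangle; label 0 marks the field border
    std::vector<double> vx = {0.0, W, W, 0.0};
    std::vector<double> vy = {0.0, 0.0, H, H};
    std::vector<int> lab = {0, 0, 0, 0};

    double R = 0.0; // max distance seed -> polygon vertex
    for (size_t k = 0; k < vx.size(); ++k) {
      const double dx = vx[k] - xi, dy = vy[k] - yi;
      R = std::max(R, std::sqrt(dx * dx + dy * dy));
    }

    for (int t = 0; t < n; ++t) {
      const int j = ord[t];
      if (j == i)
        continue;
      const double dj2 = d2[j];
      const double dj = std::sqrt(dj2);
      // radical axis distance from seed i is (dj^2 + wi - wj) / (2 dj);
      // once the lower bound exceeds R no later (farther) seed can cut
      if (dj2 > wrange && (dj2 - wrange) / (2.0 * dj) > R)
        break;
      const double a1 = 2.0 * (pts(j, 0) - xi), a2 = 2.0 * (pts(j, 1) - yi);
      const double b = pts(j, 0) * pts(j, 0) + pts(j, 1) * pts(j, 1) -
                       xi * xi - yi * yi + wi - w[j];
      const double dist_line =
          (b - (a1 * xi + a2 * yi)) / std::sqrt(a1 * a1 + a2 * a2);
      if (dist_line > R)
        continue;
      clip_halfplane(vx, vy, lab, a1, a2, b, j + 1);
      if (vx.size() < 3)
        break;
      R = 0.0;
      for (size_t k = 0; k < vx.size(); ++k) {
        const double dx = vx[k] - xi, dy = vy[k] - yi;
        R = std::max(R, std::sqrt(dx * dx + dy * dy));
      }
    }

    tidy_polygon(vx, vy, lab, tol);
    if (vx.size() < 3) {
      out[i] = R_NilValue; // degenerate (empty power cell)
      continue;
    }
    const int m = (int)vx.size();
    NumericMatrix poly(m, 2);
    IntegerVector labs(m);
    for (int k = 0; k < m; ++k) {
      poly(k, 0) = vx[k];
      poly(k, 1) = vy[k];
      labs[k] = lab[k];
    }
    out[i] = List::create(_["poly"] = poly, _["nb"] = labs);
  }
  return out;
}

//' @title Scanline polygon rasterizer (internal)
//' @description Fills each polygon into an integer label matrix. Pixel (r, c)
//'   (1-based) has its center at ((c - 0.5) * px, (r - 0.5) * px) in um.
//' @noRd
// [[Rcpp::export(name = ".rasterize_labels_cpp")]]
IntegerMatrix rasterize_labels_cpp(List polys, IntegerVector ids, int nrow,
                                   int ncol, double px) {
  IntegerMatrix out(nrow, ncol);
  const int np = polys.size();
  std::vector<double> xs;
  for (int p = 0; p < np; ++p) {
    if (Rf_isNull(polys[p]))
      continue;
    NumericMatrix poly = polys[p];
    const int m = poly.nrow();
    if (m < 3)
      continue;
    double ymin = poly(0, 1), ymax = poly(0, 1);
    for (int k = 1; k < m; ++k) {
      ymin = std::min(ymin, poly(k, 1));
      ymax = std::max(ymax, poly(k, 1));
    }
    int r0 = std::max(1, (int)std::ceil(ymin / px + 0.5));
    int r1 = std::min(nrow, (int)std::floor(ymax / px + 0.5));
    for (int r = r0; r <= r1; ++r) {
      const double y = (r - 0.5) * px;
      xs.clear();
      for (int k = 0; k < m; ++k) {
        const int k2 = (k + 1) % m;
        const double y1 = poly(k, 1), y2 = poly(k2, 1);
        if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
          const double t = (y - y1) / (y2 - y1);
          xs.push_back(poly(k, 0) + t * (poly(k2, 0) - poly(k, 0)));
        }
      }
      std::sort(xs.begin(), xs.end());
      for (size_t q = 0; q + 1 < xs.size(); q += 2) {
        int c0 = std::max(1, (int)std::ceil(xs[q] / px + 0.5));
        int c1 = std::min(ncol, (int)std::ceil(xs[q + 1] / px + 0.5) - 1);
        for (int c = c0; c <= c1; ++c)
          out(r - 1, c - 1) = ids[p];
      }
    }
  }
  return out;
}
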