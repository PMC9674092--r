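#include <Rcpp.h>
using namespace Rcpp;

// Sliding log-odds scan of an integer-coded sequence (0=A,1=C,2=G,3=T,
// -1=ambiguous) against a 4 x width score matrix. Ambiguous bases
// contribute 0 (background odds).
// [[Rcpp::export]]
NumericVector pwm_scan_scores(IntegerVector codes, NumericMatrix lut) {
  const int n = codes.size();
  const int w = lut.ncol();
  if (n < w) return NumericVector(0);
  NumericVector out(n - w + 1);
  for (int i = 0; i <= n - w; ++i) {
    double s = 0.0;
    for (int j = 0; j < w; ++j) {
      const int b = codes[i + j];
      if (b >= 0) s += lut(b, j);
    }
    out[i] = s;
  }
  return out;
}

static void euler_rot(const double a[3], double R[9]) {
  const double cx = std::cos(a[0]), sx = std::sin(a[0]);
  const double cy = std::cos(a[1]), sy = std::sin(a[1]);
  const double cz = std::cos(a[2]), sz = std::sin(a[2]);
  // Rx * Ry * Rz
  R[0] = cy * cz;              R[3] = -cy * sz;             R[6] = sy;
  R[1] = cx * sz + sx * sy * cz; R[4] = cx * cz - sx * sy * sz; R[7] = -sx * cy;
  R[2] = sx * sz - cx * sy * cz; R[5] = sx * cz + cx * sy * sz; R[8] = cx * cy;
}

// Regularized oriented-bounding-box volume prod(extent + eps) at Euler
// angles a. Writes extents to ext.
static double obb_obj(const std::vector<double> &pts, int n,
                      const double a[3], double eps, double ext[3]) {
  double R[9];
  euler_rot(a, R);
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int i = 0; i < n; ++i) {
    const double *p = &pts[3 * i];
    for (int k = 0; k < 3; ++k) {
      const double v = p[0] * R[3 * k] + p[1] * R[3 * k + 1] +
                       p[2] * R[3 * k + 2];
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
  }
  double prod = 1.0;
  for (int k = 0; k < 3; ++k) {
    ext[k] = hi[k] - lo[k];
    prod *= ext[k] + eps;
  }
  return prod;
}

static inline double max3(const double e[3]) {
  return std::max(e[0], std::max(e[1], e[2]));
}

// lexicographic comparison: smaller regularized volume wins; volumes
// within relative tolerance are ties, broken toward the smaller longest
// edge (degenerate planar/collinear sets have genuinely tied volumes)
static inline bool lex_better(double v, double mx, double v0, double mx0) {
  const double tol = 1e-9 * (v0 > 0 ? v0 : 1.0);
  if (v < v0 - tol) return true;
  if (v <= v0 + tol && mx < mx0 - 1e-12) return true;
  return false;
}

// Longest edge of an approximately minimal oriented bounding box of a 3D
// point set (already centered / pre-rotated by the caller): coarse Euler
// grid followed by coordinate pattern search from the best cells.
// [[Rcpp::export]]
double obb_longest_edge_core(NumericMatrix pts, double eps) {
  const int n = pts.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pts(i, k);
  const double step0 = M_PI / 30.0;  // 6 degrees
  double ext[3];
  // coarse grid over a fundamental-domain-covering Euler range; keep the
  // best few cells and refine each by coordinate pattern search
  // the grid visits many symmetry copies of each box orientation, so the
  // kept cells are deduplicated by objective level: one representative
  // per (approximately) distinct volume, keeping the search from
  // refining eight copies of the same basin while missing the runner-up
  const int KEEP = 8;
  double top_val[KEEP], top_mx[KEEP], top_a[KEEP][3];
  int n_top = 0;
  double a[3];
  for (a[0] = 0; a[0] < 2 * M_PI; a[0] += step0)
    for (a[1] = 0; a[1] < M_PI; a[1] += step0)
      for (a[2] = 0; a[2] < M_PI; a[2] += step0) {
        const double v = obb_obj(x, n, a, eps, ext);
        const double mx = max3(ext);
        int dup = -1;
        for (int k = 0; k < n_top; ++k)
          if (std::fabs(v - top_val[k]) <=
              1e-4 * std::max(v, top_val[k])) { dup = k; break; }
        if (dup >= 0) {
          if (lex_better(v, mx, top_val[dup], top_mx[dup])) {
            top_val[dup] = v;
            top_mx[dup] = mx;
            for (int q = 0; q < 3; ++q) top_a[dup][q] = a[q];
          }
          continue;
        }
        if (n_top < KEEP) {
          top_val[n_top] = v;
          top_mx[n_top] = mx;
          for (int q = 0; q < 3; ++q) top_a[n_top][q] = a[q];
          ++n_top;
        } else {
          // replace the worst kept level if this one is better
          int worst = 0;
          for (int k = 1; k < KEEP; ++k)
            if (lex_better(top_val[worst], top_mx[worst], top_val[k],
                           top_mx[k])) worst = k;
          if (lex_better(v, mx, top_val[worst], top_mx[worst])) {
            top_val[worst] = v;
            top_mx[worst] = mx;
            for (int q = 0; q < 3; ++q) top_a[worst][q] = a[q];
          }
        }
      }
  double best = 1e300, best_mx = 1e300, best_a[3] = {0, 0, 0};
  for (int t = 0; t < n_top; ++t) {
    double cur_a[3] = {top_a[t][0], top_a[t][1], top_a[t][2]};
    double cur = top_val[t], cur_mx = top_mx[t];
    double step = step0 / 2.0;
    while (step > 1e-6) {
      bool improved = false;
      for (int k = 0; k < 3; ++k) {
        for (int s = -1; s <= 1; s += 2) {
          double cand[3] = {cur_a[0], cur_a[1], cur_a[2]};
          cand[k] += s * step;
          const double v = obb_obj(x, n, cand, eps, ext);
          const double mx = max3(ext);
          if (lex_better(v, mx, cur, cur_mx)) {
            cur = v;
            cur_mx = mx;
            for (int kk = 0; kk < 3; ++kk) cur_a[kk] = cand[kk];
            improved = true;
          }
        }
      }
      if (!improved) step /= 2.0;
    }
    if (lex_better(cur, cur_mx, best, best_mx)) {
      best = cur;
      best_mx = cur_mx;
      for (int k = 0; k < 3; ++k) best_a[k] = cur_a[k];
    }
  }
  obb_obj(x, n, best_a, eps, ext);
  return max3(ext);
}

// Minimum distance between two 3D segments p1-p2 and q1-q2 (classic
// clamped closest-point computation).
static double seg_seg_dist(const double *p1, const double *p2,
                           const double *q1, const double *q2) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = p2[k] - p1[k];
    d2[k] = q2[k] - q1[k];
    r[k] = p1[k] - q1[k];
  }
  double a = 0, e = 0, f = 0, c = 0, b = 0;
  for (int k = 0; k < 3; ++k) {
    a += d1[k] * d1[k]; e += d2[k] * d2[k];
    f += d2[k] * r[k]; c += d1[k] * r[k]; b += d1[k] * d2[k];
  }
  double s = 0, t = 0;
  const double denom = a * e - b * b;
  if (denom > 1e-300) s = std::min(1.0, std::max(0.0, (b * f - c * e) / denom));
  if (e > 1e-300) {
    t = (b * s + f) / e;
    if (t < 0) { t = 0; s = (a > 1e-300) ? std::min(1.0, std::max(0.0, -c / a)) : 0; }
    else if (t > 1) { t = 1; s = (a > 1e-300) ? std::min(1.0, std::max(0.0, (b - c) / a)) : 0; }
  }
  double d = 0;
  for (int k = 0; k < 3; ++k) {
    const double u = (p1[k] + s * d1[k]) - (q1[k] + t * d2[k]);
    d += u * u;
  }
  return std::sqrt(d);
}

// Minimum spatial distance between segment pairs of a polyline (n x 3
// coordinate matrix) whose arc-length separation (between segment
// midpoints, along the curve) is at least min_arc_sep. Contiguous curves
// trivially have nearby neighbouring segments, so only pairs far apart
// *along* the curve can witness a loop or self-approach. Returns
// R_PosInf when no eligible pair exists.
// [[Rcpp::export]]
double polyline_self_distance(NumericMatrix pts, double min_arc_sep) {
  const int n = pts.nrow();
  const int nseg = n - 1;
  if (nseg < 3) return R_PosInf;
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pts(i, k);
  // cumulative arc length at segment midpoints
  std::vector<double> mid(nseg);
  double acc = 0.0;
  for (int i = 0; i < nseg; ++i) {
    double l = 0.0;
    for (int k = 0; k < 3; ++k) {
      const double d = x[3 * (i + 1) + k] - x[3 * i + k];
      l += d * d;
    }
    l = std::sqrt(l);
    mid[i] = acc + 0.5 * l;
    acc += l;
  }
  double best = R_PosInf;
  for (int i = 0; i < nseg; ++i) {
    for (int j = i + 2; j < nseg; ++j) {
      if (mid[j] - mid[i] < min_arc_sep) continue;
      const double d = seg_seg_dist(&x[3 * i], &x[3 * (i + 1)],
                                    &x[3 * j], &x[3 * (j + 1)]);
      if (d < best) best = d;
    }
  }
  return best;
}
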