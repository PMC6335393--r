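#include <Rcpp.h>
#include <cmath>
#include <set>
using namespace Rcpp;

// Minimum distance between two 3D line segments, closed form with
// clamping (Eberly's robust scheme). A "contact point" is a pair of
// segments, one axonal and one dendritic, closer than the distance
// criterion; counting is over segment pairs (optionally aggregated to
// branch pairs).

static double seg_seg_dist2(const double *p0, const double *p1,
                            const double *q0, const double *q1) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = p1[k] - p0[k];
    d2[k] = q1[k] - q0[k];
    r[k] = p0[k] - q0[k];
  }
  double a = d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2];
  double e = d2[0] * d2[0] + d2[1] * d2[1] + d2[2] * d2[2];
  double f = d2[0] * r[0] + d2[1] * r[1] + d2[2] * r[2];
  double s = 0.0, t = 0.0;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) {
    // both degenerate: point-point
  } else if (a <= EPS) {
    t = f / e; t = std::min(1.0, std::max(0.0, t));
  } else {
    double c = d1[0] * r[0] + d1[1] * r[1] + d1[2] * r[2];
    if (e <= EPS) {
      s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      double b = d1[0] * d2[0] + d1[1] * d2[1] + d1[2] * d2[2];
      double denom = a * e - b * b;
      if (denom > EPS) {
        s = std::min(1.0, std::max(0.0, (b * f - c * e) / denom));
      }
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::min(1.0, std::max(0.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::min(1.0, std::max(0.0, (b - c) / a));
      }
    }
  }
  double dd = 0.0;
  for (int k = 0; k < 3; ++k) {
    double u = (p0[k] + s * d1[k]) - (q0[k] + t * d2[k]);
    dd += u * u;
  }
  return dd;
}

// [[Rcpp::export(name = ".seg_seg_dist_cpp")]]
double seg_seg_dist_cpp(NumericVector p0, NumericVector p1,
                        NumericVector q0, NumericVector q1) {
  return std::sqrt(seg_seg_dist2(&p0[0], &p1[0], &q0[0], &q1[0]));
}

// Count (axonal segment of A, dendritic segment of B) pairs with minimum
// distance <= max_dist. a0/a1: n_a x 3 start/end points; likewise b0/b1.
// branch_a/branch_b: branch ids per segment; if per_branch, count unique
// (branch_a, branch_b) pairs instead of segment pairs.
// [[Rcpp::export(name = ".count_contacts_cpp")]]
int count_contacts_cpp(NumericMatrix a0, NumericMatrix a1,
                       NumericMatrix b0, NumericMatrix b1,
                       double max_dist,
                       IntegerVector branch_a, IntegerVector branch_b,
                       bool per_branch) {
  const int na = a0.nrow(), nb = b0.nrow();
  const double md2 = max_dist * max_dist;
  if (na == 0 || nb == 0) return 0;
  // per-segment bounding boxes for a cheap reject
  std::vector<double> alo(3 * na), ahi(3 * na), blo(3 * nb), bhi(3 * nb);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) {
      alo[3 * i + k] = std::min(a0(i, k), a1(i, k));
      ahi[3 * i + k] = std::max(a0(i, k), a1(i, k));
    }
  for (int j = 0; j < nb; ++j)
    for (int k = 0; k < 3; ++k) {
      blo[3 * j + k] = std::min(b0(j, k), b1(j, k));
      bhi[3 * j + k] = std::max(b0(j, k), b1(j, k));
    }
  int count = 0;
  std::set<std::pair<int, int>> branch_pairs;
  std::vector<double> pa0(3), pa1(3), pb0(3), pb1(3);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      bool reject = false;
      for (int k = 0; k < 3; ++k) {
        double gap = std::max(blo[3 * j + k] - ahi[3 * i + k],
                              alo[3 * i + k] - bhi[3 * j + k]);
        if (gap > max_dist) { reject = true; break; }
      }
      if (reject) continue;
      for (int k = 0; k < 3; ++k) {
        pa0[k] = a0(i, k); pa1[k] = a1(i, k);
        pb0[k] = b0(j, k); pb1[k] = b1(j, k);
      }
      if (seg_seg_dist2(&pa0[0], &pa1[0], &pb0[0], &pb1[0]) <= md2) {
        if (per_branch) branch_pairs.insert({branch_a[i], branch_b[j]});
        else ++count;
      }
    }
  }
  return per_branch ? (int)branch_pairs.size() : count;
}
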