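// Discrete Gauss double sum for the linking number of two closed polygonal
// curves: the contribution of each segment pair is the signed solid angle of
// the quadrilateral spanned by the four endpoints (Klenin-Langowski style
// closed form), accumulated over all pairs and divided by 4*pi. For disjoint
// closed curves the sum is an integer up to rounding error.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };

inline V3 sub(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

inline V3 unit_or_zero(const V3& a) {
  double n = norm(a);
  if (n < 1e-12) return {0.0, 0.0, 0.0};
  return {a.x / n, a.y / n, a.z / n};
}

inline double casin(double v) {
  if (v > 1.0) v = 1.0;
  if (v < -1.0) v = -1.0;
  return std::asin(v);
}

// signed solid angle / (4 pi) subtended by segment (a1,a2) and (b1,b2)
double pair_term(const V3& a1, const V3& a2, const V3& b1, const V3& b2) {
  V3 r13 = sub(b1, a1), r14 = sub(b2, a1);
  V3 r23 = sub(b1, a2), r24 = sub(b2, a2);
  V3 r12 = sub(a2, a1), r34 = sub(b2, b1);
  V3 n1 = unit_or_zero(cross(r13, r14));
  V3 n2 = unit_or_zero(cross(r14, r24));
  V3 n3 = unit_or_zero(cross(r24, r23));
  V3 n4 = unit_or_zero(cross(r23, r13));
  double omega = casin(dot(n1, n2)) + casin(dot(n2, n3)) +
                 casin(dot(n3, n4)) + casin(dot(n4, n1));
  double s = dot(cross(r34, r12), r13);
  double sgn = (s > 0.0) - (s < 0.0);
  return omega * sgn / (4.0 * M_PI);
}

} // namespace

// [[Rcpp::export(name = ".rm_gauss_linking")]]
double rm_gauss_linking(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  if (na < 3 || nb < 3) stop("a closed polygonal curve needs at least 3 vertices");
  double acc = 0.0;
  for (int i = 0; i < na; ++i) {
    int i2 = (i + 1) % na;
    V3 a1{A(i, 0), A(i, 1), A(i, 2)}, a2{A(i2, 0), A(i2, 1), A(i2, 2)};
    for (int j = 0; j < nb; ++j) {
      int j2 = (j + 1) % nb;
      V3 b1{B(j, 0), B(j, 1), B(j, 2)}, b2{B(j2, 0), B(j2, 1), B(j2, 2)};
      acc += pair_term(a1, a2, b1, b2);
    }
  }
  return acc;
}
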