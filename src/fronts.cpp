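#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// First-order upwind fast-marching solver for |grad T| = 1/v with multiple
// labeled sources. Pixels keep the label of the upwind neighbor that first
// determines their arrival time; simultaneous claims resolve to the lower
// label id, so the evolution is fully deterministic.

namespace {

struct Node {
  double t;
  int idx;
  int label;
  bool operator>(const Node& o) const {
    if (t != o.t) return t > o.t;
    if (label != o.label) return label > o.label;
    return idx > o.idx;
  }
};

// Solve the quadratic upwind update from the smaller axis values a <= b
// with slowness s = 1/v.
inline double eikonal_update(double a, double b, double s) {
  if (!std::isfinite(a)) return std::numeric_limits<double>::infinity();
  if (!std::isfinite(b)) return a + s;
  if (a > b) std::swap(a, b);
  double diff = b - a;
  if (diff >= s) return a + s;
  // two-sided update
  double sum = a + b;
  double disc = sum * sum - 2.0 * (a * a + b * b - s * s);
  if (disc < 0.0) return a + s;
  return 0.5 * (sum + std::sqrt(disc));
}

} // namespace

// [[Rcpp::export(name = ".fmm_fronts_cpp")]]
List fmm_fronts_cpp(NumericMatrix speed, IntegerMatrix seeds) {
  const int nr = speed.nrow(), nc = speed.ncol(), n = nr * nc;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> T(n, INF);
  std::vector<int> lab(n, 0);
  std::vector<char> accepted(n, 0);

  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > heap;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int idx = i + j * nr;
      if (seeds[idx] > 0) {
        T[idx] = 0.0;
        lab[idx] = seeds[idx];
        heap.push(Node{0.0, idx, seeds[idx]});
      }
    }

  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  while (!heap.empty()) {
    Node cur = heap.top();
    heap.pop();
    if (accepted[cur.idx]) continue;
    accepted[cur.idx] = 1;
    lab[cur.idx] = cur.label;
    T[cur.idx] = cur.t;

    int ci = cur.idx % nr, cj = cur.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int ni = ci + di[k], nj = cj + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      int nidx = ni + nj * nr;
      if (accepted[nidx]) continue;
      double v = speed[nidx];
      if (!(v > 0.0)) continue;
      // upwind values along each axis from accepted neighbors only
      double ax = INF, ay = INF;
      if (ni > 0 && accepted[nidx - 1]) ax = std::min(ax, T[nidx - 1]);
      if (ni < nr - 1 && accepted[nidx + 1]) ax = std::min(ax, T[nidx + 1]);
      if (nj > 0 && accepted[nidx - nr]) ay = std::min(ay, T[nidx - nr]);
      if (nj < nc - 1 && accepted[nidx + nr]) ay = std::min(ay, T[nidx + nr]);
      double tnew = eikonal_update(std::min(ax, ay), std::max(ax, ay), 1.0 / v);
      if (tnew < T[nidx]) {
        T[nidx] = tnew;
        heap.push(Node{tnew, nidx, cur.label});
      } else if (tnew == T[nidx] && lab[nidx] != 0 && cur.label < lab[nidx]) {
        heap.push(Node{tnew, nidx, cur.label});
      }
      if (lab[nidx] == 0) lab[nidx] = cur.label;
    }
  }

  NumericMatrix Tout(nr, nc);
  IntegerMatrix Lout(nr, nc);
  for (int idx = 0; idx < n; ++idx) {
    Tout[idx] = T[idx];
    Lout[idx] = accepted[idx] ? lab[idx] : 0;
  }
  return List::create(_["arrival"] = Tout, _["labels"] = Lout);
}

// [[Rcpp::export(name = ".cc_label_3d_cpp")]]
IntegerVector cc_label_3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<long> stack;
  int next_label = 0;
  for (long start = 0; start < n; ++start) {
    if (!mask[start] || out[start]) continue;
    ++next_label;
    stack.push_back(start);
    out[start] = next_label;
    while (!stack.empty()) {
      long cur = stack.back();
      stack.pop_back();
      int x = cur % nx;
      int y = (cur / nx) % ny;
      int z = cur / ((long)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            long nb = X + (long)nx * (Y + (long)ny * Z);
            if (mask[nb] && !out[nb]) {
              out[nb] = next_label;
              stack.push_back(nb);
            }
          }
    }
  }
  out.attr("dim") = dims;
  return out;
}
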