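// Multiresolution region-growing segmentation.
//
// Objects start as single pixels and are merged pairwise while the increase
// in weighted heterogeneity ("merge cost") stays below scale^2.  The cost of
// merging objects a, b into m is
//
//   cost = w_color * dh_color + (1 - w_color) * dh_shape
//   dh_color = sum_b wband_b [ n_m sigma_b(m) - n_a sigma_b(a) - n_b sigma_b(b) ]
//   dh_shape = w_compact * dh_cmp + (1 - w_compact) * dh_smooth
//   h_cmp = l / sqrt(n),  h_smooth = l / (bounding box perimeter)
//   dh_x  = n_m h_x(m) - n_a h_x(a) - n_b h_x(b)
//
// with sigma the population standard deviation kept incrementally from
// per-band sums and sums of squares, and l the exposed-edge perimeter
// (merged perimeter = l_a + l_b - 2 * shared edges).  Merging follows local
// mutual best fitting: objects are visited in a seeded pseudo-random order
// each pass, and an object merges with its minimum-cost neighbour only when
// the choice is mutual and the cost is strictly below scale^2; ties are
// broken towards the smallest object id.  Passes repeat until none merges.
// Nodata pixels take segment id 0 and never participate.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <functional>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Region {
  double n = 0;
  std::vector<double> sum, ssq;
  double perim = 0;
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
  bool alive = false;
};

// xorshift64* PRNG: deterministic across platforms, unlike std::shuffle.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n) by rejection
  uint64_t bounded(uint64_t n) {
    uint64_t lim = UINT64_MAX - UINT64_MAX % n;
    uint64_t x;
    do { x = next(); } while (x >= lim);
    return x % n;
  }
};

inline double sd_pop(double n, double s, double q) {
  double v = q / n - (s / n) * (s / n);
  return v > 0 ? std::sqrt(v) : 0.0;
}

struct Merger {
  int B;
  double w_color, w_compact, s2;
  std::vector<double> wband;
  std::vector<Region> reg;
  std::vector<std::unordered_map<int, double>> adj; // neighbour -> shared edges
  std::vector<int> parent;                          // union-find for final ids

  double cost(int a, int b, double shared) const {
    const Region &A = reg[a], &B_ = reg[b];
    double nm = A.n + B_.n;
    double dcol = 0;
    for (int k = 0; k < B; ++k) {
      double sm = A.sum[k] + B_.sum[k], qm = A.ssq[k] + B_.ssq[k];
      double d = nm * sd_pop(nm, sm, qm) -
                 A.n * sd_pop(A.n, A.sum[k], A.ssq[k]) -
                 B_.n * sd_pop(B_.n, B_.sum[k], B_.ssq[k]);
      dcol += wband[k] * d;
    }
    if (dcol < 0) dcol = 0;
    double lm = A.perim + B_.perim - 2.0 * shared;
    int rmin = std::min(A.rmin, B_.rmin), rmax = std::max(A.rmax, B_.rmax);
    int cmin = std::min(A.cmin, B_.cmin), cmax = std::max(A.cmax, B_.cmax);
    double bper_m = 2.0 * ((rmax - rmin + 1) + (cmax - cmin + 1));
    double bper_a = 2.0 * ((A.rmax - A.rmin + 1) + (A.cmax - A.cmin + 1));
    double bper_b = 2.0 * ((B_.rmax - B_.rmin + 1) + (B_.cmax - B_.cmin + 1));
    double dcmp = nm * (lm / std::sqrt(nm)) -
                  A.n * (A.perim / std::sqrt(A.n)) -
                  B_.n * (B_.perim / std::sqrt(B_.n));
    double dsm = nm * (lm / bper_m) - A.n * (A.perim / bper_a) -
                 B_.n * (B_.perim / bper_b);
    double dshape = w_compact * dcmp + (1 - w_compact) * dsm;
    double c = w_color * dcol + (1 - w_color) * dshape;
    return c > 0 ? c : 0.0;
  }

  // best (min-cost) neighbour of a; ties to smallest id.  Returns -1 if none.
  int best_neighbour(int a, double &best_cost) const {
    int best = -1;
    best_cost = R_PosInf;
    for (const auto &kv : adj[a]) {
      double c = cost(a, kv.first, kv.second);
      if (c < best_cost || (c == best_cost && best >= 0 && kv.first < best)) {
        best_cost = c;
        best = kv.first;
      }
    }
    return best;
  }

  // merge b into a (a = survivor, caller guarantees a < b)
  void merge(int a, int b) {
    Region &A = reg[a], &B_ = reg[b];
    double shared = adj[a].at(b);
    A.n += B_.n;
    for (int k = 0; k < B; ++k) { A.sum[k] += B_.sum[k]; A.ssq[k] += B_.ssq[k]; }
    A.perim += B_.perim - 2.0 * shared;
    A.rmin = std::min(A.rmin, B_.rmin); A.rmax = std::max(A.rmax, B_.rmax);
    A.cmin = std::min(A.cmin, B_.cmin); A.cmax = std::max(A.cmax, B_.cmax);
    adj[a].erase(b);
    adj[b].erase(a);
    for (const auto &kv : adj[b]) {
      int c = kv.first;
      adj[a][c] += kv.second;
      adj[c].erase(b);
      adj[c][a] = adj[a][c];
    }
    adj[b].clear();
    B_.alive = false;
    B_.sum.clear(); B_.ssq.clear();
    parent[b] = a;
  }
};

} // namespace

// [[Rcpp::export(name = ".segment_cpp")]]
List segment_cpp(NumericVector pixels, LogicalVector nodata,
                 int H, int W, int B,
                 double scale, double w_color, double w_compact,
                 NumericVector band_weights, double seed) {
  const int N = H * W;
  std::vector<int> obj_of(N, -1);
  std::vector<int> px_of; px_of.reserve(N);
  for (int p = 0; p < N; ++p)
    if (!nodata[p]) { obj_of[p] = (int)px_of.size(); px_of.push_back(p); }
  const int M = (int)px_of.size();
  if (M == 0) stop("scene has no valid pixels");

  Merger mg;
  mg.B = B;
  mg.w_color = w_color;
  mg.w_compact = w_compact;
  mg.s2 = scale * scale;
  mg.wband.assign(band_weights.begin(), band_weights.end());
  mg.reg.resize(M);
  mg.adj.resize(M);
  mg.parent.resize(M);
  for (int i = 0; i < M; ++i) {
    int p = px_of[i];
    int r = p % H, c = p / H;
    Region &R_ = mg.reg[i];
    R_.n = 1; R_.perim = 4;
    R_.rmin = R_.rmax = r; R_.cmin = R_.cmax = c;
    R_.sum.resize(B); R_.ssq.resize(B);
    for (int k = 0; k < B; ++k) {
      double v = pixels[p + (R_xlen_t)k * N];
      R_.sum[k] = v; R_.ssq[k] = v * v;
    }
    R_.alive = true;
    mg.parent[i] = i;
    if (r + 1 < H && !nodata[p + 1]) {
      int j = obj_of[p + 1];
      mg.adj[i][j] = 1; mg.adj[j][i] = 1;
    }
    if (c + 1 < W && !nodata[p + H]) {
      int j = obj_of[p + H];
      mg.adj[i][j] = 1; mg.adj[j][i] = 1;
    }
  }

  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<int> order(M);
  bool merged_any = true;
  int passes = 0;
  while (merged_any) {
    merged_any = false;
    ++passes;
    int na = 0;
    for (int i = 0; i < M; ++i) if (mg.reg[i].alive) order[na++] = i;
    for (int i = na - 1; i > 0; --i)
      std::swap(order[i], order[rng.bounded((uint64_t)i + 1)]);
    for (int oi = 0; oi < na; ++oi) {
      int a = order[oi];
      if (!mg.reg[a].alive) continue;
      double ca;
      int b = mg.best_neighbour(a, ca);
      if (b < 0 || !(ca < mg.s2)) continue;
      double cb;
      int back = mg.best_neighbour(b, cb);
      if (back != a) continue;
      int s = std::min(a, b), t = std::max(a, b);
      mg.merge(s, t);
      merged_any = true;
    }
    if (passes > 10 * M + 10) stop("segmentation failed to converge");
  }

  // path-compressed resolve, then renumber by first occurrence in
  // column-major pixel order
  std::function<int(int)> find = [&](int x) {
    while (mg.parent[x] != x) { mg.parent[x] = mg.parent[mg.parent[x]]; x = mg.parent[x]; }
    return x;
  };
  std::vector<int> newid(M, 0);
  int K = 0;
  IntegerMatrix ids(H, W);
  for (int p = 0; p < N; ++p) {
    int r = p % H, c = p / H;
    if (obj_of[p] < 0) { ids(r, c) = 0; continue; }
    int root = find(obj_of[p]);
    if (newid[root] == 0) newid[root] = ++K;
    ids(r, c) = newid[root];
  }

  NumericVector n(K), perim(K);
  IntegerVector rmin(K), rmax(K), cmin(K), cmax(K);
  NumericMatrix sum(K, B), ssq(K, B);
  List adj_out(K);
  std::vector<std::vector<int>> nb(K);
  for (int i = 0; i < M; ++i) {
    if (!mg.reg[i].alive) continue;
    int id = newid[i] - 1;
    const Region &R_ = mg.reg[i];
    n[id] = R_.n; perim[id] = R_.perim;
    rmin[id] = R_.rmin + 1; rmax[id] = R_.rmax + 1;
    cmin[id] = R_.cmin + 1; cmax[id] = R_.cmax + 1;
    for (int k = 0; k < B; ++k) { sum(id, k) = R_.sum[k]; ssq(id, k) = R_.ssq[k]; }
    for (const auto &kv : mg.adj[i]) nb[id].push_back(newid[find(kv.first)]);
  }
  for (int id = 0; id < K; ++id) {
    std::sort(nb[id].begin(), nb[id].end());
    adj_out[id] = IntegerVector(nb[id].begin(), nb[id].end());
  }

  return List::create(_["ids"] = ids, _["n"] = n, _["perimeter"] = perim,
                      _["rmin"] = rmin, _["rmax"] = rmax,
                      _["cmin"] = cmin, _["cmax"] = cmax,
                      _["sum"] = sum, _["ssq"] = ssq,
                      _["adjacency"] = adj_out, _["passes"] = passes);
}
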