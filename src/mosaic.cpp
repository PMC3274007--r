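// Stand mosaic growth: multi-source shortest-path (Dijkstra) region growing
// on a random pixel-cost field.  Every pixel is captured by the seed with the
// cheapest accumulated entry cost, which yields irregular, 4-connected,
// Voronoi-like stands whose shapes are controlled by the cost field supplied
// from R (heavier-tailed costs give more irregular boundaries).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".grow_mosaic_cpp")]]
IntegerMatrix grow_mosaic_cpp(int H, int W, IntegerVector seed_pixels,
                              NumericVector cost) {
  const int N = H * W;
  std::vector<double> dist(N, R_PosInf);
  std::vector<int> stand(N, 0);
  // (distance, pixel): ties broken on pixel index for determinism
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  for (int s = 0; s < seed_pixels.size(); ++s) {
    int p = seed_pixels[s];
    if (p < 0 || p >= N) stop("seed pixel out of range");
    if (dist[p] == 0) continue;
    dist[p] = 0;
    stand[p] = s + 1;
    pq.push(Node(0.0, p));
  }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int p = nd.second;
    if (nd.first > dist[p]) continue;
    int r = p % H, c = p / H;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      int q = rr + cc * H;
      double d = nd.first + cost[q];
      if (d < dist[q]) {
        dist[q] = d;
        stand[q] = stand[p];
        pq.push(Node(d, q));
      }
    }
  }
  IntegerMatrix out(H, W);
  for (int p = 0; p < N; ++p) out[p] = stand[p];
  return out;
}
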