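#include <Rcpp.h>
#include <queue>
#include <cmath>

using namespace Rcpp;

static inline double wrap_pi(double d) {
  // principal value in (-pi, pi], matching the R-level wrap_phase()
  return d - 2.0 * M_PI * std::ceil((d - M_PI) / (2.0 * M_PI));
}

// Breadth-first flood-fill integration of wrapped phase. Cut pixels are
// barriers during the first pass; a second multi-source pass extends into
// cut/unreached pixels (still congruent mod 2*pi) and flags them.
// [[Rcpp::export]]
List cpp_integrate(NumericMatrix psi, IntegerMatrix cut,
                   int seed_r, int seed_c) {
  const int nr = psi.nrow(), nc = psi.ncol(), n = nr * nc;
  NumericMatrix out(nr, nc);
  IntegerMatrix low(nr, nc);
  std::vector<char> vis(n, 0);
  std::queue<int> q;

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  int s = seed_c * nr + seed_r;
  out[s] = psi[s];
  vis[s] = 1;
  q.push(s);
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int r = cur % nr, c = cur / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int nb = c2 * nr + r2;
      if (vis[nb] || cut[nb]) continue;
      out[nb] = out[cur] + wrap_pi(psi[nb] - psi[cur]);
      vis[nb] = 1;
      q.push(nb);
    }
  }
  // second pass: nearest-neighbour extension into everything not yet filled
  for (int i = 0; i < n; ++i) {
    if (!vis[i]) continue;
    int r = i % nr, c = i / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!vis[c2 * nr + r2]) { q.push(i); break; }
    }
  }
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int r = cur % nr, c = cur / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int nb = c2 * nr + r2;
      if (vis[nb]) continue;
      out[nb] = out[cur] + wrap_pi(psi[nb] - psi[cur]);
      vis[nb] = 1;
      low[nb] = 1;
      q.push(nb);
    }
  }
  return List::create(_["values"] = out, _["low_confidence"] = low);
}

// 8-connected component labelling of a binary mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::queue<int> q;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int r = cur % nr, c = cur / nr;
      for (int dr2 = -1; dr2 <= 1; ++dr2) {
        for (int dc2 = -1; dc2 <= 1; ++dc2) {
          if (!dr2 && !dc2) continue;
          int r2 = r + dr2, c2 = c + dc2;
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int nb = c2 * nr + r2;
          if (mask[nb] && !lab[nb]) { lab[nb] = next; q.push(nb); }
        }
      }
    }
  }
  return lab;
}
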