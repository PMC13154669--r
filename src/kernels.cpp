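#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Meyer-style flooding from labelled markers over an arbitrary scalar
// surface, restricted to a mask. Pixels are claimed in order of increasing
// surface height (FIFO within equal heights, so output is deterministic);
// every mask pixel reachable from a marker ends up labelled, i.e. no
// watershed-line pixels are dropped. 8-connectivity.
struct QItem {
  double h;
  long long order;
  int idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.h != b.h) return a.h > b.h;
    return a.order > b.order;
  }
};

// [[Rcpp::export(name = ".flood_from_markers")]]
IntegerMatrix flood_from_markers(NumericMatrix surface, IntegerMatrix markers,
                                 LogicalMatrix mask) {
  const int nr = surface.nrow(), nc = surface.ncol();
  IntegerMatrix out(nr, nc);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long counter = 0;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int idx = j * nr + i;
      if (mask[idx] && markers[idx] > 0) {
        out[idx] = markers[idx];
        pq.push(QItem{surface[idx], counter++, idx});
      }
    }

  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  while (!pq.empty()) {
    QItem cur = pq.top();
    pq.pop();
    int i = cur.idx % nr, j = cur.idx / nr;
    int lab = out[cur.idx];
    for (int k = 0; k < 8; ++k) {
      int ni = i + dr[k], nj = j + dc[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      int nidx = nj * nr + ni;
      if (!mask[nidx] || out[nidx] != 0) continue;
      out[nidx] = lab;
      pq.push(QItem{surface[nidx], counter++, nidx});
    }
  }
  return out;
}

// Median filter over a disk-shaped neighbourhood of the given radius
// (offsets with dr^2 + dc^2 <= r^2); borders handled by clamping.
// [[Rcpp::export(name = ".disk_median")]]
NumericMatrix disk_median(NumericMatrix x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  if (radius < 1) return clone(x);

  std::vector<int> offr, offc;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius) {
        offr.push_back(dr);
        offc.push_back(dc);
      }
  const int m = (int)offr.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(m);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int k = 0; k < m; ++k) {
        int ii = std::min(std::max(i + offr[k], 0), nr - 1);
        int jj = std::min(std::max(j + offc[k], 0), nc - 1);
        buf[k] = x(ii, jj);
      }
      int mid = m / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (m % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}
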