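#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Separable convolution with reflected (mirror) boundaries.
// Used for Gaussian smoothing; `kernel` must be odd-length and normalized.
// [[Rcpp::export]]
NumericMatrix cpp_sep_convolve(NumericMatrix img, NumericVector kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int k = kernel.size(), h = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -h; t <= h; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii;                 // reflect
        if (ii >= nr) ii = 2 * nr - 2 - ii;
        if (ii < 0) ii = 0;                   // degenerate 1-row case
        acc += img(ii, j) * kernel[t + h];
      }
      tmp(i, j) = acc;
    }
  }
  // along columns (horizontal)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -h; t <= h; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj;
        if (jj >= nc) jj = 2 * nc - 2 - jj;
        if (jj < 0) jj = 0;
        acc += tmp(i, jj) * kernel[t + h];
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Grayscale erosion/dilation with an arbitrary structuring element given as
// an n x 2 matrix of (row, col) offsets. Out-of-image samples are ignored
// (border values are computed over the in-bounds part of the SE).
// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(NumericMatrix img, IntegerMatrix offsets, bool dilate) {
  int nr = img.nrow(), nc = img.ncol(), m = offsets.nrow();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = dilate ? R_NegInf : R_PosInf;
      for (int t = 0; t < m; ++t) {
        int ii = i + offsets(t, 0), jj = j + offsets(t, 1);
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = img(ii, jj);
        if (dilate) { if (v > best) best = v; } else { if (v < best) best = v; }
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Connected-component labeling of a binary mask (BFS), connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int ndir = (connectivity == 8) ? 8 : 4;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int d = 0; d < ndir; ++d) {
          int ii = p.first + dr[d], jj = p.second + dc[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

struct UF {
  std::vector<int> parent;
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

// Peak detection with topographic prominence (persistence sweep).
//
// Pixels are processed in decreasing intensity (ties by linear index). Each
// new component is born at a (plateau) maximum; when two components merge at
// level v the one with the lower birth value dies and is assigned
// prominence = birth - v. Among equal-birth components the one whose peak
// pixel has the smaller linear index survives. Survivors get
// prominence = birth - min(img). Returns one row per peak: 1-based (row, col)
// of the first-processed peak pixel, its value, and its prominence.
// [[Rcpp::export]]
DataFrame cpp_peaks(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const double *v = img.begin();
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });
  double vmin = *std::min_element(v, v + n);

  UF uf; uf.parent.assign(n, -1);
  std::vector<int> comp_peak(n, -1);       // root -> peak pixel
  std::vector<double> comp_birth(n, 0.0);  // root -> birth value
  std::vector<char> processed(n, 0);
  std::vector<int> peak_px; std::vector<double> peak_val, peak_prom;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  for (int idx = 0; idx < n; ++idx) {
    int p = order[idx];
    double vp = v[p];
    int pi = p % nr, pj = p / nr;  // column-major
    uf.parent[p] = p; comp_peak[p] = p; comp_birth[p] = vp;
    processed[p] = 1;
    for (int d = 0; d < 8; ++d) {
      int ii = pi + dr[d], jj = pj + dc[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int q = ii + jj * nr;
      if (!processed[q]) continue;
      int rp = uf.find(p), rq = uf.find(q);
      if (rp == rq) continue;
      // decide survivor: higher birth wins; tie -> smaller peak pixel index
      int keep = rq, die = rp;
      if (comp_birth[rp] > comp_birth[rq] ||
          (comp_birth[rp] == comp_birth[rq] && comp_peak[rp] < comp_peak[rq])) {
        keep = rp; die = rq;
      }
      double prom = comp_birth[die] - vp;
      peak_px.push_back(comp_peak[die]);
      peak_val.push_back(comp_birth[die]);
      peak_prom.push_back(prom);
      uf.parent[die] = keep;
    }
  }
  // surviving components (normally one): prominence = birth - global min
  std::vector<char> seen(n, 0);
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    if (!seen[r]) {
      seen[r] = 1;
      peak_px.push_back(comp_peak[r]);
      peak_val.push_back(comp_birth[r]);
      peak_prom.push_back(comp_birth[r] - vmin);
    }
  }
  int m = peak_px.size();
  IntegerVector row(m), col(m); NumericVector val(m), prom(m);
  for (int i = 0; i < m; ++i) {
    row[i] = peak_px[i] % nr + 1;
    col[i] = peak_px[i] / nr + 1;
    val[i] = peak_val[i];
    prom[i] = peak_prom[i];
  }
  return DataFrame::create(_["row"] = row, _["col"] = col,
                           _["value"] = val, _["prominence"] = prom);
}

// Overlap (shared pixel) counts between two label images of equal shape.
// Returns a data frame of (prev label, curr label, n shared pixels) for all
// co-occurring label pairs (both > 0).
// [[Rcpp::export]]
DataFrame cpp_overlap_table(IntegerMatrix a, IntegerMatrix b) {
  std::map<std::pair<int, int>, int> counts;
  int n = a.size();
  for (int i = 0; i < n; ++i) {
    int la = a[i], lb = b[i];
    if (la > 0 && lb > 0) counts[std::make_pair(la, lb)]++;
  }
  int m = counts.size();
  IntegerVector pa(m), pb(m), cnt(m);
  int i = 0;
  for (std::map<std::pair<int, int>, int>::iterator it = counts.begin();
       it != counts.end(); ++it, ++i) {
    pa[i] = it->first.first; pb[i] = it->first.second; cnt[i] = it->second;
  }
  return DataFrame::create(_["prev"] = pa, _["curr"] = pb, _["overlap"] = cnt);
}
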