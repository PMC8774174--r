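#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 3D neighbor offsets for 6- or 26-connectivity
static std::vector<std::array<int,3>> neighborOffsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  if (connectivity == 6) {
    off = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) off.push_back({{dx, dy, dz}});
  }
  return off;
}

// Iterative candidate-lesion extraction from a voxel likelihood map:
// repeatedly take the global maximum voxel (lowest linear index wins
// ties), flood the 3D-connected region with value >= relThreshold * peak,
// record it, zero it out, until the peak drops below minPeak or
// maxCandidates regions have been extracted. Indices returned 1-based.
// [[Rcpp::export]]
List cpp_extract_candidates(NumericVector map, IntegerVector dims,
                            double relThreshold, int maxCandidates,
                            double minPeak, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> w(map.begin(), map.end());
  auto off = neighborOffsets(connectivity);
  List out;
  std::vector<R_xlen_t> stack, members;
  std::vector<char> inRegion(n, 0);

  for (int c = 0; c < maxCandidates; ++c) {
    R_xlen_t best = -1;
    double peak = -1.0;
    for (R_xlen_t i = 0; i < n; ++i)
      if (w[i] > peak) { peak = w[i]; best = i; }
    if (best < 0 || peak < minPeak) break;
    const double thr = relThreshold * peak;

    stack.clear(); members.clear();
    stack.push_back(best);
    inRegion[best] = 1;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      members.push_back(v);
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      for (auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (!inRegion[u] && w[u] >= thr) {
          inRegion[u] = 1;
          stack.push_back(u);
        }
      }
    }
    IntegerVector idx(members.size());
    for (size_t k = 0; k < members.size(); ++k) {
      idx[k] = (int)(members[k] + 1);
      w[members[k]] = 0.0;      // candidate removed from the prediction
      inRegion[members[k]] = 0;
    }
    std::sort(idx.begin(), idx.end());
    out.push_back(List::create(_["indices"] = idx, _["peak"] = peak));
  }
  return out;
}

// Connected-component labelling of a binary 3D mask; labels 1..K in
// order of first (lowest linear index) occurrence, 0 background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  auto off = neighborOffsets(connectivity);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    stack.clear(); stack.push_back(i); lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      for (auto &o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[u] != 0 && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  lab.attr("nComponents") = next;
  return lab;
}

// Mann-Whitney / trapezoid AUC with midrank tie handling
static double aucScore(const std::vector<double> &s,
                       const std::vector<int> &ord,
                       const LogicalVector &isPos, int nPos, int nNeg) {
  const int n = (int)s.size();
  double rankSumPos = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && s[ord[j + 1]] == s[ord[i]]) ++j;
    double midrank = (i + j) / 2.0 + 1.0;  // average of ranks i+1..j+1
    for (int k = i; k <= j; ++k)
      if (isPos[ord[k]]) rankSumPos += midrank;
    i = j + 1;
  }
  return (rankSumPos - nPos * (nPos + 1.0) / 2.0) / ((double)nPos * nNeg);
}

// Paired sign-flip permutation null for the difference in patient-level
// AUC between two models scored on the same patients. Each iteration
// swaps the A/B assignment per patient with probability 1/2 and returns
// the permuted AUC difference. Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_perm_auc(NumericVector a, NumericVector b,
                           LogicalVector isPos, int iters) {
  const int n = a.size();
  int nPos = 0;
  for (int i = 0; i < n; ++i) if (isPos[i]) ++nPos;
  const int nNeg = n - nPos;
  NumericVector out(iters);
  std::vector<double> sA(n), sB(n);
  std::vector<int> ordA(n), ordB(n);
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) {
      bool swap = unif_rand() < 0.5;
      sA[i] = swap ? b[i] : a[i];
      sB[i] = swap ? a[i] : b[i];
    }
    for (int i = 0; i < n; ++i) ordA[i] = ordB[i] = i;
    std::sort(ordA.begin(), ordA.end(),
              [&](int l, int r) { return sA[l] < sA[r]; });
    std::sort(ordB.begin(), ordB.end(),
              [&](int l, int r) { return sB[l] < sB[r]; });
    out[it] = aucScore(sA, ordA, isPos, nPos, nNeg) -
              aucScore(sB, ordB, isPos, nPos, nNeg);
  }
  return out;
}

// partial area under the piecewise-linear curve through (x, y) knots
// (x non-decreasing), constant-extended beyond the last knot, over
// [lo, hi] on the x axis
static double pauc_polyline(const std::vector<double> &x,
                            const std::vector<double> &y,
                            double lo, double hi) {
  const int n = (int)x.size();
  if (n == 0) return 0.0;
  auto interp = [&](double t) {
    if (t <= x[0]) return y[0];
    if (t >= x[n - 1]) return y[n - 1];
    int j = (int)(std::upper_bound(x.begin(), x.end(), t) - x.begin());
    // x[j-1] <= t < x[j]
    if (x[j] == x[j - 1]) return y[j];
    double f = (t - x[j - 1]) / (x[j] - x[j - 1]);
    return y[j - 1] + f * (y[j] - y[j - 1]);
  };
  double area = 0.0, prevX = lo, prevY = interp(lo);
  for (int i = 0; i < n; ++i) {
    if (x[i] <= lo) continue;
    if (x[i] >= hi) break;
    area += (x[i] - prevX) * (prevY + y[i]) / 2.0;
    prevX = x[i]; prevY = y[i];
  }
  area += (hi - prevX) * (prevY + interp(hi)) / 2.0;
  return area;
}

// Paired sign-flip permutation null for the difference in pAUC-FROC.
// Candidates of both models are pooled and pre-sorted by confidence
// (descending); each iteration swaps the per-patient model assignment
// and rebuilds both FROC curves in one sweep. 'src' is 0 for model A
// candidates, 1 for model B; 'patient' is 0-based; isTP marks candidates
// matched to a ground-truth lesion. totalLesions and nPatients are
// identical for both models (same cohort, same ground truth).
// [[Rcpp::export]]
NumericVector cpp_perm_pauc(IntegerVector patient, NumericVector conf,
                            LogicalVector isTP, IntegerVector src,
                            int nPatients, int totalLesions,
                            double fpLo, double fpHi, int iters) {
  const int m = conf.size();
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int l, int r) { return conf[l] > conf[r]; });
  std::vector<char> swap(nPatients);
  NumericVector out(iters);
  std::vector<double> xA, yA, xB, yB;
  xA.reserve(m + 1); yA.reserve(m + 1);
  xB.reserve(m + 1); yB.reserve(m + 1);
  for (int it = 0; it < iters; ++it) {
    for (int p = 0; p < nPatients; ++p) swap[p] = unif_rand() < 0.5;
    int tpA = 0, fpA = 0, tpB = 0, fpB = 0;
    xA.assign(1, 0.0); yA.assign(1, 0.0);
    xB.assign(1, 0.0); yB.assign(1, 0.0);
    int i = 0;
    while (i < m) {
      int j = i;  // process a run of tied confidences as one threshold
      while (j < m && conf[ord[j]] == conf[ord[i]]) {
        int c = ord[j];
        int eff = src[c] ^ (int)swap[patient[c]];
        if (eff == 0) { if (isTP[c]) ++tpA; else ++fpA; }
        else          { if (isTP[c]) ++tpB; else ++fpB; }
        ++j;
      }
      xA.push_back((double)fpA / nPatients);
      yA.push_back((double)tpA / totalLesions);
      xB.push_back((double)fpB / nPatients);
      yB.push_back((double)tpB / totalLesions);
      i = j;
    }
    out[it] = pauc_polyline(xA, yA, fpLo, fpHi) -
              pauc_polyline(xB, yB, fpLo, fpHi);
  }
  return out;
}
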