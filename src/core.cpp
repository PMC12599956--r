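#include <Rcpp.h>
#include <queue>
#include <map>
using namespace Rcpp;

// Multi-source BFS label fill. lab: 0 = free, >0 = claimed, -1 = blocked.
// Free pixels are assigned to the (4-connected, chamfer-)nearest claimed
// label whose corresponding entry in `expandable` is true. Blocked pixels
// and non-expandable claims are left untouched. Free pixels unreachable
// from any expandable claim stay 0.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_nearest(IntegerMatrix lab, LogicalMatrix expandable) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix out = clone(lab);
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (out(i, j) > 0 && expandable(i, j)) q.push(j * nr + i);
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int i = idx % nr, j = idx / nr;
    int v = out(i, j);
    for (int k = 0; k < 4; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (out(ii, jj) == 0) {
        out(ii, jj) = v;
        q.push(jj * nr + ii);
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (out(i, j) < 0) out(i, j) = lab(i, j);
  return out;
}

// Count pixel-pair contacts between distinct positive labels.
// connectivity 4: right/down offsets; connectivity 8: adds both diagonals.
// Returns a data.frame (a, b, count) with a < b.
// [[Rcpp::export]]
DataFrame cpp_contacts(IntegerMatrix lab, int connectivity) {
  int nr = lab.nrow(), nc = lab.ncol();
  std::map<std::pair<int,int>, int> acc;
  int noff = (connectivity == 8) ? 4 : 2;
  const int di[4] = {0, 1, 1, 1};
  const int dj[4] = {1, 0, 1, -1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int a = lab(i, j);
      if (a <= 0) continue;
      for (int k = 0; k < noff; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int b = lab(ii, jj);
        if (b <= 0 || b == a) continue;
        std::pair<int,int> key = (a < b) ? std::make_pair(a, b) : std::make_pair(b, a);
        acc[key] += 1;
      }
    }
  }
  int n = acc.size();
  IntegerVector av(n), bv(n), cv(n);
  int r = 0;
  for (std::map<std::pair<int,int>, int>::iterator it = acc.begin(); it != acc.end(); ++it, ++r) {
    av[r] = it->first.first; bv[r] = it->first.second; cv[r] = it->second;
  }
  return DataFrame::create(_["a"] = av, _["b"] = bv, _["count"] = cv);
}

// Geodesic (within-mask) nearest-seed partition used by oversegmentation:
// identical to cpp_fill_nearest but expansion is confined to pixels whose
// `region` value matches the seed's region, so fragments never leak across
// cell walls.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_within(IntegerMatrix lab, IntegerMatrix region) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix out = clone(lab);
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (out(i, j) > 0) q.push(j * nr + i);
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int i = idx % nr, j = idx / nr;
    int v = out(i, j);
    int reg = region(i, j);
    for (int k = 0; k < 4; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (out(ii, jj) == 0 && region(ii, jj) == reg) {
        out(ii, jj) = v;
        q.push(jj * nr + ii);
      }
    }
  }
  return out;
}

// One or more 3x3 majority-label smoothing passes over unlocked pixels,
// the error-correction step applied to competition-filled images: removes
// thread-like spurious contacts left by rasterization overlap. A label's
// last pixel is never removed, so cell ids are conserved.
// [[Rcpp::export]]
IntegerMatrix cpp_majority_smooth(IntegerMatrix lab, LogicalMatrix locked, int iters) {
  int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix out = clone(lab);
  int maxlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (out(i, j) > maxlab) maxlab = out(i, j);
  std::vector<int> npix(maxlab + 1, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (out(i, j) > 0) npix[out(i, j)]++;
  for (int it = 0; it < iters; ++it) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (locked(i, j)) continue;
        int cur = out(i, j);
        if (cur <= 0) continue;
        if (npix[cur] <= 1) continue;
        // count labels in the 3x3 neighborhood
        int labs[9]; int cnts[9]; int nlab = 0;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            int v = out(ii, jj);
            if (v <= 0) continue;
            if (locked(ii, jj) && v != cur) continue;  // fixed cells never grow
            bool found = false;
            for (int k = 0; k < nlab; ++k)
              if (labs[k] == v) { cnts[k]++; found = true; break; }
            if (!found) { labs[nlab] = v; cnts[nlab] = 1; nlab++; }
          }
        }
        int best = cur, bestc = 0, curc = 0;
        for (int k = 0; k < nlab; ++k) {
          if (labs[k] == cur) curc = cnts[k];
          if (cnts[k] > bestc) { bestc = cnts[k]; best = labs[k]; }
        }
        if (best != cur && bestc > curc) {
          out(i, j) = best;
          npix[cur]--; npix[best]++;
        }
      }
    }
  }
  return out;
}

// Placement stage of the randomization engine. Cells are processed in the
// given order; for each cell the rotated pixel cloud is anchored at each
// candidate anchor in turn and the first anchor losing at most
// overlap_cap of the cell's pixels to prior claims (or the best anchor
// tried) is accepted; claimed pixels are first-come. claim: 0 free,
// -1 blocked/fixed. Guarantees every cell at least one pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_place_cells(IntegerMatrix claim, List relcoords,
                              IntegerVector ids, NumericVector angles,
                              List anchors, double overlap_cap) {
  int nr = claim.nrow(), nc = claim.ncol();
  IntegerMatrix out = clone(claim);
  int ncell = relcoords.size();
  for (int ci = 0; ci < ncell; ++ci) {
    NumericMatrix rel = relcoords[ci];
    NumericMatrix anc = anchors[ci];
    int np = rel.nrow();
    double th = angles[ci];
    std::vector<double> rdr(np), rdc(np);
    double ct = cos(th), st = sin(th);
    for (int p = 0; p < np; ++p) {
      rdr[p] = rel(p, 0) * ct - rel(p, 1) * st;
      rdc[p] = rel(p, 0) * st + rel(p, 1) * ct;
    }
    int best_n = -1;
    std::vector<int> best_idx;
    for (int t = 0; t < anc.nrow(); ++t) {
      std::vector<int> idx;
      idx.reserve(np);
      for (int p = 0; p < np; ++p) {
        int rr = (int) std::lround(rdr[p] + anc(t, 0)) - 1;
        int cc = (int) std::lround(rdc[p] + anc(t, 1)) - 1;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (out(rr, cc) == 0) idx.push_back(cc * nr + rr);
      }
      if ((int) idx.size() > best_n) {
        best_n = idx.size();
        best_idx = idx;
      }
      if (1.0 - (double) idx.size() / np <= overlap_cap) break;
    }
    if (best_n <= 0) {
      // fallback: nearest free unclaimed pixel to the first anchor
      double bd = 1e18; int bi = -1;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i)
          if (out(i, j) == 0) {
            double d = (i + 1 - anc(0, 0)) * (i + 1 - anc(0, 0)) +
                       (j + 1 - anc(0, 1)) * (j + 1 - anc(0, 1));
            if (d < bd) { bd = d; bi = j * nr + i; }
          }
      if (bi < 0) stop("placement failure for cell %d", ids[ci]);
      best_idx.assign(1, bi);
    }
    for (size_t p = 0; p < best_idx.size(); ++p)
      out[best_idx[p]] = ids[ci];
  }
  return out;
}
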