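#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 8-connected neighbourhood offsets
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Prominence-based local-maximum detection (Fiji "Find Maxima" semantics).
// A candidate maximum at value v is accepted iff the flood region of
// 8-connected pixels with intensity > v - tol neither reaches a pixel above v
// nor a region claimed by a previously accepted (higher) maximum. One
// representative point per plateau: centroid of the equal-valued plateau,
// rounded to the nearest pixel (exact halves toward the smaller index).
// Returns an n x 2 matrix of 1-based (row, col) coordinates.
// [[Rcpp::export]]
IntegerMatrix cpp_find_maxima(NumericMatrix img, double tol) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  double vmin = R_PosInf, vmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (img[i] < vmin) vmin = img[i];
    if (img[i] > vmax) vmax = img[i];
  }
  if (!(vmax > vmin)) return IntegerMatrix(0, 2); // constant image: no maxima

  // candidate local maxima: >= all 8 neighbours
  std::vector<int> cand;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double v = img[r + c * nr];
      bool ismax = true;
      for (int k = 0; k < 8 && ismax; ++k) {
        const int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (img[rr + cc * nr] > v) ismax = false;
      }
      if (ismax) cand.push_back(r + c * nr);
    }
  }
  std::sort(cand.begin(), cand.end(), [&](int a, int b) {
    if (img[a] != img[b]) return img[a] > img[b];
    return a < b;
  });

  std::vector<int> status(n, 0); // 0 = untouched, else generation id of flood
  std::vector<int> region;
  std::vector<int> stack;
  std::vector<double> out_r, out_c;
  int gen = 0;

  for (size_t ci = 0; ci < cand.size(); ++ci) {
    const int c0 = cand[ci];
    if (status[c0] != 0) continue; // absorbed by a higher maximum's flood
    const double v = img[c0];
    ++gen;
    bool rejected = false;
    region.clear();
    stack.clear();
    status[c0] = gen;
    stack.push_back(c0);
    while (!stack.empty()) {
      const int p = stack.back();
      stack.pop_back();
      region.push_back(p);
      const int pr = p % nr, pc = p / nr;
      for (int k = 0; k < 8; ++k) {
        const int rr = pr + DR[k], cc = pc + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int q = rr + cc * nr;
        if (img[q] > v) { rejected = true; continue; } // path ascends
        if (img[q] > v - tol) {
          if (status[q] == 0) {
            status[q] = gen;
            stack.push_back(q);
          } else if (status[q] != gen) {
            rejected = true; // touches a higher maximum's region
          }
        }
      }
    }
    if (rejected) continue;
    // plateau = equal-valued pixels of this region connected to the candidate
    std::vector<char> inplat(region.size(), 0);
    // plateau flood restricted to status==gen && img==v
    std::vector<int> pstack;
    // mark plateau membership with status = -gen
    status[c0] = -gen;
    pstack.push_back(c0);
    double sr = 0, sc = 0;
    int np = 0;
    while (!pstack.empty()) {
      const int p = pstack.back();
      pstack.pop_back();
      sr += p % nr;
      sc += p / nr;
      ++np;
      const int pr = p % nr, pc = p / nr;
      for (int k = 0; k < 8; ++k) {
        const int rr = pr + DR[k], cc = pc + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int q = rr + cc * nr;
        if (status[q] == gen && img[q] == v) {
          status[q] = -gen;
          pstack.push_back(q);
        }
      }
    }
    // restore flood marks so lower candidates inside stay claimed
    for (size_t i = 0; i < region.size(); ++i)
      if (status[region[i]] == -gen) status[region[i]] = gen;
    // centroid rounded; exact .5 goes to the smaller index
    const double mr = sr / np, mc = sc / np;
    out_r.push_back(std::ceil(mr - 0.5));
    out_c.push_back(std::ceil(mc - 0.5));
  }

  IntegerMatrix res(out_r.size(), 2);
  for (size_t i = 0; i < out_r.size(); ++i) {
    res(i, 0) = (int)out_r[i] + 1; // 1-based for R
    res(i, 1) = (int)out_c[i] + 1;
  }
  return res;
}

struct WsEntry {
  double v;
  long long ord;
  int idx;
  int lab;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.v != b.v) return a.v < b.v; // max-heap on intensity
    return a.ord > b.ord;             // FIFO among equal intensities
  }
};

// Marker-seeded watershed by descending-intensity priority flood, restricted
// to a binary mask. seeds: k x 2 matrix of 1-based (row, col); label i+... is
// the seed's row number. Seeds outside the mask get no region (label absent).
// [[Rcpp::export]]
IntegerMatrix cpp_seeded_watershed(NumericMatrix img, LogicalMatrix mask,
                                   IntegerMatrix seeds) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix labels(nr, nc);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long long ord = 0;
  for (int i = 0; i < seeds.nrow(); ++i) {
    const int r = seeds(i, 0) - 1, c = seeds(i, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
    if (!mask(r, c)) continue;
    if (labels(r, c) != 0) continue; // duplicate seed pixel
    labels(r, c) = i + 1;
    pq.push({img(r, c), ord++, r + c * nr, i + 1});
  }
  while (!pq.empty()) {
    const WsEntry e = pq.top();
    pq.pop();
    const int pr = e.idx % nr, pc = e.idx / nr;
    for (int k = 0; k < 8; ++k) {
      const int rr = pr + DR[k], cc = pc + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) || labels(rr, cc) != 0) continue;
      labels(rr, cc) = e.lab;
      pq.push({img(rr, cc), ord++, rr + cc * nr, e.lab});
    }
  }
  return labels;
}
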