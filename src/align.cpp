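#include "ps_core.h"
#include <climits>
using namespace Rcpp;

int gapless_mm(const std::string& a, const std::string& b, int diag, int& ov, int mm_cap) {
  int la = (int)a.size(), lb = (int)b.size();
  int s = std::max(0, diag), e = std::min(la, diag + lb);
  ov = e - s;
  if (ov <= 0) { ov = 0; return mm_cap + 1; }
  int mm = 0;
  for (int i = s; i < e; ++i) {
    char x = a[i], y = b[i - diag];
    int cx = base_code(x), cy = base_code(y);
    if (cx < 0 || cy < 0 || cx != cy) {  // N never matches, even N vs N
      if (++mm > mm_cap) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List cpp_gapless_extend(std::string a, std::string b, int diagonal,
                        int min_overlap, double max_mismatch_rate) {
  int ov = 0;
  int la = (int)a.size(), lb = (int)b.size();
  int s = std::max(0, diagonal), e = std::min(la, diagonal + lb);
  ov = e - s;
  if (ov < min_overlap)
    return List::create(_["ok"] = false, _["overlap_len"] = std::max(ov, 0),
                        _["mismatches"] = NA_INTEGER);
  int cap = (int)std::floor(max_mismatch_rate * ov);
  int mm = gapless_mm(a, b, diagonal, ov, cap);
  bool ok = mm <= cap;
  return List::create(_["ok"] = ok, _["overlap_len"] = ov,
                      _["mismatches"] = ok ? mm : NA_INTEGER);
}

// Affine-gap Smith-Waterman with full traceback. A gap of length k scores
// gap_open + k * gap_extend. Best cell ties resolve to the smaller end in
// `a`, then in `b`; traceback prefers diagonal, then gap-in-b (D), then
// gap-in-a (I).
SWResult sw_align_core(const std::string& a, const std::string& b,
                       int match, int mismatch, int gap_open, int gap_extend) {
  const int NEG = INT_MIN / 4;
  int n = (int)a.size(), m = (int)b.size();
  SWResult res;
  if (n == 0 || m == 0) return res;
  // H, E (gap in a: consumes b), F (gap in b: consumes a); buffers are
  // reused across calls, so only the boundary row/column needs resetting —
  // every interior cell is written before it is read
  thread_local std::vector<int> H, E, F;
  size_t need = (size_t)(n + 1) * (m + 1);
  if (H.size() < need) { H.resize(need); E.resize(need); F.resize(need); }
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) { H[at(0, j)] = 0; E[at(0, j)] = NEG; F[at(0, j)] = NEG; }
  for (int i = 0; i <= n; ++i) { H[at(i, 0)] = 0; E[at(i, 0)] = NEG; F[at(i, 0)] = NEG; }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[at(i, j - 1)] + gap_open + gap_extend,
                       E[at(i, j - 1)] + gap_extend);
      int f = std::max(H[at(i - 1, j)] + gap_open + gap_extend,
                       F[at(i - 1, j)] + gap_extend);
      int ca = base_code(a[i - 1]), cb = base_code(b[j - 1]);
      int sub = (ca >= 0 && ca == cb) ? match : mismatch;
      int h = H[at(i - 1, j - 1)] + sub;
      h = std::max(std::max(h, std::max(e, f)), 0);
      E[at(i, j)] = e; F[at(i, j)] = f; H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return res;  // empty local alignment
  res.score = best;
  res.a_end = bi; res.b_end = bj;
  // traceback
  std::string ops;
  int i = bi, j = bj, state = 0;  // 0=H, 1=E, 2=F
  while (i > 0 || j > 0) {
    if (state == 0) {
      int h = H[at(i, j)];
      if (h == 0) break;
      int ca = (i > 0) ? base_code(a[i - 1]) : -9;
      int cb = (j > 0) ? base_code(b[j - 1]) : -9;
      int sub = (ca >= 0 && ca == cb) ? match : mismatch;
      if (i > 0 && j > 0 && h == H[at(i - 1, j - 1)] + sub) {
        ops.push_back('M');
        res.n_cols++;
        if (ca >= 0 && ca == cb) res.n_match++; else res.n_mm++;
        --i; --j;
      } else if (i > 0 && h == F[at(i, j)]) {
        state = 2;
      } else if (j > 0 && h == E[at(i, j)]) {
        state = 1;
      } else break;
    } else if (state == 1) {  // gap in a, consume b
      ops.push_back('I');
      res.n_cols++; res.n_gap++;
      if (E[at(i, j)] == H[at(i, j - 1)] + gap_open + gap_extend) state = 0;
      --j;
    } else {  // gap in b, consume a
      ops.push_back('D');
      res.n_cols++; res.n_gap++;
      if (F[at(i, j)] == H[at(i - 1, j)] + gap_open + gap_extend) state = 0;
      --i;
    }
  }
  res.a_start = i; res.b_start = j;
  // compress reversed ops into a CIGAR
  std::string cig;
  for (auto it = ops.rbegin(); it != ops.rend();) {
    char op = *it;
    int run = 0;
    while (it != ops.rend() && *it == op) { ++run; ++it; }
    cig += std::to_string(run);
    cig.push_back(op);
  }
  res.cigar = cig;
  return res;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend) {
  SWResult r = sw_align_core(a, b, match, mismatch, gap_open, gap_extend);
  bool found = r.score > 0;
  return List::create(
      _["found"] = found, _["score"] = r.score,
      _["a_start"] = r.a_start, _["a_end"] = r.a_end,
      _["b_start"] = r.b_start, _["b_end"] = r.b_end,
      _["cigar"] = r.cigar, _["n_cols"] = r.n_cols,
      _["n_match"] = r.n_match, _["n_mismatch"] = r.n_mm, _["n_gap"] = r.n_gap);
}

// Banded global alignment of a pseudo-Sanger read against its truth
// fragment(s), unit costs. A substitution column is free when the read base
// equals either haplotype allele at that truth position (diploid tolerance);
// indel columns always cost 1. Returns the minimal error count and the
// read-local positions of the error columns (deletions charged to the
// preceding read position).
// [[Rcpp::export]]
List cpp_align_truth(std::string ps, std::string truth_a, std::string truth_b, int band) {
  int n = (int)ps.size(), m = (int)truth_a.size();
  bool dip = truth_b.size() == truth_a.size() && !truth_b.empty();
  if (n == 0 || m == 0)
    return List::create(_["ok"] = false, _["errors"] = NA_INTEGER,
                        _["err_pos"] = IntegerVector(0));
  int w = band + std::abs(n - m);
  const int INF = INT_MAX / 4;
  // D[i][j] over band |j - i*m/n| ... simple band around the main diagonal j ~ i + (m-n)*...
  // we band on |j - i| <= w (read and fragment lengths are close)
  auto idx = [w](int i, int j) { return (size_t)i * (2 * w + 1) + (j - i + w); };
  std::vector<int> D((size_t)(n + 1) * (2 * w + 1), INF);
  for (int j = 0; j <= std::min(m, w); ++j) D[idx(0, j)] = j;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i - w), jhi = std::min(m, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      int best = INF;
      if (j > 0 && j - 1 >= i - w) {
        int sub = 1;
        int cp = base_code(ps[i - 1]), ca = base_code(truth_a[j - 1]);
        if (cp >= 0 && cp == ca) sub = 0;
        else if (dip && cp >= 0 && cp == base_code(truth_b[j - 1])) sub = 0;
        if (D[idx(i - 1, j - 1)] < INF) best = std::min(best, D[idx(i - 1, j - 1)] + sub);
      }
      if (j - 1 >= std::max(0, i - w) && D[idx(i, j - 1)] < INF)
        best = std::min(best, D[idx(i, j - 1)] + 1);       // deletion in read
      if (j <= (i - 1) + w && D[idx(i - 1, j)] < INF)
        best = std::min(best, D[idx(i - 1, j)] + 1);       // insertion in read
      D[idx(i, j)] = best;
    }
  }
  if (m < n - w || D[idx(n, m)] >= INF)
    return List::create(_["ok"] = false, _["errors"] = NA_INTEGER,
                        _["err_pos"] = IntegerVector(0));
  // traceback for error positions on the read
  std::vector<int> pos;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int cur = D[idx(i, j)];
    if (i > 0 && j > 0 && j - 1 >= i - w) {
      int sub = 1;
      int cp = base_code(ps[i - 1]), ca = base_code(truth_a[j - 1]);
      if (cp >= 0 && cp == ca) sub = 0;
      else if (dip && cp >= 0 && cp == base_code(truth_b[j - 1])) sub = 0;
      if (D[idx(i - 1, j - 1)] + sub == cur) {
        if (sub) pos.push_back(i - 1);
        --i; --j; continue;
      }
    }
    if (i > 0 && j <= (i - 1) + w && D[idx(i - 1, j)] + 1 == cur) {
      pos.push_back(i - 1); --i; continue;  // insertion in read
    }
    if (j > 0 && j - 1 >= std::max(0, i - w) && D[idx(i, j - 1)] + 1 == cur) {
      pos.push_back(std::max(i - 1, 0)); --j; continue;  // deletion in read
    }
    break;  // unreachable for a consistent table
  }
  std::sort(pos.begin(), pos.end());
  return List::create(_["ok"] = true, _["errors"] = D[idx(n, m)],
                      _["err_pos"] = IntegerVector(pos.begin(), pos.end()));
}
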