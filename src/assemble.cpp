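#include "ps_core.h"
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------- clustering ----------------
// Reads in the index are interleaved pairs: read 2i is pair i's first read,
// read 2i+1 its second; mate(r) = r ^ 1, pair(r) = r >> 1.

// Forward-overlap clustering: anchor read 1 is scanned as sequenced, so a
// matching SR read is the left end of an inward-pointing pair (its partner
// falls inside the anchor span to the right). Anchor read 2 is also scanned
// as sequenced: a match there is the right end of an inward-pointing pair,
// stored reverse-complemented on the fragment-forward strand with its raw
// partner to the left. Reads that only reverse-overlap an anchor belong to
// outward-pointing pairs and are discarded.
void cluster_one(const SSIndex& idx, const std::vector<int>& /*unused*/,
                 const std::string& ar1, const std::string& ar2,
                 const Params& P, ClusterOut& out) {
  struct H { int read, anchor, diag, ov, mm; bool gapped; };
  std::vector<H> hits;
  std::unordered_set<int> hitL, hitR;
  const std::string* anchors[2] = { &ar1, &ar2 };
  for (int a = 0; a < 2; ++a) {
    const std::string& A = *anchors[a];
    if ((int)A.size() < idx.pat.span) continue;
    std::vector<std::pair<int,int>> cands;
    scan_forward(idx, A, cands);
    for (auto& c : cands) {
      int r = c.first, d = c.second;
      const std::string& s = idx.reads[r];
      int la = (int)A.size(), lb = (int)s.size();
      int ov = std::min(la, d + lb) - std::max(0, d);
      if (ov < P.min_overlap) continue;
      int cap = (int)std::floor(P.max_mm_rate * ov);
      int mm = gapless_mm(A, s, d, ov, cap);
      bool gapped = false;
      if (mm > cap) {
        SWResult sw = sw_align_core(A, s, P.sw_match, P.sw_mismatch,
                                    P.sw_gap_open, P.sw_gap_extend);
        if (sw.score <= 0 || sw.n_cols < P.min_overlap) continue;
        if ((double)sw.n_match / sw.n_cols < P.sw_min_identity) continue;
        d = sw.a_start - sw.b_start;
        ov = sw.n_cols; mm = sw.n_mm + sw.n_gap; gapped = true;
      }
      if (a == 1) {
        // express the hit on the right anchor's fragment-forward strand
        d = (int)A.size() - d - (int)s.size();
      }
      hits.push_back({ r, a, d, ov, mm, gapped });
      (a == 0 ? hitL : hitR).insert(r);
    }
  }
  out.hitsL = (int)hitL.size();
  out.hitsR = (int)hitR.size();
  // one member entry per SR pair: keep the best hit (max overlap, then
  // fewest mismatches, then left anchor, then smaller diagonal)
  std::unordered_map<int, size_t> best;  // pair -> index into out.members
  for (auto& h : hits) {
    int pr = h.read >> 1;
    MemberPair m { pr, h.read, h.read ^ 1, h.anchor, h.anchor == 1,
                   h.diag, h.ov, h.mm, h.gapped };
    auto it = best.find(pr);
    if (it == best.end()) {
      best[pr] = out.members.size();
      out.members.push_back(m);
    } else {
      MemberPair& o = out.members[it->second];
      if (m.ov > o.ov || (m.ov == o.ov && (m.mm < o.mm ||
          (m.mm == o.mm && (m.anchor < o.anchor ||
          (m.anchor == o.anchor && m.diag < o.diag))))))
        o = m;
    }
  }
}

// [[Rcpp::export]]
List cpp_cluster_one(SEXP xp_, std::string ar1, std::string ar2, List params) {
  XPtr<SSIndex> xp(xp_);
  Params P = params_from_list(params);
  ClusterOut cl;
  std::vector<int> dummy;
  cluster_one(*xp, dummy, ar1, ar2, P, cl);
  int n = (int)cl.members.size();
  IntegerVector pair(n), m_read(n), p_read(n), diag(n), ov(n), mm(n), anchor(n);
  LogicalVector gapped(n), m_rc(n);
  for (int i = 0; i < n; ++i) {
    const MemberPair& m = cl.members[i];
    pair[i] = m.pair + 1; m_read[i] = m.m_read + 1; p_read[i] = m.p_read + 1;
    anchor[i] = m.anchor + 1; diag[i] = m.diag; ov[i] = m.ov; mm[i] = m.mm;
    gapped[i] = m.gapped; m_rc[i] = m.m_rc;
  }
  DataFrame members = DataFrame::create(
      _["pair"] = pair, _["m_read"] = m_read, _["p_read"] = p_read,
      _["anchor"] = anchor, _["m_rc"] = m_rc, _["diag"] = diag,
      _["overlap_len"] = ov, _["mismatches"] = mm, _["gapped"] = gapped);
  return List::create(_["left"] = ar1, _["right"] = revcomp(ar2),
                      _["hitsL"] = cl.hitsL, _["hitsR"] = cl.hitsR,
                      _["members"] = members);
}

// ---------------- overlap graph ----------------

void build_graph(const std::vector<std::string>& seqs, const Params& P,
                 std::vector<Edge>& edges,
                 std::vector<std::pair<int,int>>& contain) {
  int n = (int)seqs.size();
  // shared-seed candidate shifts within the cluster, via a sorted entry
  // list rather than a hash table; buffers are reused across anchors
  thread_local std::vector<std::tuple<uint64_t,int,int>> entries;  // key, node, pos
  thread_local std::vector<std::tuple<int,int,int>> cand;          // u, v, shift
  entries.clear();
  cand.clear();
  for (int u = 0; u < n; ++u) {
    const std::string& s = seqs[u];
    int m = (int)s.size() - P.pat.span + 1;
    for (int i = 0; i < m; ++i) {
      uint64_t key;
      if (seed_key_at(s, i, P.pat, key)) entries.emplace_back(key, u, i);
    }
  }
  std::sort(entries.begin(), entries.end());
  for (size_t b0 = 0, b1; b0 < entries.size(); b0 = b1) {
    b1 = b0 + 1;
    while (b1 < entries.size() &&
           std::get<0>(entries[b1]) == std::get<0>(entries[b0])) ++b1;
    if ((int)(b1 - b0) > P.bucket_cap) continue;
    for (size_t x = b0; x < b1; ++x) {
      for (size_t y = x + 1; y < b1; ++y) {
        int u = std::get<1>(entries[x]), v = std::get<1>(entries[y]);
        if (u == v) continue;
        int t = std::get<2>(entries[x]) - std::get<2>(entries[y]);
        int a, b;
        if (t > 0) { a = u; b = v; }
        else if (t < 0) { a = v; b = u; t = -t; }
        else { a = std::min(u, v); b = std::max(u, v); }
        cand.emplace_back(a, b, t);
      }
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  std::unordered_set<uint64_t> contained_seen;
  for (auto& c : cand) {
    int u = std::get<0>(c), v = std::get<1>(c), t = std::get<2>(c);
    int lu = (int)seqs[u].size(), lv = (int)seqs[v].size();
    int ov = std::min(lu, t + lv) - t;
    if (ov < P.min_overlap) continue;
    int cap = (int)std::floor(P.max_mm_rate * ov);
    int mm = gapless_mm(seqs[u], seqs[v], t, ov, cap);
    if (mm > cap) continue;
    if (t + lv <= lu) {  // v lies inside u: containment, not a path edge
      uint64_t k = ((uint64_t)v * n) + u;
      if (contained_seen.insert(k).second) contain.push_back({ v, u });
      continue;
    }
    if (t == 0) continue;  // same start, v longer: u inside v, skip as edge
    edges.push_back({ u, v, t, ov, mm });
  }
  // t == 0 with lv > lu: record u contained in v
  for (auto& c : cand) {
    int u = std::get<0>(c), v = std::get<1>(c), t = std::get<2>(c);
    if (t != 0) continue;
    int lu = (int)seqs[u].size(), lv = (int)seqs[v].size();
    if (lv <= lu) continue;
    int ov = lu;
    if (ov < P.min_overlap) continue;
    int cap = (int)std::floor(P.max_mm_rate * ov);
    int mm = gapless_mm(seqs[u], seqs[v], 0, ov, cap);
    if (mm > cap) continue;
    uint64_t k = ((uint64_t)u * n) + v;
    if (contained_seen.insert(k).second) contain.push_back({ u, v });
  }
}

// [[Rcpp::export]]
List cpp_build_graph(CharacterVector seqs, List params) {
  Params P = params_from_list(params);
  std::vector<std::string> s;
  s.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) s.push_back(as<std::string>(seqs[i]));
  std::vector<Edge> edges;
  std::vector<std::pair<int,int>> contain;
  build_graph(s, P, edges, contain);
  int ne = (int)edges.size(), nc = (int)contain.size();
  IntegerVector from(ne), to(ne), shift(ne), ov(ne), mm(ne), inner(nc), outer(nc);
  for (int i = 0; i < ne; ++i) {
    from[i] = edges[i].from + 1; to[i] = edges[i].to + 1;
    shift[i] = edges[i].shift; ov[i] = edges[i].ov; mm[i] = edges[i].mm;
  }
  for (int i = 0; i < nc; ++i) {
    inner[i] = contain[i].first + 1; outer[i] = contain[i].second + 1;
  }
  return List::create(
      _["edges"] = DataFrame::create(_["from"] = from, _["to"] = to,
                                     _["shift"] = shift, _["overlap_len"] = ov,
                                     _["mismatches"] = mm),
      _["containments"] = DataFrame::create(_["inner"] = inner, _["outer"] = outer));
}

// ---------------- traversal ----------------
// Heap search over (node, offset) states. Every edge advances the offset by
// at least 1, so processing states in increasing offset order makes the
// state space a DAG and the maximum-overlapped-bases layout exact. Ties:
// higher score, then smaller span, then lexicographically smallest node
// sequence (reconstructed against a backward score table).

TravOut traverse_core(int n_nodes, const std::vector<int>& node_len,
                      const std::vector<Edge>& edges, int left, int right,
                      int imin, int imax) {
  TravOut res;
  if (left == right || n_nodes < 2) return res;
  std::vector<std::vector<Edge>> adj(n_nodes);
  for (const Edge& e : edges) {
    if (e.shift < 1 || e.from == e.to) continue;
    if (e.to == left || e.from == right) continue;
    adj[e.from].push_back(e);
  }
  for (auto& v : adj)  // deterministic expansion order
    std::sort(v.begin(), v.end(), [](const Edge& a, const Edge& b) {
      return a.to != b.to ? a.to < b.to : a.shift < b.shift;
    });
  const int64_t W = imax + 2;
  auto key = [W](int node, int off) { return (int64_t)node * W + off; };
  std::unordered_map<int64_t, long long> f;
  using QE = std::tuple<int, int64_t, long long>;  // (offset, state, score)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  f[key(left, 0)] = 0;
  pq.push({ 0, key(left, 0), 0 });
  int lenR = node_len[right];
  while (!pq.empty()) {
    auto [off, st, sc] = pq.top(); pq.pop();
    auto it = f.find(st);
    if (it == f.end() || it->second != sc) continue;  // stale
    int u = (int)(st / W);
    if (u == right) continue;
    for (const Edge& e : adj[u]) {
      int o2 = off + e.shift;
      if (o2 > imax) continue;
      if (e.to == right) {
        if (o2 + lenR > imax) continue;
      } else if (o2 + 1 + lenR > imax) continue;
      long long ns = sc + e.ov;
      int64_t k2 = key(e.to, o2);
      auto jt = f.find(k2);
      if (jt == f.end() || jt->second < ns) {
        f[k2] = ns;
        pq.push({ o2, k2, ns });
      }
    }
  }
  // best feasible arrival at the right anchor
  long long S = -1; int bestoff = -1;
  for (auto& kv : f) {
    int node = (int)(kv.first / W), off = (int)(kv.first % W);
    if (node != right) continue;
    int span = off + lenR;
    if (span < imin || span > imax) continue;
    if (kv.second > S || (kv.second == S && span < bestoff + lenR)) {
      S = kv.second; bestoff = off;
    }
  }
  if (S < 0) return res;
  int goal = bestoff;
  // backward best-score-to-goal over reachable states
  std::vector<std::pair<int64_t, long long>> states(f.begin(), f.end());
  std::sort(states.begin(), states.end(),
            [W](const std::pair<int64_t, long long>& a,
                const std::pair<int64_t, long long>& b) {
              return (a.first % W) > (b.first % W);
            });
  std::unordered_map<int64_t, long long> g;
  g[key(right, goal)] = 0;
  for (auto& kv : states) {
    int u = (int)(kv.first / W), off = (int)(kv.first % W);
    if (u == right) continue;
    long long bestg = -1;
    for (const Edge& e : adj[u]) {
      auto jt = g.find(key(e.to, off + e.shift));
      if (jt != g.end() && jt->second >= 0) bestg = std::max(bestg, e.ov + jt->second);
    }
    if (bestg >= 0) g[kv.first] = bestg;
  }
  // lexicographically smallest optimal path, rebuilt greedily from the left
  res.found = true;
  res.score = S;
  res.span = goal + lenR;
  int u = left, off = 0;
  long long acc = 0;
  res.path.push_back(u);
  res.offsets.push_back(0);
  while (u != right) {
    int pick_v = -1, pick_t = 0, pick_ov = 0;
    for (const Edge& e : adj[u]) {
      int o2 = off + e.shift;
      if (o2 > imax) continue;
      auto jt = g.find(key(e.to, o2));
      if (jt == g.end()) continue;
      if (acc + e.ov + jt->second == S) { pick_v = e.to; pick_t = e.shift; pick_ov = e.ov; break; }
    }
    if (pick_v < 0) { res.found = false; return res; }  // defensive; cannot happen
    u = pick_v; off += pick_t; acc += pick_ov;
    res.path.push_back(u);
    res.offsets.push_back(off);
  }
  return res;
}

// [[Rcpp::export]]
List cpp_traverse(IntegerVector node_len, DataFrame edges, int left, int right,
                  int imin, int imax) {
  std::vector<int> nl(node_len.begin(), node_len.end());
  IntegerVector from = edges["from"], to = edges["to"],
                shift = edges["shift"], ov = edges["overlap_len"];
  std::vector<Edge> ev;
  for (R_xlen_t i = 0; i < from.size(); ++i) {
    if (shift[i] < 1) stop("layout edges must advance the offset (shift >= 1)");
    ev.push_back({ from[i] - 1, to[i] - 1, shift[i], ov[i], 0 });
  }
  TravOut t = traverse_core((int)nl.size(), nl, ev, left - 1, right - 1, imin, imax);
  if (!t.found)
    return List::create(_["found"] = false);
  IntegerVector path(t.path.size()), offs(t.offsets.size());
  for (size_t i = 0; i < t.path.size(); ++i) { path[i] = t.path[i] + 1; offs[i] = t.offsets[i]; }
  return List::create(_["found"] = true, _["path"] = path, _["offsets"] = offs,
                      _["score"] = (double)t.score, _["span"] = t.span);
}

// ---------------- column consensus ----------------
// Plurality vote per column; ties go to the covering read with the smallest
// offset, anchors outranking supporting reads at equal offsets. CIGARs
// (M/I/D relative to the consensus coordinate) let gapped placements vote,
// deletions voting for a gap symbol; a winning gap drops the column.

ConsOut consensus_columns(const std::vector<std::string>& seqs,
                          const std::vector<Placement>& pl, int span) {
  ConsOut out;
  if (span <= 0) return out;
  std::vector<int> rank(pl.size());
  for (size_t i = 0; i < pl.size(); ++i) rank[i] = (int)i;
  std::sort(rank.begin(), rank.end(), [&pl](int a, int b) {
    if (pl[a].offset != pl[b].offset) return pl[a].offset < pl[b].offset;
    if (pl[a].priority != pl[b].priority) return pl[a].priority < pl[b].priority;
    return a < b;
  });
  // per-column votes in rank order; code 0..3 = base, 4 = gap
  std::vector<std::vector<int8_t>> col((size_t)span);
  for (int ri : rank) {
    const Placement& p = pl[ri];
    const std::string& s = seqs[p.node];
    if (p.cigar.empty()) {
      for (int k = 0; k < (int)s.size(); ++k) {
        int j = p.offset + k;
        if (j < 0 || j >= span) continue;
        int c = base_code(s[k]);
        if (c >= 0) col[j].push_back((int8_t)c);
      }
    } else {
      int j = p.offset, k = 0;
      size_t ci = 0;
      while (ci < p.cigar.size()) {
        int run = 0;
        while (ci < p.cigar.size() && isdigit(p.cigar[ci]))
          run = run * 10 + (p.cigar[ci++] - '0');
        char op = p.cigar[ci++];
        for (int q = 0; q < run; ++q) {
          if (op == 'M') {
            if (j >= 0 && j < span) {
              int c = base_code(s[k]);
              if (c >= 0) col[j].push_back((int8_t)c);
            }
            ++j; ++k;
          } else if (op == 'D') {
            if (j >= 0 && j < span) col[j].push_back(4);
            ++j;
          } else if (op == 'I') {
            ++k;  // read base between consensus columns: no vote
          }
        }
      }
    }
  }
  static const char* B = "ACGT";
  out.seq.reserve(span);
  out.qual.reserve(span);
  out.depth.reserve(span);
  for (int j = 0; j < span; ++j) {
    if (col[j].empty()) { out.seq.push_back('N'); out.qual.push_back('!'); out.depth.push_back(0); continue; }
    int cnt[5] = { 0, 0, 0, 0, 0 };
    for (int8_t c : col[j]) cnt[c]++;
    int mx = 0;
    for (int c = 0; c < 5; ++c) mx = std::max(mx, cnt[c]);
    int winner = -1, tied = 0;
    for (int c = 0; c < 5; ++c) if (cnt[c] == mx) { tied++; if (winner < 0) winner = c; }
    if (tied > 1) {
      for (int8_t c : col[j]) if (cnt[c] == mx) { winner = c; break; }
    }
    if (winner == 4) continue;  // gap wins: column removed
    int total = (int)col[j].size();
    double fmaj = (double)cnt[winner] / total;
    int q = (int)std::lround(-10.0 * std::log10(std::max(1.0 - fmaj, 1e-4)));
    if (q > 40) q = 40;
    out.seq.push_back(B[winner]);
    out.qual.push_back((char)(33 + q));
    out.depth.push_back(total);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_consensus(CharacterVector seqs, IntegerVector offsets,
                   IntegerVector priority, CharacterVector cigars, int span) {
  std::vector<std::string> s;
  std::vector<Placement> pl;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    s.push_back(as<std::string>(seqs[i]));
    std::string cg = cigars.size() ? as<std::string>(cigars[i]) : std::string();
    pl.push_back({ (int)i, offsets[i], cg, priority[i] });
  }
  ConsOut c = consensus_columns(s, pl, span);
  return List::create(_["seq"] = c.seq, _["qual"] = c.qual,
                      _["depth"] = IntegerVector(c.depth.begin(), c.depth.end()));
}

// ---------------- inner-SR recruitment ----------------

void recruit_inner(const SSIndex& idx, const std::vector<int>& pair_lib,
                   const std::vector<int>& /*unused*/,
                   const std::vector<double>& lib_mean,
                   const std::vector<double>& lib_sd,
                   const std::string& prim, const Params& P,
                   std::vector<RecruitHit>& out) {
  int span = (int)prim.size();
  // direct seed placements of either end: forward scan finds left-end reads
  // as stored, reverse scan finds right-end reads (placed revcomp)
  struct Direct { int offset, mm; bool rc; };
  std::unordered_map<int, Direct> direct;
  std::vector<int> order;
  for (int pass = 0; pass < 2; ++pass) {
    std::vector<std::pair<int,int>> cands;
    if (pass == 0) scan_forward(idx, prim, cands);
    else {
      std::string prc = revcomp(prim);
      scan_forward(idx, prc, cands);
      for (auto& c : cands)  // re-express on the primitive's strand
        c.second = span - c.second - (int)idx.reads[c.first].size();
    }
    for (auto& c : cands) {
      int r = c.first, d = c.second;
      std::string s = pass == 0 ? idx.reads[r] : revcomp(idx.reads[r]);
      int len = (int)s.size();
      if (d < 0 || d + len > span) continue;  // inner = fully inside
      int cap = (int)std::floor(P.max_mm_rate * len);
      int ov, mm = gapless_mm(prim, s, d, ov, cap);
      if (mm > cap) continue;
      auto it = direct.find(r);
      if (it == direct.end()) {
        direct[r] = { d, mm, pass == 1 };
        order.push_back(r);
      } else if (mm < it->second.mm ||
                 (mm == it->second.mm && d < it->second.offset)) {
        it->second = { d, mm, pass == 1 };
      }
    }
  }
  std::unordered_set<int> pair_done;
  for (int r : order) {
    int pr = r >> 1;
    if (!pair_done.insert(pr).second) continue;
    int q = r ^ 1;
    Direct dp = direct[r];
    int lenm = (int)idx.reads[r].size();
    // the partner takes the opposite orientation; its expected start follows
    // from the library insert: left end + insert = right end's far edge
    std::string pseq = dp.rc ? idx.reads[q] : revcomp(idx.reads[q]);
    int lenq = (int)pseq.size();
    int lib = pair_lib[pr];
    int ins = (int)std::lround(lib_mean[lib]);
    int center = dp.rc ? dp.offset + lenm - ins : dp.offset + ins - lenq;
    int hw = (int)std::ceil(3.0 * lib_sd[lib]) + P.min_overlap;
    int lo = std::max(0, center - hw), hi = std::min(span - lenq, center + hw);
    if (lo > hi) continue;  // partner window falls outside the primitive
    int cap = (int)std::floor(P.max_mm_rate * lenq);
    int bestt = -1;
    // outward from the window centre; an off-diagonal hit inside the
    // mismatch cap would need >92% identity at the wrong offset, so the
    // first acceptable diagonal is taken
    for (int k = 0; center - k >= lo || center + k <= hi; ++k) {
      int t1 = center - k, t2 = center + k;
      if (t1 >= lo && t1 <= hi) {
        int ov, mm = gapless_mm(prim, pseq, t1, ov, cap);
        if (mm <= cap) { bestt = t1; break; }
      }
      if (k > 0 && t2 >= lo && t2 <= hi) {
        int ov, mm = gapless_mm(prim, pseq, t2, ov, cap);
        if (mm <= cap) { bestt = t2; break; }
      }
    }
    if (bestt >= 0) {
      out.push_back({ r, pr, dp.offset, "", false, dp.rc, 0, lenm });
      out.push_back({ q, pr, bestt, "", false, !dp.rc, 0, lenq });
      continue;
    }
    // Smith-Waterman fallback for the partner inside its window
    int wlo = lo, whi = std::min(span, hi + lenq);
    std::string sub = prim.substr(wlo, whi - wlo);
    SWResult sw = sw_align_core(sub, pseq, P.sw_match, P.sw_mismatch,
                                P.sw_gap_open, P.sw_gap_extend);
    if (sw.score <= 0) continue;
    if (sw.b_end - sw.b_start < (int)std::ceil(0.9 * lenq)) continue;
    if ((double)sw.n_match / sw.n_cols < P.sw_min_identity) continue;
    // the partner read must lie inside the primitive in full, not merely
    // its aligned portion: clipped boundary placements are not inner pairs
    int full_lo = wlo + sw.a_start - sw.b_start;
    if (full_lo < 0 || full_lo + lenq > span) continue;
    out.push_back({ r, pr, dp.offset, "", false, dp.rc, 0, lenm });
    out.push_back({ q, pr, wlo + sw.a_start, sw.cigar, true, !dp.rc,
                    sw.b_start, sw.b_end });
  }
}

// [[Rcpp::export]]
DataFrame cpp_recruit(SEXP xp_, IntegerVector pair_lib, NumericVector lib_mean,
                      NumericVector lib_sd, std::string prim, List params) {
  XPtr<SSIndex> xp(xp_);
  Params P = params_from_list(params);
  std::vector<int> pl(pair_lib.begin(), pair_lib.end());
  for (auto& v : pl) --v;
  std::vector<double> lm(lib_mean.begin(), lib_mean.end()),
      ls(lib_sd.begin(), lib_sd.end());
  std::vector<RecruitHit> hits;
  std::vector<int> dummy;
  recruit_inner(*xp, pl, dummy, lm, ls, prim, P, hits);
  int n = (int)hits.size();
  IntegerVector read(n), pair(n), offset(n), bs(n), be(n);
  CharacterVector cigar(n);
  LogicalVector rc(n), via_sw(n);
  for (int i = 0; i < n; ++i) {
    read[i] = hits[i].read + 1; pair[i] = hits[i].pair + 1;
    offset[i] = hits[i].offset; cigar[i] = hits[i].cigar;
    rc[i] = hits[i].rc; via_sw[i] = hits[i].via_sw;
    bs[i] = hits[i].b_start; be[i] = hits[i].b_end;
  }
  return DataFrame::create(_["read"] = read, _["pair"] = pair,
                           _["offset"] = offset, _["rc"] = rc,
                           _["cigar"] = cigar, _["via_sw"] = via_sw,
                           _["b_start"] = bs, _["b_end"] = be);
}

// ---------------- batch per-pass driver ----------------
// Assembles every anchor pair of one pass against the spaced-seed index of
// the pass's supporting reads. Status codes: 0 assembled, 1 repetitive,
// 2 empty cluster, 3 no feasible path, 4 anchor unusable.

// [[Rcpp::export]]
List cpp_run_pass(SEXP xp_, IntegerVector pair_lib, NumericVector lib_mean,
                  NumericVector lib_sd, CharacterVector ar1, CharacterVector ar2,
                  int imin, int imax, double E, List params) {
  XPtr<SSIndex> xp(xp_);
  Params P = params_from_list(params);
  std::vector<int> plib(pair_lib.begin(), pair_lib.end());
  for (auto& v : plib) --v;
  std::vector<double> lm(lib_mean.begin(), lib_mean.end()),
      ls(lib_sd.begin(), lib_sd.end());
  int n_pairs = (int)plib.size();
  if ((int)xp->reads.size() != 2 * n_pairs)
    stop("index must hold interleaved read pairs matching pair_lib");
  R_xlen_t n_ar = ar1.size();
  if (ar2.size() != n_ar) stop("ar1/ar2 length mismatch");
  double gate = P.repeat_factor * E;

  IntegerVector status(n_ar), span(n_ar), n_members(n_ar),
      hitsL(n_ar), hitsR(n_ar), depth_min(n_ar);
  NumericVector score(n_ar), depth_mean(n_ar);
  CharacterVector seq(n_ar), qual(n_ar);
  LogicalVector consumed(n_pairs), on_layout(n_pairs), recruited_any(n_pairs);
  std::vector<int> dummy;

  for (R_xlen_t a = 0; a < n_ar; ++a) {
    if (a % 256 == 0) Rcpp::checkUserInterrupt();
    seq[a] = NA_STRING; qual[a] = NA_STRING; span[a] = NA_INTEGER;
    std::string A1 = as<std::string>(ar1[a]);
    std::string A2 = as<std::string>(ar2[a]);
    std::string L = A1, R_ = revcomp(A2);
    if ((int)L.size() < xp->pat.span || (int)R_.size() < xp->pat.span) {
      status[a] = 4; continue;
    }
    ClusterOut cl;
    cluster_one(*xp, dummy, A1, A2, P, cl);
    hitsL[a] = cl.hitsL; hitsR[a] = cl.hitsR;
    n_members[a] = (int)cl.members.size();
    if (cl.hitsL > gate || cl.hitsR > gate) { status[a] = 1; continue; }
    if (cl.members.empty()) { status[a] = 2; continue; }
    // nodes: 0 = left anchor, 1 = right anchor, then (matched, partner) per member
    std::vector<std::string> seqs;
    std::vector<int> node_read;  // global read index per node, -1 for anchors
    seqs.push_back(L); node_read.push_back(-1);
    seqs.push_back(R_); node_read.push_back(-1);
    for (const MemberPair& m : cl.members) {
      if (m.m_rc) {
        seqs.push_back(revcomp(xp->reads[m.m_read]));
        seqs.push_back(xp->reads[m.p_read]);
      } else {
        seqs.push_back(xp->reads[m.m_read]);
        seqs.push_back(revcomp(xp->reads[m.p_read]));
      }
      node_read.push_back(m.m_read); node_read.push_back(m.p_read);
    }
    std::vector<Edge> edges;
    std::vector<std::pair<int,int>> contain;
    build_graph(seqs, P, edges, contain);
    std::vector<int> nl;
    for (auto& s : seqs) nl.push_back((int)s.size());
    TravOut tr = traverse_core((int)seqs.size(), nl, edges, 0, 1, imin, imax);
    if (!tr.found) { status[a] = 3; continue; }
    // primitive consensus from the layout
    std::vector<Placement> pl;
    for (size_t i = 0; i < tr.path.size(); ++i)
      pl.push_back({ tr.path[i], tr.offsets[i], "", tr.path[i] < 2 ? 0 : 1 });
    ConsOut prim = consensus_columns(seqs, pl, tr.span);
    // recruit inner SR pairs onto the primitive and vote again
    std::vector<RecruitHit> rec;
    recruit_inner(*xp, plib, dummy, lm, ls, prim.seq, P, rec);
    std::unordered_set<int> path_reads;
    for (size_t i = 0; i < tr.path.size(); ++i)
      if (node_read[tr.path[i]] >= 0) path_reads.insert(node_read[tr.path[i]]);
    std::vector<std::string> fseqs;
    std::vector<Placement> fpl;
    for (size_t i = 0; i < tr.path.size(); ++i) {
      fseqs.push_back(seqs[tr.path[i]]);
      fpl.push_back({ (int)i, tr.offsets[i], "", tr.path[i] < 2 ? 0 : 1 });
    }
    std::unordered_set<int> voting = path_reads;
    for (const RecruitHit& h : rec) {
      voting.insert(h.read);
      if (path_reads.count(h.read)) continue;  // already votes via the layout
      std::string s = h.rc ? revcomp(xp->reads[h.read]) : xp->reads[h.read];
      if (!h.cigar.empty())
        s = s.substr(h.b_start, h.b_end - h.b_start);
      fpl.push_back({ (int)fseqs.size(), h.offset, h.cigar, 2 });
      fseqs.push_back(s);
    }
    // anchor-verified member reads also vote (they may cross the primitive's
    // ends, correcting anchor errors in the thin terminal columns)
    int lenRa = nl[1];
    for (size_t mi = 0; mi < cl.members.size(); ++mi) {
      const MemberPair& m = cl.members[mi];
      if (m.gapped || voting.count(m.m_read)) continue;
      int off = m.anchor == 0 ? m.diag : tr.span - lenRa + m.diag;
      fpl.push_back({ (int)fseqs.size(), off, "", 2 });
      fseqs.push_back(seqs[2 + 2 * mi]);
    }
    ConsOut fin = consensus_columns(fseqs, fpl, tr.span);
    status[a] = 0;
    seq[a] = fin.seq; qual[a] = fin.qual;
    span[a] = (int)fin.seq.size();
    score[a] = (double)tr.score;
    long long dsum = 0; int dmin = INT_MAX;
    for (int d : fin.depth) { dsum += d; dmin = std::min(dmin, d); }
    depth_min[a] = fin.depth.empty() ? 0 : dmin;
    depth_mean[a] = fin.depth.empty() ? 0.0 : (double)dsum / fin.depth.size();
    // bookkeeping for demotion and pair classification
    for (int r : path_reads) on_layout[r >> 1] = true;
    for (const RecruitHit& h : rec) recruited_any[h.pair] = true;
    for (int r : voting) {
      int pr = r >> 1;
      if (voting.count(pr * 2) && voting.count(pr * 2 + 1)) consumed[pr] = true;
    }
  }
  return List::create(
      _["status"] = status, _["seq"] = seq, _["qual"] = qual, _["span"] = span,
      _["score"] = score, _["n_members"] = n_members,
      _["hitsL"] = hitsL, _["hitsR"] = hitsR,
      _["depth_min"] = depth_min, _["depth_mean"] = depth_mean,
      _["consumed"] = consumed, _["on_layout"] = on_layout,
      _["recruited"] = recruited_any);
}
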