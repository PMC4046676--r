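#ifndef PS_CORE_H
#define PS_CORE_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>

// ---- shared types for the pseudo-Sanger core ----

struct SeedPattern {
  std::vector<int> care;  // offsets of '1' positions within the span
  int span = 0;
};

SeedPattern parse_pattern(const std::string& mask);

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N and friends never match a seed key
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s);

// key extraction at `pos`; false if the window holds a non-ACGT base
bool seed_key_at(const std::string& s, int pos, const SeedPattern& p, uint64_t& key);

// Blocked spaced-seed index over supporting reads (stored strand only).
// Entries pack (read_id << 8) | read_offset; reads must be < 256 bp.
struct SSIndex {
  SeedPattern pat;
  int step = 1;
  std::vector<std::string> reads;
  std::unordered_map<uint64_t, std::vector<uint32_t>> table;
  int skipped_short = 0;
  long long n_entries = 0;
};

struct Params {
  SeedPattern pat;
  int min_overlap = 30;
  double max_mm_rate = 0.08;
  int sw_match = 1, sw_mismatch = -2, sw_gap_open = -3, sw_gap_extend = -1;
  double sw_min_identity = 0.92;
  double repeat_factor = 1.5;
  int bucket_cap = 1000;
};

Params params_from_list(Rcpp::List par);

// gapless overlap on a fixed diagonal: b placed at offset `diag` in a's
// coordinates; returns overlap length via `ov` and the mismatch count,
// bailing out early (returning mm_cap + 1) once mm_cap is exceeded.
int gapless_mm(const std::string& a, const std::string& b, int diag, int& ov, int mm_cap);

struct SWResult {
  int score = 0;
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;  // 0-based half-open
  std::string cigar;  // M/I/D relative to `a` (D consumes a only)
  int n_cols = 0, n_match = 0, n_mm = 0, n_gap = 0;
};

SWResult sw_align_core(const std::string& a, const std::string& b,
                       int match, int mismatch, int gap_open, int gap_extend);

// forward-strand scan of `q` against the index; (read, diagonal) pairs in
// discovery order, deduplicated
void scan_forward(const SSIndex& idx, const std::string& q,
                  std::vector<std::pair<int,int>>& out);

struct MemberPair {
  int pair;             // 0-based pair index
  int m_read, p_read;   // global read indices
  int anchor;           // 0 = left, 1 = right
  // fragment-forward node sequences: m is stored revcomp when it matched the
  // right anchor (m_rc); the partner is then stored raw, and vice versa
  bool m_rc;
  int diag, ov, mm;     // diag: m start in the matched anchor's forward coords
  bool gapped;
};

struct ClusterOut {
  int hitsL = 0, hitsR = 0;
  std::vector<MemberPair> members;
};

void cluster_one(const SSIndex& idx, const std::vector<int>& read_pair,
                 const std::string& left, const std::string& right,
                 const Params& P, ClusterOut& out);

struct Edge { int from, to, shift, ov, mm; };

void build_graph(const std::vector<std::string>& seqs, const Params& P,
                 std::vector<Edge>& edges,
                 std::vector<std::pair<int,int>>& contain);

struct TravOut {
  bool found = false;
  std::vector<int> path, offsets;
  long long score = 0;
  int span = 0;
};

TravOut traverse_core(int n_nodes, const std::vector<int>& node_len,
                      const std::vector<Edge>& edges, int left, int right,
                      int imin, int imax);

struct Placement {
  int node;        // index into the parallel seqs vector
  int offset;
  std::string cigar;  // "" = gapless full-length
  int priority;    // 0 anchor, 1 layout member, 2 recruited
};

struct ConsOut {
  std::string seq, qual;
  std::vector<int> depth;
};

ConsOut consensus_columns(const std::vector<std::string>& seqs,
                          const std::vector<Placement>& pl, int span);

struct RecruitHit {
  int read, pair;
  int offset;
  std::string cigar;  // "" gapless
  bool via_sw;
  bool rc;            // voted as reverse complement (partner reads)
  int b_start, b_end; // read interval actually placed (half-open)
};

void recruit_inner(const SSIndex& idx, const std::vector<int>& read_pair,
                   const std::vector<int>& read_lib,
                   const std::vector<double>& lib_mean,
                   const std::vector<double>& lib_sd,
                   const std::string& prim, const Params& P,
                   std::vector<RecruitHit>& out);

#endif
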