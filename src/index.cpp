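#include "ps_core.h"
using namespace Rcpp;

SeedPattern parse_pattern(const std::string& mask) {
  SeedPattern p;
  if (mask.empty()) stop("seed pattern must be non-empty");
  if (mask.front() != '1' || mask.back() != '1')
    stop("seed pattern must begin and end with '1'");
  for (size_t i = 0; i < mask.size(); ++i) {
    if (mask[i] == '1') p.care.push_back((int)i);
    else if (mask[i] != '0') stop("seed pattern may contain only '0' and '1'");
  }
  p.span = (int)mask.size();
  if ((int)p.care.size() > 31) stop("seed pattern weight must be <= 31");
  return p;
}

std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

bool seed_key_at(const std::string& s, int pos, const SeedPattern& p, uint64_t& key) {
  key = 0;
  for (int c : p.care) {
    int code = base_code(s[pos + c]);
    if (code < 0) return false;
    key = (key << 2) | (uint64_t)code;
  }
  return true;
}

Params params_from_list(List par) {
  Params P;
  P.pat = parse_pattern(as<std::string>(par["seed_pattern"]));
  P.min_overlap = as<int>(par["min_overlap"]);
  P.max_mm_rate = as<double>(par["max_mismatch_rate"]);
  NumericVector sc = par["sw_scores"];
  if (sc.size() != 4) stop("sw_scores must be (match, mismatch, gap_open, gap_extend)");
  P.sw_match = (int)sc[0]; P.sw_mismatch = (int)sc[1];
  P.sw_gap_open = (int)sc[2]; P.sw_gap_extend = (int)sc[3];
  P.sw_min_identity = as<double>(par["sw_min_identity"]);
  P.repeat_factor = as<double>(par["repeat_factor"]);
  return P;
}

// [[Rcpp::export]]
List cpp_pattern_info(std::string pattern) {
  SeedPattern p = parse_pattern(pattern);
  return List::create(_["span"] = p.span,
                      _["weight"] = (int)p.care.size(),
                      _["care"] = IntegerVector(p.care.begin(), p.care.end()));
}

// Seed keys of one sequence, as strings (NA where the window holds non-ACGT).
// [[Rcpp::export]]
CharacterVector cpp_seed_keys(std::string seq, std::string pattern, int step) {
  SeedPattern p = parse_pattern(pattern);
  if (step < 1) stop("step must be >= 1");
  int n = (int)seq.size() - p.span + 1;
  std::vector<int> pos;
  for (int i = 0; i < n; i += step) pos.push_back(i);
  CharacterVector out(pos.size());
  IntegerVector at(pos.size());
  for (size_t k = 0; k < pos.size(); ++k) {
    at[k] = pos[k];
    std::string key;
    bool ok = true;
    for (int c : p.care) {
      char b = seq[pos[k] + c];
      if (base_code(b) < 0) { ok = false; break; }
      key.push_back((char)toupper(b));
    }
    if (ok) out[k] = key; else out[k] = NA_STRING;
  }
  out.attr("positions") = at;
  return out;
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector reads, std::string pattern, int step) {
  if (step < 1) stop("step must be >= 1");
  XPtr<SSIndex> xp(new SSIndex(), true);
  xp->pat = parse_pattern(pattern);
  xp->step = step;
  xp->reads.reserve(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() > 255) stop("indexed reads must be <= 255 bp");
    xp->reads.push_back(s);
  }
  for (size_t r = 0; r < xp->reads.size(); ++r) {
    const std::string& s = xp->reads[r];
    int n = (int)s.size() - xp->pat.span + 1;
    if (n <= 0) { xp->skipped_short++; continue; }
    for (int i = 0; i < n; i += step) {
      uint64_t key;
      if (!seed_key_at(s, i, xp->pat, key)) continue;
      xp->table[key].push_back(((uint32_t)r << 8) | (uint32_t)i);
      xp->n_entries++;
    }
  }
  return xp;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp_) {
  XPtr<SSIndex> xp(xp_);
  return List::create(_["n_reads"] = (int)xp->reads.size(),
                      _["n_keys"] = (double)xp->table.size(),
                      _["n_entries"] = (double)xp->n_entries,
                      _["skipped_short"] = xp->skipped_short,
                      _["span"] = xp->pat.span,
                      _["weight"] = (int)xp->pat.care.size(),
                      _["step"] = xp->step);
}

// [[Rcpp::export]]
CharacterVector cpp_index_reads(SEXP xp_) {
  XPtr<SSIndex> xp(xp_);
  return wrap(xp->reads);
}

void scan_forward(const SSIndex& idx, const std::string& q,
                  std::vector<std::pair<int,int>>& out) {
  int n = (int)q.size() - idx.pat.span + 1;
  std::unordered_set<uint64_t> seen;
  for (int i = 0; i < n; ++i) {
    uint64_t key;
    if (!seed_key_at(q, i, idx.pat, key)) continue;
    auto it = idx.table.find(key);
    if (it == idx.table.end()) continue;
    for (uint32_t e : it->second) {
      int r = (int)(e >> 8), off = (int)(e & 0xff);
      int diag = i - off;  // read start in query coordinates
      uint64_t k = ((uint64_t)r << 24) | (uint32_t)(diag + (1 << 20));
      if (seen.insert(k).second) out.emplace_back(r, diag);
    }
  }
}

// Scan a query against the index; strand '-' rows report coordinates on the
// reverse-complemented query.
// [[Rcpp::export]]
DataFrame cpp_index_scan(SEXP xp_, std::string query, bool both_strands) {
  XPtr<SSIndex> xp(xp_);
  std::vector<int> id, diag;
  std::vector<std::string> strand;
  std::vector<std::pair<int,int>> fwd;
  scan_forward(*xp, query, fwd);
  for (auto& c : fwd) { id.push_back(c.first + 1); diag.push_back(c.second); strand.push_back("+"); }
  if (both_strands) {
    std::vector<std::pair<int,int>> rev;
    std::string qrc = revcomp(query);
    scan_forward(*xp, qrc, rev);
    for (auto& c : rev) { id.push_back(c.first + 1); diag.push_back(c.second); strand.push_back("-"); }
  }
  return DataFrame::create(_["sr_id"] = id, _["diagonal"] = diag,
                           _["strand"] = strand, _["stringsAsFactors"] = false);
}
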