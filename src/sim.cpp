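#include "ps_core.h"
using namespace Rcpp;

// Uniform substitution errors via R's RNG (caller controls the seed).
// Each base is substituted with probability `rate`, never to itself;
// returns mutated reads plus 0-based error offsets per read.
// [[Rcpp::export]]
List cpp_inject_errors(CharacterVector reads, double rate) {
  R_xlen_t n = reads.size();
  CharacterVector out(n);
  List pos(n);
  RNGScope scope;
  const char* bases = "ACGT";
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string s = as<std::string>(reads[r]);
    std::vector<int> p;
    for (size_t i = 0; i < s.size(); ++i) {
      if (unif_rand() < rate) {
        int code = base_code(s[i]);
        if (code < 0) continue;  // leave N untouched
        int shift = 1 + (int)(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        s[i] = bases[(code + shift) & 3];
        p.push_back((int)i);
      }
    }
    out[r] = s;
    pos[r] = IntegerVector(p.begin(), p.end());
  }
  return List::create(_["reads"] = out, _["positions"] = pos);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}
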