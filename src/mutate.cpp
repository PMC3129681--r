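// Apply planted point events to a sequence in one pass.
#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// pos: 0-based, sorted ascending, at most one event per position.
// type: 0 = substitution (replace with base), 1 = insertion (base inserted
// before position; pos == length appends), 2 = single-base deletion.
// [[Rcpp::export]]
std::string cpp_apply_mutations(std::string seq, IntegerVector pos,
                                IntegerVector type, CharacterVector base) {
  const int n = (int)seq.size();
  const int m = pos.size();
  std::string out;
  out.reserve(seq.size() + m);
  int pi = 0;
  for (int i = 0; i <= n; ++i) {
    while (pi < m && pos[pi] == i && type[pi] == 1) {
      out.push_back(CHAR(STRING_ELT(base, pi))[0]);
      ++pi;
    }
    if (i == n) break;
    if (pi < m && pos[pi] == i) {
      if (type[pi] == 0) {
        out.push_back(CHAR(STRING_ELT(base, pi))[0]);
        ++pi;
      } else if (type[pi] == 2) {
        ++pi;  // skip the base
      } else {
        out.push_back(seq[i]);
      }
    } else {
      out.push_back(seq[i]);
    }
  }
  return out;
}

// Membership mask of homopolymer runs of at least min_run bases.
// [[Rcpp::export]]
LogicalVector cpp_homopolymer_mask(std::string seq, int min_run) {
  const int n = (int)seq.size();
  LogicalVector out(n, false);
  int i = 0;
  while (i < n) {
    int j = i + 1;
    while (j < n && seq[j] == seq[i]) ++j;
    if (j - i >= min_run) {
      for (int x = i; x < j; ++x) out[x] = true;
    }
    i = j;
  }
  return out;
}
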