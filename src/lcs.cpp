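#include <Rcpp.h>
#include <array>
#include <string>
#include <vector>

using namespace Rcpp;

// Suffix automaton over the pattern; streaming each subject through it
// yields the exact longest common substring length in O(|subject|).
namespace {

inline int code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;  // N and anything else
  }
}

struct SuffixAutomaton {
  std::vector<std::array<int, 5>> nxt;
  std::vector<int> link, len;
  int last;

  explicit SuffixAutomaton(const std::string &s) {
    size_t cap = 2 * s.size() + 4;
    nxt.reserve(cap); link.reserve(cap); len.reserve(cap);
    nxt.push_back({{-1, -1, -1, -1, -1}});
    link.push_back(-1);
    len.push_back(0);
    last = 0;
    for (char ch : s) extend(code(ch));
  }

  void extend(int c) {
    int cur = static_cast<int>(nxt.size());
    nxt.push_back({{-1, -1, -1, -1, -1}});
    len.push_back(len[last] + 1);
    link.push_back(-1);
    int p = last;
    while (p != -1 && nxt[p][c] == -1) {
      nxt[p][c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = static_cast<int>(nxt.size());
        std::array<int, 5> qtrans = nxt[q];
        nxt.push_back(qtrans);
        len.push_back(len[p] + 1);
        link.push_back(link[q]);
        while (p != -1 && nxt[p][c] == q) {
          nxt[p][c] = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }

  int longest_common_with(const std::string &t) const {
    int v = 0, l = 0, best = 0;
    for (char ch : t) {
      int c = code(ch);
      while (v != 0 && nxt[v][c] == -1) {
        v = link[v];
        l = len[v];
      }
      if (nxt[v][c] != -1) {
        v = nxt[v][c];
        ++l;
      } else {
        v = 0;
        l = 0;
      }
      if (l > best) best = l;
    }
    return best;
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerVector lcs_lengths_cpp(std::string pattern, CharacterVector subjects) {
  SuffixAutomaton sam(pattern);
  R_xlen_t n = subjects.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string t = as<std::string>(subjects[i]);
    out[i] = sam.longest_common_with(t);
  }
  return out;
}
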