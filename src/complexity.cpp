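#include <Rcpp.h>
#include <string>
#include <vector>

// Distinct-substring counting via a suffix automaton. The number of distinct
// substrings of a string equals sum over automaton states of len(s) -
// len(link(s)); building the automaton is O(n) for a fixed alphabet, which
// keeps sliding-window complexity profiles tractable at kilobase scales.

namespace {

struct SuffixAutomaton {
  std::vector<int> len, link;
  std::vector<std::array<int, 4>> next;
  int last;

  explicit SuffixAutomaton(size_t reserve_n) {
    len.reserve(2 * reserve_n);
    link.reserve(2 * reserve_n);
    next.reserve(2 * reserve_n);
    len.push_back(0);
    link.push_back(-1);
    next.push_back({-1, -1, -1, -1});
    last = 0;
  }

  int new_state(int l) {
    len.push_back(l);
    link.push_back(-1);
    next.push_back({-1, -1, -1, -1});
    return static_cast<int>(len.size()) - 1;
  }

  void extend(int c) {
    int cur = new_state(len[last] + 1);
    int p = last;
    while (p != -1 && next[p][c] == -1) {
      next[p][c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = next[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = new_state(len[p] + 1);
        next[clone] = next[q];
        link[clone] = link[q];
        while (p != -1 && next[p][c] == q) {
          next[p][c] = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }

  double distinct_substrings() const {
    double total = 0.0;
    for (size_t s = 1; s < len.size(); ++s)
      total += len[s] - len[link[s]];
    return total;
  }
};

inline int base_code(char b) {
  switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

double distinct_count(const int* codes, int n) {
  SuffixAutomaton sa(static_cast<size_t>(n));
  for (int i = 0; i < n; ++i) sa.extend(codes[i]);
  return sa.distinct_substrings();
}

// Maximum possible number of distinct substrings: sum_k min(4^k, n-k+1).
double max_vocabulary(int n) {
  double total = 0.0, pow4 = 1.0;
  for (int k = 1; k <= n; ++k) {
    if (pow4 < 4e18) pow4 *= 4.0;
    double slots = static_cast<double>(n - k + 1);
    total += (pow4 < slots) ? pow4 : slots;
  }
  return total;
}

std::vector<int> encode_or_throw(const std::string& seq) {
  std::vector<int> codes(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) Rcpp::stop("sequence contains a non-ACGT character");
    codes[i] = c;
  }
  return codes;
}

}  // namespace

// [[Rcpp::export]]
double cpp_distinct_substrings(std::string seq) {
  if (seq.empty()) Rcpp::stop("empty sequence");
  std::vector<int> codes = encode_or_throw(seq);
  return distinct_count(codes.data(), static_cast<int>(codes.size()));
}

// [[Rcpp::export]]
double cpp_linguistic_complexity(std::string seq) {
  if (seq.empty()) Rcpp::stop("empty sequence");
  std::vector<int> codes = encode_or_throw(seq);
  int n = static_cast<int>(codes.size());
  return distinct_count(codes.data(), n) / max_vocabulary(n);
}

// L for every window of length W; NA where the window contains a non-ACGT
// base. Returns n - W + 1 values.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_lcomplexity_sliding(std::string seq, int W) {
  int n = static_cast<int>(seq.size());
  if (W < 1 || W > n) Rcpp::stop("window length out of range");
  std::vector<int> codes(n);
  for (int i = 0; i < n; ++i) codes[i] = base_code(seq[i]);
  double denom = max_vocabulary(W);
  Rcpp::NumericVector out(n - W + 1);
  for (int s = 0; s + W <= n; ++s) {
    bool ok = true;
    for (int i = s; i < s + W; ++i)
      if (codes[i] < 0) { ok = false; break; }
    out[s] = ok ? distinct_count(codes.data() + s, W) / denom : NA_REAL;
  }
  return out;
}
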