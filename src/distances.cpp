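#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <algorithm>

// Bit-parallel Levenshtein distance (blocked Myers / Hyyro algorithm).
// Pattern bitmasks are rebuilt per pattern; text is streamed one byte at a
// time.  Works for arbitrary lengths; bits above the pattern length in the
// last block are garbage but cannot contaminate lower bits (carries in the
// add propagate upward only).

namespace {

struct MyersPattern {
  int m;
  int W;
  std::vector<uint64_t> peq;  // 256 * W bitmasks

  void build(const char* p, int len) {
    m = len;
    W = (len + 63) / 64;
    peq.assign(256 * static_cast<size_t>(W), 0ULL);
    for (int i = 0; i < len; ++i) {
      unsigned char c = static_cast<unsigned char>(p[i]);
      peq[static_cast<size_t>(c) * W + (i >> 6)] |= 1ULL << (i & 63);
    }
  }
};

int myers_distance(const MyersPattern& pat, const char* t, int n,
                   std::vector<uint64_t>& VP, std::vector<uint64_t>& VN) {
  const int m = pat.m;
  if (m == 0) return n;
  if (n == 0) return m;
  const int W = pat.W;
  VP.assign(W, ~0ULL);
  VN.assign(W, 0ULL);
  const uint64_t score_bit = 1ULL << ((m - 1) & 63);
  const uint64_t top_bit = 1ULL << 63;
  int score = m;
  for (int j = 0; j < n; ++j) {
    const uint64_t* eqc =
        &pat.peq[static_cast<size_t>(static_cast<unsigned char>(t[j])) * W];
    int hin = 1;  // global distance: row 0 of the DP matrix is j, not 0
    for (int b = 0; b < W; ++b) {
      uint64_t pv = VP[b], mv = VN[b];
      uint64_t eq = eqc[b];
      const uint64_t xv = eq | mv;
      if (hin < 0) eq |= 1ULL;
      const uint64_t xh = (((eq & pv) + pv) ^ pv) | eq;
      uint64_t ph = mv | ~(xh | pv);
      uint64_t mh = pv & xh;
      if (b == W - 1) {
        if (ph & score_bit) ++score;
        else if (mh & score_bit) --score;
      }
      const int hout = (ph & top_bit) ? 1 : ((mh & top_bit) ? -1 : 0);
      ph <<= 1;
      mh <<= 1;
      if (hin < 0) mh |= 1ULL;
      else if (hin > 0) ph |= 1ULL;
      VP[b] = mh | ~(xv | ph);
      VN[b] = ph & xv;
      hin = hout;
    }
  }
  return score;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_lev_pair")]]
int cpp_lev_pair(std::string a, std::string b) {
  MyersPattern pat;
  pat.build(a.data(), static_cast<int>(a.size()));
  std::vector<uint64_t> VP, VN;
  return myers_distance(pat, b.data(), static_cast<int>(b.size()), VP, VN);
}

// All pairwise distances i < j, condensed ordering (1,2),(1,3),...,(n-1,n).
// [[Rcpp::export(name = ".cpp_lev_condensed")]]
Rcpp::IntegerVector cpp_lev_condensed(Rcpp::CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = Rcpp::as<std::string>(seqs[i]);
  Rcpp::IntegerVector out(static_cast<R_xlen_t>(n) * (n - 1) / 2);
  MyersPattern pat;
  std::vector<uint64_t> VP, VN;
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i) {
    pat.build(s[i].data(), static_cast<int>(s[i].size()));
    for (int j = i + 1; j < n; ++j) {
      out[k++] = myers_distance(pat, s[j].data(),
                                static_cast<int>(s[j].size()), VP, VN);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Rectangular distance matrix between two sequence sets.
// [[Rcpp::export(name = ".cpp_lev_matrix")]]
Rcpp::IntegerMatrix cpp_lev_matrix(Rcpp::CharacterVector a,
                                   Rcpp::CharacterVector b) {
  const int na = a.size(), nb = b.size();
  Rcpp::IntegerMatrix out(na, nb);
  MyersPattern pat;
  std::vector<uint64_t> VP, VN;
  for (int i = 0; i < na; ++i) {
    const std::string ai = Rcpp::as<std::string>(a[i]);
    pat.build(ai.data(), static_cast<int>(ai.size()));
    for (int j = 0; j < nb; ++j) {
      const std::string bj = Rcpp::as<std::string>(b[j]);
      out(i, j) = myers_distance(pat, bj.data(),
                                 static_cast<int>(bj.size()), VP, VN);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// k-th smallest distance from each sequence to the rest (multiset semantics:
// only the sequence's own position is excluded, duplicates elsewhere count).
// [[Rcpp::export(name = ".cpp_lev_kth_nn")]]
Rcpp::IntegerVector cpp_lev_kth_nn(Rcpp::CharacterVector seqs, int k) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = Rcpp::as<std::string>(seqs[i]);
  // full condensed distances, then per-row k-th order statistic
  std::vector<int> cond(static_cast<size_t>(n) * (n - 1) / 2);
  MyersPattern pat;
  std::vector<uint64_t> VP, VN;
  size_t kk = 0;
  for (int i = 0; i < n - 1; ++i) {
    pat.build(s[i].data(), static_cast<int>(s[i].size()));
    for (int j = i + 1; j < n; ++j)
      cond[kk++] = myers_distance(pat, s[j].data(),
                                  static_cast<int>(s[j].size()), VP, VN);
    Rcpp::checkUserInterrupt();
  }
  auto at = [&](int i, int j) -> int {
    if (i > j) std::swap(i, j);
    // index of (i,j), i<j, in condensed ordering
    return cond[static_cast<size_t>(i) * n - static_cast<size_t>(i) * (i + 1) / 2
                + (j - i - 1)];
  };
  Rcpp::IntegerVector out(n);
  std::vector<int> row(n - 1);
  for (int i = 0; i < n; ++i) {
    int idx = 0;
    for (int j = 0; j < n; ++j)
      if (j != i) row[idx++] = at(i, j);
    std::nth_element(row.begin(), row.begin() + (k - 1), row.end());
    out[i] = row[k - 1];
  }
  return out;
}

// k-th nearest-neighbor distance of selected query positions (0-based)
// against the full set, excluding each query's own position once.
// [[Rcpp::export(name = ".cpp_lev_nn_query")]]
Rcpp::IntegerVector cpp_lev_nn_query(Rcpp::IntegerVector idx0,
                                     Rcpp::CharacterVector seqs, int k) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = Rcpp::as<std::string>(seqs[i]);
  Rcpp::IntegerVector out(idx0.size());
  MyersPattern pat;
  std::vector<uint64_t> VP, VN;
  std::vector<int> row;
  row.reserve(n);
  for (int q = 0; q < idx0.size(); ++q) {
    const int i = idx0[q];
    pat.build(s[i].data(), static_cast<int>(s[i].size()));
    row.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      row.push_back(myers_distance(pat, s[j].data(),
                                   static_cast<int>(s[j].size()), VP, VN));
    }
    std::nth_element(row.begin(), row.begin() + (k - 1), row.end());
    out[q] = row[k - 1];
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Hamming distance; sequences must have equal length (checked in R).
// [[Rcpp::export(name = ".cpp_hamming_pair")]]
int cpp_hamming_pair(std::string a, std::string b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) d += (a[i] != b[i]);
  return d;
}

// [[Rcpp::export(name = ".cpp_hamming_condensed")]]
Rcpp::IntegerVector cpp_hamming_condensed(Rcpp::CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = Rcpp::as<std::string>(seqs[i]);
  Rcpp::IntegerVector out(static_cast<R_xlen_t>(n) * (n - 1) / 2);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = 0;
      const std::string &a = s[i], &b = s[j];
      for (size_t t = 0; t < a.size(); ++t) d += (a[t] != b[t]);
      out[k++] = d;
    }
  return out;
}
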