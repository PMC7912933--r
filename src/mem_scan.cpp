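#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Only A,C,G,T match themselves; N and IUPAC ambiguity codes never match,
// so runs of N break matches (exact-match semantics, no bridging).
static inline bool base_ok(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// All maximal exact matches of length >= k between a genome contig `g`
// (reference) and a probe `p` (query), forward orientation, 1-based
// inclusive coordinates. A match is reported once: seeds are the leftmost
// k-mer window of each match and must be left-maximal.
// [[Rcpp::export(name = ".mem_scan")]]
IntegerMatrix mem_scan(std::string g, std::string p, int k) {
  const int n = (int)g.size(), m = (int)p.size();
  std::vector<int> rs, re, qs, qe;
  if (k >= 1 && n >= k && m >= k) {
    std::unordered_multimap<std::string, int> idx;
    idx.reserve((size_t)n);
    // valid-run bookkeeping avoids O(n*k) rescans
    int run = 0;
    std::vector<char> valid_upto(n, 0); // 1 if k-mer starting at j is all-ACGT
    for (int j = n - 1; j >= 0; --j) {
      run = base_ok(g[j]) ? run + 1 : 0;
      if (run >= k) valid_upto[j] = 1;
    }
    for (int j = 0; j + k <= n; ++j)
      if (valid_upto[j]) idx.emplace(g.substr((size_t)j, (size_t)k), j);

    run = 0;
    std::vector<char> pvalid(m, 0);
    for (int i = m - 1; i >= 0; --i) {
      run = base_ok(p[i]) ? run + 1 : 0;
      if (run >= k) pvalid[i] = 1;
    }
    for (int i = 0; i + k <= m; ++i) {
      if (!pvalid[i]) continue;
      auto range = idx.equal_range(p.substr((size_t)i, (size_t)k));
      for (auto it = range.first; it != range.second; ++it) {
        int j = it->second;
        // left-maximality: previous bases must not match
        if (i > 0 && j > 0 && base_ok(p[i - 1]) && p[i - 1] == g[j - 1])
          continue;
        int l = k;
        while (i + l < m && j + l < n && base_ok(p[i + l]) &&
               p[i + l] == g[j + l])
          ++l;
        rs.push_back(j + 1);
        re.push_back(j + l);
        qs.push_back(i + 1);
        qe.push_back(i + l);
      }
    }
  }
  const int nm = (int)rs.size();
  IntegerMatrix out(nm, 5);
  for (int t = 0; t < nm; ++t) {
    out(t, 0) = rs[t];
    out(t, 1) = re[t];
    out(t, 2) = qs[t];
    out(t, 3) = qe[t];
    out(t, 4) = re[t] - rs[t] + 1;
  }
  colnames(out) = CharacterVector::create("ref_start", "ref_end", "qry_start",
                                          "qry_end", "length");
  return out;
}
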