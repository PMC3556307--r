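#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Maximal exact matches between two sequences via seeded anchors.
//
// A maximal exact match (MEM) is a maximal run of agreeing positions along
// one diagonal (i - j constant): extending one base left or right in both
// sequences simultaneously hits a mismatch, a non-ACGT letter, or a
// sequence end. Every MEM of length >= L contains a full L-mer anchor at
// its left end, so hashing all L-mers of `a` and scanning the L-mers of
// `b` finds each MEM exactly once: an anchor pair is kept only when it is
// the left end of its run (left characters differ, are non-ACGT, or a
// boundary). Candidate anchors are verified character by character, so hash
// collisions cannot create false matches. Runs near-linear on hard-masked
// genomes, where long shared seeds are rare outside genuine elements.

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export(name = ".find_mems_cpp")]]
IntegerMatrix find_mems_cpp(std::string a, std::string b, int min_len) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> sa, sb, sl;
  if (n < min_len || m < min_len || min_len < 1)
    return IntegerMatrix(0, 3);

  const uint64_t B = 1000003ULL;
  // rolling (prefix) hashes of all valid L-mers of a
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve((size_t)(n > min_len ? n - min_len + 1 : 1) * 2);
  {
    std::vector<uint64_t> pre(n + 1, 0);
    std::vector<int> run(n + 1, 0);
    for (int i = 0; i < n; ++i) {
      pre[i + 1] = pre[i] * B + (uint64_t)(unsigned char)a[i];
      run[i + 1] = is_base(a[i]) ? run[i] + 1 : 0;
    }
    std::vector<uint64_t> pw(min_len + 1, 1);
    for (int k = 1; k <= min_len; ++k) pw[k] = pw[k - 1] * B;
    for (int i = 0; i + min_len <= n; ++i) {
      if (run[i + min_len] < min_len) continue;  // window has a non-base
      uint64_t h = pre[i + min_len] - pre[i] * pw[min_len];
      index[h].push_back(i);
    }
  }

  std::vector<uint64_t> preb(m + 1, 0);
  std::vector<int> runb(m + 1, 0);
  for (int j = 0; j < m; ++j) {
    preb[j + 1] = preb[j] * B + (uint64_t)(unsigned char)b[j];
    runb[j + 1] = is_base(b[j]) ? runb[j] + 1 : 0;
  }
  uint64_t pwL = 1;
  for (int k = 0; k < min_len; ++k) pwL *= B;

  std::vector<int> ra, rb, rl;
  for (int j = 0; j + min_len <= m; ++j) {
    if (runb[j + min_len] < min_len) continue;
    uint64_t h = preb[j + min_len] - preb[j] * pwL;
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
      index.find(h);
    if (it == index.end()) continue;
    for (size_t t = 0; t < it->second.size(); ++t) {
      int i = it->second[t];
      // left-maximality: skip unless run starts here
      if (i > 0 && j > 0 && is_base(a[i - 1]) && a[i - 1] == b[j - 1]) continue;
      // verify anchor (guards against hash collisions)
      if (std::memcmp(a.data() + i, b.data() + j, (size_t)min_len) != 0)
        continue;
      // extend right maximally
      int len = min_len;
      while (i + len < n && j + len < m && is_base(a[i + len]) &&
             a[i + len] == b[j + len])
        ++len;
      ra.push_back(i); rb.push_back(j); rl.push_back(len);
    }
  }

  IntegerMatrix out((int)ra.size(), 3);
  for (int r = 0; r < (int)ra.size(); ++r) {
    out(r, 0) = ra[r]; out(r, 1) = rb[r]; out(r, 2) = rl[r];
  }
  return out;
}
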