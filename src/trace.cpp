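// Backward lineage tracing over a parent-pointer table.
//
// Records are in topological birth order (parent index < child index) and a
// child's generation is its parent's plus one, so the ancestors of a
// generation-gs sample, g generations back, all carry generation gs - g.

#include <Rcpp.h>
using namespace Rcpp;

// counts[g + 1] = number of distinct ancestors g generations back of all
// cells whose generation equals sampleGen; length sampleGen + 1.
// [[Rcpp::export(name = ".cppTraceCounts")]]
IntegerVector cppTraceCounts(IntegerVector parent, IntegerVector generation,
                             int sampleGen) {
  int n = parent.size();
  std::vector<int> cur;
  for (int i = 0; i < n; ++i)
    if (generation[i] == sampleGen) cur.push_back(i);
  if (cur.empty()) stop("no cells with generation %d in the genealogy", sampleGen);

  IntegerVector counts(sampleGen + 1);
  std::vector<char> seen(n, 0);
  std::vector<int> nxt;
  for (int g = 0; g <= sampleGen; ++g) {
    counts[g] = (int)cur.size();
    if (g == sampleGen) break;
    if (cur.size() == 1) {             // coalesced: single-lineage chain
      for (int gg = g + 1; gg <= sampleGen; ++gg) counts[gg] = 1;
      break;
    }
    nxt.clear();
    for (size_t i = 0; i < cur.size(); ++i) {
      int p = parent[cur[i]];
      if (p == NA_INTEGER)
        stop("record %d has no parent before the trace reached generation 0",
             cur[i] + 1);
      --p;                             // 1-based -> 0-based
      if (!seen[p]) { seen[p] = 1; nxt.push_back(p); }
    }
    for (size_t i = 0; i < nxt.size(); ++i) seen[nxt[i]] = 0;
    cur.swap(nxt);
  }
  return counts;
}
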