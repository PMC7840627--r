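#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right scan for runs of homozygosity over one chromosome's
// genotype calls (0/1/2/NA). A run starts and ends on a homozygous marker
// and tolerates at most maxHet heterozygous and maxMiss missing calls in
// between. Returns 1-based [start, end] marker indices plus the het/miss
// counts actually inside each run.
// [[Rcpp::export]]
IntegerMatrix rohRunsC(IntegerVector calls, int maxHet, int maxMiss) {
  int n = calls.size();
  std::vector<int> s, e, nhet, nmiss;
  int i = 0;
  while (i < n) {
    int gi = calls[i];
    bool hom = (gi != NA_INTEGER) && (gi == 0 || gi == 2);
    if (!hom) { ++i; continue; }
    int start = i, lastHom = i, hc = 0, mc = 0, j = i + 1;
    while (j < n) {
      int gj = calls[j];
      if (gj == NA_INTEGER) {
        if (mc < maxMiss) { ++mc; ++j; } else break;
      } else if (gj == 1) {
        if (hc < maxHet) { ++hc; ++j; } else break;
      } else {
        lastHom = j; ++j;
      }
    }
    int h = 0, m = 0;
    for (int k = start; k <= lastHom; ++k) {
      if (calls[k] == NA_INTEGER) ++m;
      else if (calls[k] == 1) ++h;
    }
    s.push_back(start + 1); e.push_back(lastHom + 1);
    nhet.push_back(h); nmiss.push_back(m);
    i = j;
  }
  IntegerMatrix out(s.size(), 4);
  for (size_t r = 0; r < s.size(); ++r) {
    out(r, 0) = s[r]; out(r, 1) = e[r]; out(r, 2) = nhet[r]; out(r, 3) = nmiss[r];
  }
  colnames(out) = CharacterVector::create("start", "end", "nHet", "nMiss");
  return out;
}
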