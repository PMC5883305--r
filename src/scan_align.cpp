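#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped scan of integer-encoded queries against a consensus
// acceptance table. accept is L x 4 (0/1): accept(p, b) says base b (0..3)
// matches consensus position p under the current bisulfite collapse.
// Queries are rows of q (codes 0..3, -1 for N / pad), true length qlen[i].
// Offsets run from -(qlen - min_overlap) to L - min_overlap; mismatches are
// counted over the overlap only, with early termination past max_mm.
// Returns per query: best mismatch count, best offset (0-based, may be
// negative), and the number of (offset) placements achieving the best count.
// [[Rcpp::export(name = ".scan_mode")]]
List scan_mode(IntegerMatrix q, IntegerVector qlen, IntegerMatrix accept,
               int max_mm, int min_overlap) {
  const int n = q.nrow();
  const int L = accept.nrow();
  IntegerVector best(n), best_off(n), n_best(n);
  for (int i = 0; i < n; ++i) {
    const int len = qlen[i];
    int bi = max_mm + 1, boff = 0, nb = 0;
    const int lo = -(len - min_overlap);
    const int hi = L - min_overlap;
    for (int off = lo; off <= hi; ++off) {
      const int p0 = off < 0 ? -off : 0;        // first query index in overlap
      const int p1 = (off + len > L ? L - off : len);  // one past last
      if (p1 - p0 < min_overlap) continue;
      int mm = 0;
      for (int p = p0; p < p1; ++p) {
        const int b = q(i, p);
        if (b < 0 || !accept(off + p, b)) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) {
        if (mm < bi) { bi = mm; boff = off; nb = 1; }
        else if (mm == bi) ++nb;
      }
    }
    best[i] = bi; best_off[i] = boff; n_best[i] = nb;
  }
  return List::create(_["mismatch"] = best, _["offset"] = best_off,
                      _["n_best"] = n_best);
}
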