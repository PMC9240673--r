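// Sliding-window ROH caller, compiled path for whole-cohort scans.
// Semantics mirror PLINK 1.9 --homozyg: per-SNP hit ratio over containing
// windows, runs split at large gaps, het/missing ends trimmed, segments
// tested on SNP count, length and density.
#include <Rcpp.h>
using namespace Rcpp;

// Flags for one sample on one chromosome.
static std::vector<bool> flags_one(const int* g, int L, int window_snp,
                                   int window_het, int window_missing,
                                   double threshold) {
  int w = std::min(window_snp, L);
  int n_win = L - w + 1;
  std::vector<int> ok(n_win + 1, 0); // prefix sums of window homozygosity
  int n_het = 0, n_mis = 0;
  for (int k = 0; k < w; ++k) {
    if (g[k] == NA_INTEGER) ++n_mis;
    else if (g[k] == 1) ++n_het;
  }
  for (int j = 0; j < n_win; ++j) {
    if (j > 0) {
      int out = g[j - 1], in = g[j + w - 1];
      if (out == NA_INTEGER) --n_mis; else if (out == 1) --n_het;
      if (in == NA_INTEGER) ++n_mis; else if (in == 1) ++n_het;
    }
    ok[j + 1] = ok[j] + ((n_het <= window_het && n_mis <= window_missing)
                         ? 1 : 0);
  }
  std::vector<bool> flags(L);
  for (int i = 0; i < L; ++i) {
    int lo = std::max(0, i - w + 1);
    int hi = std::min(n_win - 1, i);
    int tot = hi - lo + 1;
    int hits = ok[hi + 1] - ok[lo];
    flags[i] = (double)hits / tot >= threshold;
  }
  return flags;
}

// [[Rcpp::export]]
LogicalVector roh_flags_cpp(const IntegerVector& g, int window_snp,
                            int window_het, int window_missing,
                            double threshold) {
  std::vector<bool> f = flags_one(&g[0], g.size(), window_snp, window_het,
                                  window_missing, threshold);
  return LogicalVector(f.begin(), f.end());
}

// [[Rcpp::export]]
List roh_call_chrom_cpp(const IntegerMatrix& geno, // samples x SNPs
                        const NumericVector& pos,
                        int window_snp, int min_snp, double min_kb,
                        double max_gap_kb, double density_kb_per_snp,
                        int window_missing, int window_het,
                        double threshold) {
  const int n = geno.nrow(), L = geno.ncol();
  std::vector<int> out_sample, out_nsnp;
  std::vector<double> out_start, out_end;
  std::vector<int> gvec(L);

  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < L; ++j) gvec[j] = geno(s, j);
    std::vector<bool> flags = flags_one(gvec.data(), L, window_snp,
                                        window_het, window_missing,
                                        threshold);
    int i = 0;
    while (i < L) {
      if (!flags[i]) { ++i; continue; }
      int j = i;
      while (j + 1 < L && flags[j + 1]) ++j;
      // split run [i, j] at gaps > max_gap_kb, test each piece
      int piece_start = i;
      for (int k = i; k <= j; ++k) {
        bool close_piece = (k == j) ||
          (pos[k + 1] - pos[k] > max_gap_kb * 1000.0);
        if (!close_piece) continue;
        int a = piece_start, b = k;
        // trim het/missing ends
        while (a <= b && (gvec[a] == NA_INTEGER || gvec[a] == 1)) ++a;
        while (b >= a && (gvec[b] == NA_INTEGER || gvec[b] == 1)) --b;
        int nsnp = b - a + 1;
        if (nsnp >= min_snp) {
          double len = pos[b] - pos[a] + 1;
          if (len >= min_kb * 1000.0 &&
              (len / 1000.0) / nsnp <= density_kb_per_snp) {
            out_sample.push_back(s + 1);
            out_start.push_back(pos[a]);
            out_end.push_back(pos[b]);
            out_nsnp.push_back(nsnp);
          }
        }
        piece_start = k + 1;
      }
      i = j + 1;
    }
  }
  return List::create(_["sample"] = out_sample, _["start_bp"] = out_start,
                      _["end_bp"] = out_end, _["n_snps"] = out_nsnp);
}
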