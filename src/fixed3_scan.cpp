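#include <Rcpp.h>
using namespace Rcpp;

// Locate the 3'-fixed oligo in each read by a leftmost Hamming scan.
//
// At candidate start p (0-based) the probe is the first
// L = min(min_anchor, read_length - p) bases of fixed3. The mismatch
// allowance scales with the overlap, floor(max_mismatch * L / min_anchor),
// so short terminal overlaps must match exactly (same convention as
// overlap-scaled adapter trimming). Returns the 1-based start of the first
// accepted occurrence, or 0 when none is found.
// [[Rcpp::export]]
IntegerVector scan_fixed3_cpp(CharacterVector reads, std::string fixed3,
                              int max_mismatch, int min_anchor) {
  const int n = reads.size();
  const int flen = (int) fixed3.size();
  if (flen == 0) stop("fixed3 sequence must be non-empty");
  if (min_anchor < 1 || min_anchor > flen)
    stop("min_anchor must be in [1, nchar(fixed3)]");
  if (max_mismatch < 0) stop("max_mismatch must be >= 0");
  IntegerVector cut(n);
  for (int r = 0; r < n; ++r) {
    if (reads[r] == NA_STRING) { cut[r] = NA_INTEGER; continue; }
    const char *s = CHAR(STRING_ELT(reads, r));
    const int len = (int) strlen(s);
    int hit = 0;
    for (int p = 0; p < len; ++p) {
      int L = len - p;
      if (L > min_anchor) L = min_anchor;
      if (L > flen) L = flen;
      const int allow = (L >= min_anchor) ? max_mismatch
                                          : (max_mismatch * L) / min_anchor;
      int mm = 0;
      for (int j = 0; j < L; ++j) {
        if (s[p + j] != fixed3[j] && ++mm > allow) break;
      }
      if (mm <= allow) { hit = p + 1; break; }
    }
    cut[r] = hit;
  }
  return cut;
}
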