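#include <Rcpp.h>
using namespace Rcpp;

// Sliding ungapped Hamming scan of `query` along `subject` (both normalized
// lowercase RNA).  Returns a 2-column integer matrix: 0-based window start,
// mismatch count, for every window with distance <= max_mm.
// [[Rcpp::export(name = ".cpp_hamming_scan")]]
IntegerMatrix cpp_hamming_scan(std::string subject, std::string query,
                               int max_mm) {
  const int n = (int) subject.size(), m = (int) query.size();
  std::vector<int> starts, mms;
  for (int s = 0; s + m <= n; ++s) {
    int mm = 0;
    for (int p = 0; p < m; ++p) {
      if (subject[s + p] != query[p] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) { starts.push_back(s); mms.push_back(mm); }
  }
  IntegerMatrix out((int) starts.size(), 2);
  for (size_t i = 0; i < starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = mms[i];
  }
  return out;
}

static inline bool is_pair(char a, char b) {
  return (a == 'a' && b == 'u') || (a == 'u' && b == 'a') ||
         (a == 'g' && b == 'c') || (a == 'c' && b == 'g');
}
static inline bool is_wobble(char a, char b) {
  return (a == 'g' && b == 'u') || (a == 'u' && b == 'g');
}

// Complementarity scan of a miRNA against a transcript (sense strand).
// Duplex convention: miRNA position p (1-based from its 5' end) pairs the
// transcript base at window_end - p.  Counts Watson-Crick mismatches and
// G:U wobbles separately; reports windows with
// mismatches + wobble_weight * wobbles <= max_score.
// Columns: 0-based window start, mismatches, wobbles.
// [[Rcpp::export(name = ".cpp_target_scan")]]
IntegerMatrix cpp_target_scan(std::string subject, std::string mirna,
                              double max_score, double wobble_weight) {
  const int n = (int) subject.size(), m = (int) mirna.size();
  std::vector<int> starts, mms, wbs;
  for (int s = 0; s + m <= n; ++s) {
    int mm = 0, wb = 0;
    bool keep = true;
    for (int p = 0; p < m; ++p) {
      char mb = mirna[p];
      char tb = subject[s + m - 1 - p];
      if (is_pair(mb, tb)) continue;
      if (is_wobble(mb, tb)) ++wb; else ++mm;
      if (mm + wobble_weight * wb > max_score) { keep = false; break; }
    }
    if (keep) { starts.push_back(s); mms.push_back(mm); wbs.push_back(wb); }
  }
  IntegerMatrix out((int) starts.size(), 3);
  for (size_t i = 0; i < starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = mms[i];
    out(i, 2) = wbs[i];
  }
  return out;
}
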