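#include <Rcpp.h>
using namespace Rcpp;

// Ungapped end-to-end placement of a read at every offset of a reference.
// Returns c(start0, mismatches) for the best placement (fewest mismatches,
// leftmost on ties) if it needs <= max_mm mismatches, else an empty vector.
// [[Rcpp::export]]
IntegerVector cpp_best_match(std::string read, std::string ref, int max_mm) {
  const int n = read.size(), m = ref.size();
  if (n == 0) stop("empty read");
  if (n > m) return IntegerVector(0);
  int best_start = -1, best_mm = max_mm + 1;
  for (int s = 0; s + n <= m; ++s) {
    int mm = 0;
    for (int i = 0; i < n; ++i) {
      if (read[i] != ref[s + i]) {
        if (++mm >= best_mm) break;
      }
    }
    if (mm < best_mm) {
      best_mm = mm;
      best_start = s;
      if (best_mm == 0) break;
    }
  }
  if (best_start < 0) return IntegerVector(0);
  return IntegerVector::create(best_start, best_mm);
}

// Best hit of a read across a set of references. refs must be supplied in
// name order; ties are resolved by (mismatches, start, reference rank).
// Returns c(ref_index1, start0, mismatches) or an empty vector.
// [[Rcpp::export]]
IntegerVector cpp_best_match_set(std::string read, CharacterVector refs,
                                 int max_mm) {
  const int n = read.size();
  if (n == 0) stop("empty read");
  int best_ref = -1, best_start = -1, best_mm = max_mm + 1;
  for (int r = 0; r < refs.size(); ++r) {
    std::string ref = as<std::string>(refs[r]);
    const int m = ref.size();
    if (n > m) continue;
    for (int s = 0; s + n <= m; ++s) {
      // placements that cannot beat the current best are skipped early
      int mm = 0;
      bool viable = true;
      for (int i = 0; i < n; ++i) {
        if (read[i] != ref[s + i]) {
          if (++mm > best_mm) { viable = false; break; }
        }
      }
      if (!viable) continue;
      bool better = (mm < best_mm) ||
        (mm == best_mm && best_ref >= 0 && s < best_start);
      if (best_ref < 0 || better) {
        best_mm = mm;
        best_start = s;
        best_ref = r;
      }
    }
  }
  if (best_ref < 0 || best_mm > max_mm) return IntegerVector(0);
  return IntegerVector::create(best_ref + 1, best_start, best_mm);
}

// 3' adapter localisation for a vector of reads. The adapter may occur in
// full or as a prefix overlapping the read's 3' end by >= min_overlap bases;
// occurrences pass if mismatches / overlap <= max_mismatch_rate. Among
// passing occurrences the one with fewest mismatches wins, leftmost on ties.
// Returns the 0-based adapter start in each read, or -1 when absent.
// [[Rcpp::export]]
IntegerVector cpp_find_adapter(CharacterVector reads, std::string adapter,
                               int min_overlap, double max_mismatch_rate) {
  const int alen = adapter.size();
  if (alen == 0) stop("empty adapter");
  if (alen < min_overlap) stop("adapter shorter than min_overlap");
  IntegerVector out(reads.size());
  for (int k = 0; k < reads.size(); ++k) {
    std::string read = as<std::string>(reads[k]);
    const int rlen = read.size();
    if (rlen == 0) stop("empty read");
    int best_s = -1, best_mm = alen + 1;
    for (int s = 0; s <= rlen - min_overlap; ++s) {
      const int ov = std::min(alen, rlen - s);
      int mm = 0;
      for (int i = 0; i < ov; ++i)
        if (read[s + i] != adapter[i]) ++mm;
      if (mm <= max_mismatch_rate * ov && mm < best_mm) {
        best_mm = mm;
        best_s = s;
      }
    }
    out[k] = best_s;
  }
  return out;
}
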