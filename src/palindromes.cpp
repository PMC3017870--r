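#include <Rcpp.h>
using namespace Rcpp;

// Inverted-repeat (palindrome) candidate scan.
//
// A candidate is a pair of arms arm1 = [i, i+L), arm2 = [j, j+L) with
// arm2 equal to the reverse complement of arm1 up to max_mismatch
// substitutions, gap = j - (i + L) in [0, max_gap], and L in
// [min_arm, max_arm]. Along one antidiagonal (constant s = p + q) the arm
// pairs are the position pairs (p, s - p). Candidates are maximal: the
// innermost and outermost pairs match, the arm cannot be extended inward
// (to a matching pair with gap >= 0) nor outward (to a matching pair
// without exceeding max_mismatch or max_arm).
//
// seq_int: sequence coded 0=A,1=C,2=G,3=T,4=N (N never matches).
// Returns a matrix with columns: arm1_start, arm2_start, arm_len, gap,
// mismatches (all 0-based).
// [[Rcpp::export(name = ".palindrome_scan")]]
IntegerMatrix palindrome_scan(IntegerVector seq_int, int min_arm, int max_arm,
                              int max_gap, int max_mismatch) {
  const int n = seq_int.size();
  // complement codes; N (4) -> 4, and match(4, x) is always false
  static const int comp[5] = {3, 2, 1, 0, 4};
  std::vector<int> x(seq_int.begin(), seq_int.end());
  std::vector<int> res;  // flattened rows of 5

  auto match = [&](int p, int q) {
    return x[p] != 4 && x[q] != 4 && x[p] == comp[x[q]];
  };

  for (long s = 1; s <= 2L * n - 3; ++s) {
    // inner pair (p, s - p): gap = s - 2p - 1 in [0, max_gap]
    int p_hi = (int)((s - 1) / 2);
    long p_lo_l = (s - 1 - max_gap + 1) / 2;  // ceil((s-1-max_gap)/2)
    if ((s - 1 - max_gap) % 2 == 0) p_lo_l = (s - 1 - max_gap) / 2;
    int p_lo = (int)std::max(0L, p_lo_l);
    for (int p = p_hi; p >= p_lo; --p) {
      long q = s - p;
      if (q >= n) break;          // q grows as p shrinks: stop this diagonal
      if (!match(p, (int)q)) continue;
      // inward maximality: skip if the pair one step inward also matches
      int gap = (int)(s - 2L * p - 1);
      if (gap >= 2 && match(p + 1, (int)q - 1)) continue;
      // outward extension
      int mm = 0, last_good = 0, mm_at_good = 0;
      for (int k = 1;; ++k) {
        if (p - k < 0 || q + k >= n) break;
        if (k + 1 > max_arm) break;
        if (match(p - k, (int)q + k)) {
          last_good = k;
          mm_at_good = mm;
        } else {
          if (++mm > max_mismatch) break;
        }
      }
      int arm_len = last_good + 1;
      if (arm_len < min_arm) continue;
      res.push_back(p - last_good);      // arm1_start
      res.push_back((int)q);             // arm2_start
      res.push_back(arm_len);
      res.push_back(gap);
      res.push_back(mm_at_good);
    }
  }

  int nrow = (int)(res.size() / 5);
  IntegerMatrix out(nrow, 5);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < 5; ++j) out(i, j) = res[5 * i + j];
  colnames(out) = CharacterVector::create("arm1_start", "arm2_start",
                                          "arm_len", "gap", "mismatches");
  return out;
}
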