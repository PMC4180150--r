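#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment over a precomputed column-pair
// score matrix S (rows = columns of profile A, cols = columns of profile B),
// affine gaps. Returns the aligned column index vectors (0 = gap).
// [[Rcpp::export]]
List cpp_global_affine(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // three-state Gotoh: M, X (gap in B / consume A), Y (gap in A / consume B)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);
  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = gap_open + (i - 1) * gap_extend;
    tbX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = gap_open + (j - 1) * gap_extend;
    tbY(0, j) = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S(i - 1, j - 1);
      // M: diagonal from best of three
      double a = M(i - 1, j - 1), b = X(i - 1, j - 1), c = Y(i - 1, j - 1);
      int t = 0; double best = a;
      if (b > best) { best = b; t = 1; }
      if (c > best) { best = c; t = 2; }
      M(i, j) = best + s; tbM(i, j) = t;
      // X: gap in B (consume row i)
      double xo = M(i - 1, j) + gap_open, xe = X(i - 1, j) + gap_extend;
      if (xo >= xe) { X(i, j) = xo; tbX(i, j) = 0; }
      else          { X(i, j) = xe; tbX(i, j) = 1; }
      // Y: gap in A (consume col j)
      double yo = M(i, j - 1) + gap_open, ye = Y(i, j - 1) + gap_extend;
      if (yo >= ye) { Y(i, j) = yo; tbY(i, j) = 0; }
      else          { Y(i, j) = ye; tbY(i, j) = 2; }
    }
  }
  int state = 0; double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int t = tbM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j; state = t;
    } else if (state == 1) {
      int t = tbX(i, j);
      ai.push_back(i); bi.push_back(0);
      --i; state = (t == 1) ? 1 : 0;
    } else {
      int t = tbY(i, j);
      ai.push_back(0); bi.push_back(j);
      --j; state = (t == 2) ? 2 : 0;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best,
                      _["a_cols"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_cols"] = IntegerVector(bi.begin(), bi.end()));
}

// Frameshift-aware local alignment of a protein against a DNA fragment
// (single strand; caller handles reverse complement). dna: codes 0..3 = ACGT,
// 4 = other; prot: indices into the amino-acid alphabet of `blosum`;
// codon_aa: length-64 map (16*a+4*b+c) -> aa index; x_idx / stop_idx: alphabet
// indices of 'X' and '*'. Moves consume k nt per aa, k in {1,2,3,4,5}; k != 3
// is a frameshift with penalty fs_pen; gap_pen is a linear per-residue gap
// penalty (protein residue vs nothing, or silent codon).
// [[Rcpp::export]]
List cpp_translated_align(IntegerVector dna, IntegerVector prot,
                          NumericMatrix blosum, IntegerVector codon_aa,
                          int x_idx, int stop_idx,
                          double fs_pen, double gap_pen,
                          bool protein_global = false) {
  int n = dna.size(), m = prot.size();
  NumericMatrix D(n + 1, m + 1);
  IntegerMatrix TB(n + 1, m + 1);   // 0=stop, 1..5=codon move k, 6=del aa, 7=ins codon
  auto codon_of = [&](int i) -> int {   // codon ending at dna position i (1-based end)
    if (i < 3) return x_idx;
    int a = dna[i - 3], b = dna[i - 2], c = dna[i - 1];
    if (a > 3 || b > 3 || c > 3) return x_idx;
    return codon_aa[16 * a + 4 * b + c];
  };
  const double NEG = -1e30;
  double bestScore = protein_global ? NEG : 0;
  int bi = 0, bj = 0;
  for (int i = 0; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // local mode: free restart anywhere; protein-global: restart only at j=0
      double best = protein_global ? NEG : 0;
      int tb = 0;
      int pj = prot[j - 1];
      for (int k = 1; k <= 5; ++k) {
        if (i - k < 0) continue;
        int aa = (k >= 3) ? codon_of(i) : x_idx;
        double s = D(i - k, j - 1) + blosum(aa, pj) + (k == 3 ? 0.0 : fs_pen);
        if (s > best) { best = s; tb = k; }
      }
      double del = D(i, j - 1) + gap_pen;           // protein residue unmatched
      if (del > best) { best = del; tb = 6; }
      if (i >= 3) {
        double ins = D(i - 3, j) + gap_pen;         // silent codon in DNA
        if (ins > best) { best = ins; tb = 7; }
      }
      D(i, j) = best; TB(i, j) = tb;
      bool track = protein_global ? (j == m) : true;
      if (track && best > bestScore) { bestScore = best; bi = i; bj = j; }
    }
  }
  // traceback
  std::vector<int> fs_pos, stop_pos;
  int i = bi, j = bj;
  int dna_end = bi, prot_end = bj;
  int naligned = 0, nident = 0;
  while (i > 0 || j > 0) {
    int tb = TB(i, j);
    if (tb == 0) break;
    if (tb >= 1 && tb <= 5) {
      if (tb != 3) fs_pos.push_back(i - tb);        // 0-based lesion position
      if (tb >= 3) {
        int aa = codon_of(i);
        if (aa == stop_idx) stop_pos.push_back(i - 3);
        ++naligned;
        if (aa == prot[j - 1]) ++nident;
      } else ++naligned;
      i -= tb; --j;
    } else if (tb == 6) {
      --j;
    } else {
      int aa = codon_of(i);
      if (aa == stop_idx) stop_pos.push_back(i - 3);
      i -= 3;
    }
  }
  std::reverse(fs_pos.begin(), fs_pos.end());
  std::reverse(stop_pos.begin(), stop_pos.end());
  return List::create(
    _["score"] = bestScore,
    _["dna_start"] = i, _["dna_end"] = dna_end,
    _["prot_start"] = j, _["prot_end"] = prot_end,
    _["frameshifts"] = IntegerVector(fs_pos.begin(), fs_pos.end()),
    _["internal_stops"] = IntegerVector(stop_pos.begin(), stop_pos.end()),
    _["n_aligned"] = naligned, _["n_identical"] = nident);
}

static double max_segment(const std::vector<int>& agree, double penalty) {
  // penalty <= 0 means exact runs only (disagreement resets the segment)
  double best = 0, cur = 0;
  for (size_t i = 0; i < agree.size(); ++i) {
    if (agree[i]) cur += 1.0;
    else if (penalty <= 0) cur = 0;
    else { cur -= penalty; if (cur < 0) cur = 0; }
    if (cur > best) best = cur;
  }
  return best;
}

// Observed maximal fragment score and its permutation null for one sequence
// pair: `agree` is the 0/1 agreement vector over polymorphic columns.
// [[Rcpp::export]]
List cpp_fragment_null(IntegerVector agree, double penalty,
                       int n_perm, int seed) {
  std::vector<int> v(agree.begin(), agree.end());
  double obs = max_segment(v, penalty);
  std::mt19937 rng(static_cast<unsigned>(seed));
  NumericVector nullv(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    for (size_t i = v.size(); i > 1; --i) {
      std::uniform_int_distribution<size_t> u(0, i - 1);
      std::swap(v[i - 1], v[u(rng)]);
    }
    nullv[p] = max_segment(v, penalty);
  }
  return List::create(_["observed"] = obs, _["null"] = nullv);
}
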