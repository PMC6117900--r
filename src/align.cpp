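#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming aligners shared by the protein search, the
// progressive codon aligner and the read-vs-barcode aligner. Gap of length g
// costs gap_open + g * gap_ext (same convention as Biostrings).

// Banded local alignment score of read a against barcode b, restricted to
// diagonals (j - i) in [dlo, dhi]. Out-of-band cells act as fresh local
// starts (score 0), so the result is a lower bound of the unbanded score
// that is exact whenever the optimal path stays inside the band.
static double banded_local(const int* a, int na, const int* b, int nb,
                           int dlo, int dhi, const NumericMatrix& sm,
                           double gi, double ge) {
  const int A = sm.nrow();
  std::vector<double> H(nb + 2, 0.0), E(nb + 2, R_NegInf);
  double best = 0.0;
  int prev_end = 0; // rightmost j written in previous row
  for (int i = 1; i <= na; ++i) {
    int js = std::max(1, i + dlo), je = std::min(nb, i + dhi);
    if (js > je) continue;
    double diag = (js == 1) ? 0.0 : 0.0; // out-of-band or H[0]: both 0
    if (js > 1 && js - 1 <= prev_end) diag = H[js - 1];
    // cells right of prev_end were never written for row i-1
    double F = R_NegInf;
    const int ai = a[i - 1];
    for (int j = js; j <= je; ++j) {
      double hup = (j <= prev_end) ? H[j] : 0.0;   // H[i-1][j]
      double eup = (j <= prev_end) ? E[j] : R_NegInf;
      E[j] = std::max(hup - gi, eup - ge);
      double hleft = (j - 1 >= js) ? H[j - 1] : 0.0; // in-row, already updated
      F = std::max(hleft - gi, F - ge);
      const int bj = b[j - 1];
      double s = (ai >= 0 && ai < A && bj >= 0 && bj < A) ? sm(ai, bj) : -1e9;
      double h = diag + s;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0.0) h = 0.0;
      diag = hup;
      H[j] = h;
      if (h > best) best = h;
    }
    // clear the cell dropped from the band so it cannot leak later
    if (js >= 2) { H[js - 1] = 0.0; E[js - 1] = R_NegInf; }
    prev_end = je;
  }
  return best;
}

// Batch banded scores for candidate (read, barcode, diagonal range)
// triples. reads/barcodes are lists of integer code vectors; strand picks
// the precomputed orientation of the read.
// [[Rcpp::export]]
NumericVector cpp_candidate_scores(List reads_fwd, List reads_rc,
                                   List barcodes, IntegerVector read_idx,
                                   IntegerVector strand,
                                   IntegerVector bar_idx,
                                   IntegerVector dlo, IntegerVector dhi,
                                   NumericMatrix submat,
                                   double gap_open, double gap_ext) {
  const int n = read_idx.size();
  NumericVector out(n);
  const double gi = gap_open + gap_ext;
  for (int c = 0; c < n; ++c) {
    IntegerVector rv = (strand[c] == 1) ?
      as<IntegerVector>(reads_fwd[read_idx[c] - 1]) :
      as<IntegerVector>(reads_rc[read_idx[c] - 1]);
    IntegerVector bv = as<IntegerVector>(barcodes[bar_idx[c] - 1]);
    out[c] = banded_local(INTEGER(rv), rv.size(), INTEGER(bv), bv.size(),
                          dlo[c], dhi[c], submat, gi, gap_ext);
  }
  return out;
}

// Full DP with traceback on a precomputed pair-score matrix S (n x m).
// local = TRUE: Smith-Waterman, best local path; FALSE: Needleman-Wunsch with
// penalized end gaps. Returns the score and the aligned index paths
// (1-based; 0 marks a gap in that sequence).
// [[Rcpp::export]]
List cpp_align_matrix(NumericMatrix S, double gap_open, double gap_ext,
                      bool local) {
  const int n = S.nrow(), m = S.ncol();
  const double gi = gap_open + gap_ext;
  const double NEG = -1e18;
  // state matrices and traceback (flat vectors, row-major (m+1) stride)
  const size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<double> H_(sz), E_(sz), F_(sz);
  std::vector<unsigned char> TH_(sz), TE_(sz), TF_(sz);
  const int stride = m + 1;
  #define H(i, j) H_[(size_t)(i) * stride + (j)]
  #define E(i, j) E_[(size_t)(i) * stride + (j)]
  #define F(i, j) F_[(size_t)(i) * stride + (j)]
  #define TH(i, j) TH_[(size_t)(i) * stride + (j)]
  #define TE(i, j) TE_[(size_t)(i) * stride + (j)]
  #define TF(i, j) TF_[(size_t)(i) * stride + (j)]
  // TH: 0 stop, 1 diag, 2 from E (gap in A), 3 from F (gap in B)
  // TE/TF: 1 open (from H), 0 extend
  for (int j = 0; j <= m; ++j) {
    E(0, j) = NEG; F(0, j) = NEG;
    if (local) { H(0, j) = 0.0; TH(0, j) = 0; }
    else {
      H(0, j) = (j == 0) ? 0.0 : -(gap_open + j * gap_ext);
      TH(0, j) = (j == 0) ? 0 : 2;
    }
  }
  for (int i = 1; i <= n; ++i) {
    E(i, 0) = NEG; F(i, 0) = NEG;
    if (local) { H(i, 0) = 0.0; TH(i, 0) = 0; }
    else { H(i, 0) = -(gap_open + i * gap_ext); TH(i, 0) = 3; }
  }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eo = H(i, j - 1) - gi, ee = E(i, j - 1) - gap_ext;
      if (eo >= ee) { E(i, j) = eo; TE(i, j) = 1; } else { E(i, j) = ee; TE(i, j) = 0; }
      double fo = H(i - 1, j) - gi, fe = F(i - 1, j) - gap_ext;
      if (fo >= fe) { F(i, j) = fo; TF(i, j) = 1; } else { F(i, j) = fe; TF(i, j) = 0; }
      double d = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = d; int t = 1;
      if (E(i, j) > h) { h = E(i, j); t = 2; }
      if (F(i, j) > h) { h = F(i, j); t = 3; }
      if (local && h < 0.0) { h = 0.0; t = 0; }
      H(i, j) = h; TH(i, j) = t;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (!local) { best = H(n, m); bi = n; bj = m; }
  // traceback
  std::vector<int> pa, pb;
  int i = bi, j = bj, state = 0; // 0 = in H
  while (i > 0 || j > 0) {
    if (state == 0) {
      int t = TH(i, j);
      if (t == 0) break; // local stop
      if (t == 1) { pa.push_back(i); pb.push_back(j); --i; --j; }
      else if (t == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      pa.push_back(0); pb.push_back(j);
      if (TE(i, j) == 1) state = 0;
      --j;
    } else {
      pa.push_back(i); pb.push_back(0);
      if (TF(i, j) == 1) state = 0;
      --i;
    }
    if (local && state == 0 && (i == 0 || j == 0)) {
      if (TH(i, j) == 0) break;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  #undef H
  #undef E
  #undef F
  #undef TH
  #undef TE
  #undef TF
  return List::create(_["score"] = best,
                      _["a_idx"] = IntegerVector(pa.begin(), pa.end()),
                      _["b_idx"] = IntegerVector(pb.begin(), pb.end()));
}
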