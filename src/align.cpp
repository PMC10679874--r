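// Affine-gap local/global alignment (Gotoh) plus the spliced-leader
// suffix scanner. Sequences arrive as 0-based integer codes indexing the
// substitution matrix; code < 0 marks a masked position (score -inf) so
// iterative hit extraction can blank out previously reported regions.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e18;

static inline double subscore(const NumericMatrix& m, int a, int b) {
  if (a < 0 || b < 0) return -1e9;  // masked residue
  return m(a, b);
}

// Score-only Gotoh. Gap of length L costs gap_open + L * gap_extend.
// local = TRUE: Smith-Waterman best local score (>= 0);
// local = FALSE: Needleman-Wunsch global score.
// [[Rcpp::export]]
double gotoh_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                       double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  const int nrow = submat.nrow();
  const double gi = gap_open + gap_extend;
  const double* S = submat.begin();
  std::vector<int> boff(m);
  for (int j = 0; j < m; ++j) boff[j] = b[j] < 0 ? -1 : b[j] * nrow;
  std::vector<double> H(m + 1), E(m + 1);
  double best = 0.0;
  if (!local) {
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) H[j] = -(gap_open + gap_extend * j);
  } else {
    std::fill(H.begin(), H.end(), 0.0);
  }
  std::fill(E.begin(), E.end(), NEG);
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    double Hdiag = H[0];          // H[i-1][0]
    double F = NEG;               // gap in b (vertical)
    if (local) H[0] = 0.0; else H[0] = -(gap_open + gap_extend * i);
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - gap_extend, H[j] - gi);      // gap in a, from row i-1
      F    = std::max(F    - gap_extend, H[j - 1] - gi);  // gap in b, current row
      double h = Hdiag +
        ((ai < 0 || boff[j - 1] < 0) ? -1e9 : S[ai + boff[j - 1]]);
      Hdiag = H[j];
      h = std::max(h, std::max(E[j], F));
      if (local && h < 0.0) h = 0.0;
      H[j] = h;
      if (local && h > best) best = h;
    }
  }
  return local ? best : H[m];
}

// Full Gotoh with traceback via explicit direction matrices (no score
// re-derivation, so the reported path always realizes the reported score).
// Returns score, 0-based half-open ranges on a and b, and the two gapped
// alignment strings as integer codes (-1 = gap).
//
// Per-cell preference: diagonal (match/mismatch), then gap-in-b (consume
// a), then gap-in-a (consume b). Local mode: among co-optimal end cells
// (row-major scan, capped) each is traced back and the alignment with the
// smallest a-start, then smallest b-start, is kept.
// [[Rcpp::export]]
List gotoh_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                     double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  const int nrow = submat.nrow();
  const double* S = submat.begin();
  const double gi = gap_open + gap_extend;
  const size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<double> H(sz), E(sz), F(sz);
  // dirH: 0 = stop/local-start, 1 = diag, 2 = from E (vertical, consume a),
  //       3 = from F (horizontal, consume b)
  // dirE / dirF: 1 = opened from H, 0 = extension
  std::vector<unsigned char> dirH(sz, 0), dirE(sz, 0), dirF(sz, 0);
  const size_t M1 = m + 1;
  auto at = [M1](int i, int j) { return (size_t)i * M1 + j; };

  for (int j = 0; j <= m; ++j) {
    H[at(0, j)] = local ? 0.0 : -(gap_open + gap_extend * j);
    E[at(0, j)] = NEG; F[at(0, j)] = NEG;
    if (!local && j > 0) dirH[at(0, j)] = 3;
  }
  H[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    H[at(i, 0)] = local ? 0.0 : -(gap_open + gap_extend * i);
    E[at(i, 0)] = NEG; F[at(i, 0)] = NEG;
    if (!local) dirH[at(i, 0)] = 2;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t c = at(i, j), up = at(i - 1, j), lf = at(i, j - 1),
                   dg = at(i - 1, j - 1);
      double e_open = H[up] - gi, e_ext = E[up] - gap_extend;
      if (e_open >= e_ext) { E[c] = e_open; dirE[c] = 1; }
      else { E[c] = e_ext; dirE[c] = 0; }
      double f_open = H[lf] - gi, f_ext = F[lf] - gap_extend;
      if (f_open >= f_ext) { F[c] = f_open; dirF[c] = 1; }
      else { F[c] = f_ext; dirF[c] = 0; }
      const int bj = b[j - 1];
      double diag = H[dg] +
        ((ai < 0 || bj < 0) ? -1e9 : S[ai + bj * nrow]);
      double h = diag; unsigned char d = 1;
      if (E[c] > h) { h = E[c]; d = 2; }
      if (F[c] > h) { h = F[c]; d = 3; }
      if (local && h <= 0.0) { h = 0.0; d = 0; }
      H[c] = h; dirH[c] = d;
    }
  }

  double best;
  std::vector<std::pair<int, int> > ends;
  if (local) {
    best = 0.0;
    for (size_t c = 0; c < sz; ++c) if (H[c] > best) best = H[c];
    if (best > 0.0)
      for (int i = 1; i <= n && (int)ends.size() < 64; ++i)
        for (int j = 1; j <= m && (int)ends.size() < 64; ++j)
          if (H[at(i, j)] == best) ends.push_back(std::make_pair(i, j));
    if (ends.empty()) ends.push_back(std::make_pair(0, 0));
  } else {
    best = H[at(n, m)];
    ends.push_back(std::make_pair(n, m));
  }

  std::vector<int> best_aa, best_ab;
  int best_as = -1, best_bs = -1, best_ae = 0, best_be = 0;
  for (size_t e = 0; e < ends.size(); ++e) {
    int i = ends[e].first, j = ends[e].second;
    std::vector<int> aa, ab;
    int state = 0;  // 0 = H, 1 = E, 2 = F
    while (i > 0 || j > 0) {
      const size_t c = at(i, j);
      if (state == 0) {
        unsigned char d = dirH[c];
        if (d == 0) break;                       // local start
        if (d == 1) { aa.push_back(a[i - 1]); ab.push_back(b[j - 1]); --i; --j; }
        else if (d == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        aa.push_back(a[i - 1]); ab.push_back(-1);
        state = dirE[c] ? 0 : 1;
        --i;
      } else {
        aa.push_back(-1); ab.push_back(b[j - 1]);
        state = dirF[c] ? 0 : 2;
        --j;
      }
    }
    if (best_as < 0 || i < best_as || (i == best_as && j < best_bs)) {
      best_as = i; best_bs = j;
      best_ae = ends[e].first; best_be = ends[e].second;
      std::reverse(aa.begin(), aa.end());
      std::reverse(ab.begin(), ab.end());
      best_aa = aa; best_ab = ab;
    }
  }
  if (best_as < 0) { best_as = 0; best_bs = 0; }

  return List::create(
    _["score"] = best,
    _["a_start"] = best_as, _["a_end"] = best_ae,
    _["b_start"] = best_bs, _["b_end"] = best_be,
    _["a_aln"] = IntegerVector(best_aa.begin(), best_aa.end()),
    _["b_aln"] = IntegerVector(best_ab.begin(), best_ab.end()));
}

// Spliced-leader suffix scan: does a suffix (length >= min_match) of `sl`
// occur within the first `window` start offsets of the read with at most
// `max_mismatch` mismatches (no indels)? Longest qualifying suffix wins;
// ties broken by the smallest read offset.
// [[Rcpp::export]]
DataFrame sl_scan_cpp(CharacterVector reads, std::string sl,
                      int min_match, int max_mismatch, int window) {
  const int nr = reads.size(), ls = (int)sl.size();
  LogicalVector detected(nr);
  IntegerVector matched_len(nr), mismatches(nr), read_offset(nr);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int lr = (int)rd.size();
    int bl = -1, bo = -1, bm = -1;
    for (int len = ls; len >= min_match; --len) {
      for (int off = 0; off <= window; ++off) {
        if (off + len > lr) continue;
        int mm = 0;
        const char* s = sl.c_str() + (ls - len);
        const char* p = rd.c_str() + off;
        for (int k = 0; k < len && mm <= max_mismatch; ++k)
          if (s[k] != p[k]) ++mm;
        if (mm <= max_mismatch) { bl = len; bo = off; bm = mm; break; }
      }
      if (bl >= 0) break;
    }
    detected[r] = bl >= 0;
    matched_len[r] = bl >= 0 ? bl : 0;
    mismatches[r] = bl >= 0 ? bm : NA_INTEGER;
    read_offset[r] = bl >= 0 ? bo : NA_INTEGER;
  }
  return DataFrame::create(
    _["detected"] = detected, _["matched_len"] = matched_len,
    _["mismatches"] = mismatches, _["read_offset"] = read_offset,
    _["stringsAsFactors"] = false);
}
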