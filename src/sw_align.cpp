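#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
//
// Sequences arrive as 1-based integer indices into the substitution matrix.
// A gap of length k costs gap_open + k * gap_extend.  Traceback starts from
// the first (lowest i, then lowest j) maximal cell and breaks ties
// diagonal > up (gap in subject, consuming query) > left (gap in query).

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  const int m = q.size(), n = s.size();
  const int NEG = -1000000000;
  // H, E (gap in query: move left), F (gap in subject: move up)
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);
  std::vector<int> F((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int eh = H[at(i, j - 1)] - gap_open - gap_extend;
      int ee = E[at(i, j - 1)] - gap_extend;
      E[at(i, j)] = eh > ee ? eh : ee;
      int fh = H[at(i - 1, j)] - gap_open - gap_extend;
      int ff = F[at(i - 1, j)] - gap_extend;
      F[at(i, j)] = fh > ff ? fh : ff;
      int diag = H[at(i - 1, j - 1)] + sub(q[i - 1] - 1, s[j - 1] - 1);
      int h = 0;
      if (diag > h) h = diag;
      if (F[at(i, j)] > h) h = F[at(i, j)];
      if (E[at(i, j)] > h) h = E[at(i, j)];
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback
  int i = bi, j = bj;
  int identities = 0, alen = 0;
  int state = 0; // 0 = H, 1 = F (up), 2 = E (left)
  int qe = bi, se = bj; // 1-based inclusive ends
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H[at(i, j)];
      if (h == 0) break;
      int diag = H[at(i - 1, j - 1)] + sub(q[i - 1] - 1, s[j - 1] - 1);
      if (h == diag) {
        if (q[i - 1] == s[j - 1]) ++identities;
        ++alen; --i; --j;
      } else if (h == F[at(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // consuming query row i against a gap
      ++alen;
      int f = F[at(i, j)];
      if (f == H[at(i - 1, j)] - gap_open - gap_extend) state = 0;
      --i;
    } else {
      ++alen;
      int e = E[at(i, j)];
      if (e == H[at(i, j - 1)] - gap_open - gap_extend) state = 0;
      --j;
    }
  }
  int qs = i, ss = j; // 0-based starts of the local alignment

  return List::create(
    _["score"] = best,
    _["identities"] = identities,
    _["alignment_length"] = alen,
    _["query_start"] = qs, _["query_end"] = qe,
    _["subject_start"] = ss, _["subject_end"] = se);
}
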