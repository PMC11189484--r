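#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Wraparound local alignment of a read against an unbounded tandem
// repetition of a short motif, with iterative masked extraction of
// maximal-scoring segments.
//
// DP state: H[i][j] = best score of a local alignment ending at read
// position i (1-based) with motif phase j (the motif character consumed
// last). Transitions: diagonal (consume read base + motif char), up
// (insertion in the read), left (deletion of a motif char; cyclic within
// the row). The within-row cyclic dependency is resolved by re-sweeping
// the row until it is stable; with a strictly negative gap penalty a
// deletion chain never profitably wraps the full motif, so this converges
// in a handful of sweeps.
//
// Extraction: repeatedly take the best cell (ties: smallest read position,
// then smallest phase), trace back with the fixed preference
// diagonal > up > left until the score hits zero, record the candidate
// segment, mask its read interval, and recompute the rows at and after the
// masked interval. Stops when the best score drops below `stop_score`.
// Candidates are returned unfiltered; thresholding on span/identity and
// cross-form overlap resolution happen in R.

static inline int subst_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".wraparound_dp_candidates")]]
DataFrame wraparound_dp_candidates(std::string read, std::string motif,
                                   int match, int mismatch, int gap,
                                   int stop_score) {
  const int n = (int) read.size();
  const int k = (int) motif.size();
  std::vector<int> H((size_t)(n + 1) * k, 0);
  std::vector<char> masked(n, 0);
  std::vector<int> jm1(k);
  for (int j = 0; j < k; ++j) jm1[j] = (j + k - 1) % k;

  std::vector<int> c_start, c_end, c_score, c_matches, c_columns;

  if (n == 0 || k == 0) {
    return DataFrame::create(_["start"] = c_start, _["end"] = c_end,
                             _["score"] = c_score, _["matches"] = c_matches,
                             _["columns"] = c_columns);
  }

  // recompute DP rows [from_row, n]; row 0 is the all-zero boundary
  auto compute_rows = [&](int from_row) {
    for (int i = from_row; i <= n; ++i) {
      int *row = &H[(size_t)i * k];
      const int *prev = &H[(size_t)(i - 1) * k];
      if (masked[i - 1]) {
        for (int j = 0; j < k; ++j) row[j] = 0;
        continue;
      }
      char xi = read[i - 1];
      for (int j = 0; j < k; ++j) row[j] = 0;
      bool changed = true;
      int sweeps = 0;
      while (changed && sweeps < k + 2) {
        changed = false;
        ++sweeps;
        for (int j = 0; j < k; ++j) {
          int d = prev[jm1[j]] + subst_score(xi, motif[j], match, mismatch);
          int u = prev[j] + gap;
          int l = row[jm1[j]] + gap;
          int v = d;
          if (u > v) v = u;
          if (l > v) v = l;
          if (v < 0) v = 0;
          if (v > row[j]) { row[j] = v; changed = true; }
        }
      }
    }
  };

  compute_rows(1);

  for (;;) {
    int best = 0, bi = -1, bj = -1;
    for (int i = 1; i <= n; ++i) {
      const int *row = &H[(size_t)i * k];
      for (int j = 0; j < k; ++j) {
        if (row[j] > best) { best = row[j]; bi = i; bj = j; }
      }
    }
    if (best < stop_score || bi < 0) break;

    // traceback with preference diagonal > up > left
    int i = bi, j = bj;
    int matches = 0, columns = 0;
    int min_i = bi;
    while (H[(size_t)i * k + j] > 0) {
      int h = H[(size_t)i * k + j];
      int d = H[(size_t)(i - 1) * k + jm1[j]] +
              subst_score(read[i - 1], motif[j], match, mismatch);
      if (h == d) {
        ++columns;
        if (read[i - 1] != 'N' && read[i - 1] == motif[j]) ++matches;
        min_i = i;
        --i; j = jm1[j];
      } else if (h == H[(size_t)(i - 1) * k + j] + gap) {
        ++columns;
        min_i = i;
        --i;
      } else {
        ++columns;
        j = jm1[j];
      }
    }

    int start0 = min_i - 1;   // 0-based inclusive
    int end0 = bi;            // 0-based exclusive
    c_start.push_back(start0);
    c_end.push_back(end0);
    c_score.push_back(best);
    c_matches.push_back(matches);
    c_columns.push_back(columns);

    for (int p = start0; p < end0; ++p) masked[p] = 1;
    compute_rows(start0 + 1);
  }

  return DataFrame::create(_["start"] = c_start, _["end"] = c_end,
                           _["score"] = c_score, _["matches"] = c_matches,
                           _["columns"] = c_columns);
}
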