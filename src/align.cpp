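#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Unit-cost edit distance after leftmost alignment: the longer string is
// truncated to the length of the shorter before the DP runs.
// [[Rcpp::export]]
int nw_distance_cpp(const std::string& a, const std::string& b) {
  if (a.empty() || b.empty())
    stop("evolutionary distance requires two non-empty strings");
  const size_t L = std::min(a.size(), b.size());
  std::vector<int> prev(L + 1), cur(L + 1);
  for (size_t j = 0; j <= L; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= L; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= L; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[L];
}

struct SwHit {
  int score = 0, matches = 0, aln_len = 0;
  int qs = 0, qe = 0, ss = 0, se = 0;  // 0-based half-open spans
};

// Smith-Waterman, +1 match / -1 mismatch / -1 gap (linear). Among
// equal-scoring cells the first in row-major order wins, so the chosen
// alignment ends at the smallest query position, then the smallest
// subject position; the traceback prefers diagonal, then up, then left.
// That makes ties resolve to the leftmost alignment.
static SwHit sw_core(const std::string& q, const std::string& s) {
  const int n = (int)q.size(), m = (int)s.size();
  SwHit best;
  if (n == 0 || m == 0) return best;
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  const int W = m + 1;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = H[(size_t)(i - 1) * W + (j - 1)] + (qc == s[j - 1] ? 1 : -1);
      int u = H[(size_t)(i - 1) * W + j] - 1;
      int l = H[(size_t)i * W + (j - 1)] - 1;
      int v = std::max(0, std::max(d, std::max(u, l)));
      H[(size_t)i * W + j] = v;
      if (v > best.score) { best.score = v; bi = i; bj = j; }
    }
  }
  if (best.score <= 0) return SwHit();
  int i = bi, j = bj, matches = 0, alen = 0;
  while (i > 0 && j > 0 && H[(size_t)i * W + j] > 0) {
    const int v = H[(size_t)i * W + j];
    const bool eq = (q[i - 1] == s[j - 1]);
    if (v == H[(size_t)(i - 1) * W + (j - 1)] + (eq ? 1 : -1)) {
      if (eq) ++matches;
      --i; --j; ++alen;
    } else if (v == H[(size_t)(i - 1) * W + j] - 1) {
      --i; ++alen;
    } else {
      --j; ++alen;
    }
  }
  best.matches = matches; best.aln_len = alen;
  best.qs = i; best.qe = bi; best.ss = j; best.se = bj;
  return best;
}

static IntegerVector hit_to_vec(const SwHit& h) {
  return IntegerVector::create(
    _["score"] = h.score, _["matches"] = h.matches, _["aln_len"] = h.aln_len,
    _["query_start"] = h.qs, _["query_end"] = h.qe,
    _["subject_start"] = h.ss, _["subject_end"] = h.se);
}

// Best local alignment of query vs subject.
// [[Rcpp::export]]
IntegerVector sw_best_cpp(const std::string& query, const std::string& subject) {
  return hit_to_vec(sw_core(query, subject));
}

// All near-best local hits of query in subject, found by iterative
// masking: the subject span of each reported hit is overwritten with a
// sentinel before re-aligning. Stops when the score drops below
// rel_floor * best score, or after max_hits hits.
// [[Rcpp::export]]
DataFrame sw_hits_cpp(const std::string& query, std::string subject,
                      int max_hits = 8, double rel_floor = 0.75) {
  std::vector<SwHit> hits;
  int best0 = -1;
  for (int h = 0; h < max_hits; ++h) {
    SwHit hit = sw_core(query, subject);
    if (hit.score <= 0) break;
    if (best0 < 0) best0 = hit.score;
    if ((double)hit.score < rel_floor * best0) break;
    hits.push_back(hit);
    for (int j = hit.ss; j < hit.se; ++j) subject[j] = '#';
  }
  const int k = (int)hits.size();
  IntegerVector score(k), matches(k), aln_len(k), qs(k), qe(k), ss(k), se(k);
  NumericVector ident(k);
  for (int i = 0; i < k; ++i) {
    score[i] = hits[i].score; matches[i] = hits[i].matches;
    aln_len[i] = hits[i].aln_len;
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ss[i] = hits[i].ss; se[i] = hits[i].se;
    ident[i] = hits[i].aln_len > 0 ?
      100.0 * hits[i].matches / hits[i].aln_len : 0.0;
  }
  return DataFrame::create(
    _["score"] = score, _["matches"] = matches, _["aln_len"] = aln_len,
    _["identity_pct"] = ident,
    _["query_start"] = qs, _["query_end"] = qe,
    _["subject_start"] = ss, _["subject_end"] = se);
}
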