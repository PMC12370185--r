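#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Overlap search for pair merging. s2 must already be reverse-complemented.
// The shift s is the 0-based offset of s2's first base relative to s1's
// first base; all shifts with at least one overlapping column are scored as
// matches - mismatches. Best = max score, ties -> longer overlap, then
// smaller shift. Deterministic.
// [[Rcpp::export]]
List cpp_best_overlap(std::string s1, std::string s2) {
  int n1 = s1.size(), n2 = s2.size();
  int best_score = INT_MIN, best_ov = -1, best_shift = 0, best_diffs = 0;
  for (int s = -(n2 - 1); s <= n1 - 1; ++s) {
    int lo = std::max(0, s);           // overlap start in s1 coords
    int hi = std::min(n1, s + n2);     // overlap end (exclusive)
    int ov = hi - lo;
    if (ov < 1) continue;
    int match = 0, diff = 0;
    for (int i = lo; i < hi; ++i) {
      if (s1[i] == s2[i - s]) ++match; else ++diff;
    }
    int score = match - diff;
    if (score > best_score ||
        (score == best_score && (ov > best_ov ||
                                 (ov == best_ov && s < best_shift)))) {
      best_score = score;
      best_ov = ov;
      best_shift = s;
      best_diffs = diff;
    }
  }
  return List::create(_["shift"] = best_shift, _["overlap_len"] = best_ov,
                      _["n_diffs"] = best_diffs, _["score"] = best_score);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (auto &c : out) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: stop("non-ACGT character in sequence");
    }
  }
  return out;
}

// Assemble the merged read given the chosen shift (1-based start of s2 in
// s1 coordinates). Consensus base = higher quality (s1 on ties); consensus
// quality = max of the two.
// [[Rcpp::export]]
List cpp_merge_consensus(std::string s1, IntegerVector q1, std::string s2,
                         IntegerVector q2, int s) {
  int n1 = s1.size(), n2 = s2.size();
  int lo = std::min(1, s), hi = std::max(n1, s + n2 - 1);
  std::string seq;
  seq.reserve(hi - lo + 1);
  IntegerVector quals(hi - lo + 1);
  int k = 0;
  for (int p = lo; p <= hi; ++p, ++k) {
    bool in1 = p >= 1 && p <= n1;
    int j = p - s + 1;
    bool in2 = j >= 1 && j <= n2;
    if (in1 && in2) {
      seq.push_back(q1[p - 1] >= q2[j - 1] ? s1[p - 1] : s2[j - 1]);
      quals[k] = std::max(q1[p - 1], q2[j - 1]);
    } else if (in1) {
      seq.push_back(s1[p - 1]);
      quals[k] = q1[p - 1];
    } else {
      seq.push_back(s2[j - 1]);
      quals[k] = q2[j - 1];
    }
  }
  return List::create(_["seq"] = seq, _["quals"] = quals);
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming: unequal lengths");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}

// Semi-global alignment: the read is aligned end to end, the reference has
// free end gaps (leading/trailing reference bases cost nothing and are not
// alignment columns). Linear gap penalty, deliberately strong (-10): merged
// reads are substitution-dominated, and a weak penalty would let an indel
// pair re-align a substitution next to a repeat and nudge identity across
// the acceptance threshold. Identity downstream is matches / alignment
// columns, gap columns counting against identity.
// Traceback preference on score ties: diagonal, then up (read base vs gap),
// then left (reference base vs gap), for determinism.
// [[Rcpp::export]]
List cpp_semiglobal(std::string read, std::string ref,
                    int match = 1, int mismatch = -1, int gap = -10) {
  int n = read.size(), m = ref.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int> D((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) D[at(0, j)] = 0;       // free ref prefix
  for (int i = 1; i <= n; ++i) D[at(i, 0)] = i * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = D[at(i - 1, j - 1)] +
        (read[i - 1] == ref[j - 1] ? match : mismatch);
      int up = D[at(i - 1, j)] + gap;
      int left = D[at(i, j - 1)] + gap;
      int v = sub;
      if (up > v) v = up;
      if (left > v) v = left;
      D[at(i, j)] = v;
    }
  }
  int best_j = m;                                     // free ref suffix
  for (int j = m; j >= 0; --j) {
    if (D[at(n, j)] > D[at(n, best_j)]) best_j = j;
  }
  // traceback
  int i = n, j = best_j, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    if (i == 0) break;                                // free ref prefix
    if (j > 0 &&
        D[at(i, j)] == D[at(i - 1, j - 1)] +
          (read[i - 1] == ref[j - 1] ? match : mismatch)) {
      if (read[i - 1] == ref[j - 1]) ++matches;
      --i; --j; ++cols;
    } else if (D[at(i, j)] == D[at(i - 1, j)] + gap) {
      --i; ++cols;
    } else {
      --j; ++cols;
    }
  }
  return List::create(_["matches"] = matches, _["aln_cols"] = cols,
                      _["ref_start"] = j + 1, _["ref_end"] = best_j,
                      _["score"] = D[at(n, best_j)]);
}

// Cheap ungapped screen: best matches/readlen over all full placements of
// the shorter sequence within the longer. Used only to shortlist references
// before the semi-global decision alignment.
// [[Rcpp::export]]
double cpp_ungapped_screen(std::string read, std::string ref) {
  const std::string &a = read.size() <= ref.size() ? read : ref;
  const std::string &b = read.size() <= ref.size() ? ref : read;
  int na = a.size(), nb = b.size();
  int best = 0;
  for (int s = 0; s + na <= nb; ++s) {
    int match = 0;
    for (int i = 0; i < na; ++i) if (a[i] == b[s + i]) ++match;
    if (match > best) best = match;
  }
  return (double)best / (double)read.size();
}
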