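// Contig end extension: candidate reads are re-aligned to a contig and the
// soft-clipped overhangs reaching past the contig ends vote, column by
// column, on an extension. Extension proceeds while the column depth stays
// at or above min_depth; the process repeats until stable. Reads never
// extend past the end of the transcript region they were drawn from, so
// extension is self-limiting.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
#include <algorithm>

using namespace Rcpp;

std::string revcomp_str(const std::string& s);

// from aligner.cpp internals, re-exposed via the R-callable entry point
SEXP align_read_cpp(std::string read, std::string ref,
                    int match, int mismatch, int gap_open, int gap_extend,
                    int band, int clip, int seed_len, int min_score);

namespace {
inline int b2i(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1;
  case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}
}

// [[Rcpp::export(name = ".extend_contig_cpp")]]
std::string extend_contig_cpp(std::string contig, CharacterVector reads,
                              int match, int mismatch, int gap_open,
                              int gap_extend, int band, int clip,
                              int seed_len, int min_score,
                              int min_depth, int max_iter) {
  const int nr = reads.size();
  std::vector<std::string> rs(nr);
  for (int i = 0; i < nr; ++i) rs[i] = as<std::string>(reads[i]);

  // after the first pass, only reads that were unaligned or end-clipped
  // can influence a further extension
  std::vector<char> consider(nr, 1);
  for (int iter = 0; iter < max_iter; ++iter) {
    const int L = (int)contig.size();
    // votes for columns left of 0 (index = -1 - col) and right of L-1
    std::vector<std::array<int, 4>> lv, rv;
    for (int i = 0; i < nr; ++i) {
      if (!consider[i]) continue;
      SEXP h = align_read_cpp(rs[i], contig, match, mismatch, gap_open,
                              gap_extend, band, clip, seed_len, min_score);
      if (h == R_NilValue) continue;
      List hl(h);
      const int ref_start = as<int>(hl["ref_start"]);
      const std::string cig = as<std::string>(hl["cigar"]);
      const std::string strand = as<std::string>(hl["strand"]);
      std::string oriented = (strand == "-") ? revcomp_str(rs[i]) : rs[i];
      // decode leading/trailing clip and reference-consuming length
      std::vector<std::pair<int, char>> ops;
      int num = 0;
      for (char c : cig) {
        if (c >= '0' && c <= '9') { num = num * 10 + (c - '0'); continue; }
        ops.emplace_back(num, c);
        num = 0;
      }
      int lead = 0, trail = 0, reflen = 0;
      if (!ops.empty() && ops.front().second == 'S') lead = ops.front().first;
      if (ops.size() > 1 && ops.back().second == 'S') trail = ops.back().first;
      for (auto& op : ops)
        if (op.second == 'M' || op.second == 'D') reflen += op.first;
      if (lead == 0 && trail == 0) consider[i] = 0;
      // left overhang: clipped base t (1..lead) sits at column ref_start - t
      for (int t = 1; t <= lead; ++t) {
        int col = ref_start - t;
        if (col >= 0) continue;
        size_t slot = (size_t)(-1 - col);
        if (slot >= lv.size()) lv.resize(slot + 1, {0, 0, 0, 0});
        int b = b2i(oriented[lead - t]);
        if (b >= 0) lv[slot][b]++;
      }
      // right overhang: clipped base t (1..trail) at column ref_end-1+t
      const int ref_end = ref_start + reflen;  // exclusive
      for (int t = 1; t <= trail; ++t) {
        int col = ref_end - 1 + t;
        if (col < L) continue;
        size_t slot = (size_t)(col - L);
        if (slot >= rv.size()) rv.resize(slot + 1, {0, 0, 0, 0});
        int b = b2i(oriented[(int)oriented.size() - trail - 1 + t]);
        if (b >= 0) rv[slot][b]++;
      }
    }
    static const char B[4] = {'A', 'C', 'G', 'T'};
    std::string left, right;
    for (size_t s = 0; s < lv.size(); ++s) {
      int tot = lv[s][0] + lv[s][1] + lv[s][2] + lv[s][3];
      if (tot < min_depth) break;
      int bi = 0;
      for (int b = 1; b < 4; ++b) if (lv[s][b] > lv[s][bi]) bi = b;
      left.push_back(B[bi]);  // built outward; reverse below
    }
    for (size_t s = 0; s < rv.size(); ++s) {
      int tot = rv[s][0] + rv[s][1] + rv[s][2] + rv[s][3];
      if (tot < min_depth) break;
      int bi = 0;
      for (int b = 1; b < 4; ++b) if (rv[s][b] > rv[s][bi]) bi = b;
      right.push_back(B[bi]);
    }
    if (left.empty() && right.empty()) break;
    std::reverse(left.begin(), left.end());
    contig = left + contig + right;
  }
  return contig;
}
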