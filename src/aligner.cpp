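// Seed-and-extend banded local alignment of short reads against short
// allele references, with affine gaps and a flat per-end soft-clip charge.
//
// Scoring model (shared by the heuristic and the full-DP oracle):
//   maximise  match*A - mismatch*B - sum(gap_open + k*gap_extend)
//             - clip * [read prefix clipped] - clip * [read suffix clipped]
// Reference prefix/suffix skipping is free (local in the reference).

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = INT32_MIN / 4;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    case 'N': c = 'N'; break;
    default: break;
    }
  }
  return r;
}

struct AlnParams {
  int match, mismatch, gap_open, gap_extend, band, clip, seed_len, min_score;
};

struct AlnHit {
  bool ok = false;
  int score = NEG_INF;
  int ref_start = 0;   // 0-based
  int read_start = 0;  // 0-based offset of first aligned read base
  int read_end = 0;    // 0-based exclusive
  int edit_distance = 0;
  std::string cigar;
};

// k-mer index of a reference sequence
struct KmerIndex {
  int k = 0;
  std::unordered_map<uint64_t, std::vector<int>> pos;
  void build(const std::string& ref, int k_) {
    k = k_;
    pos.clear();
    int n = (int)ref.size();
    if (n < k) return;
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int valid = 0;
    for (int j = 0; j < n; ++j) {
      int b = base2bits(ref[j]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++valid >= k) pos[key].push_back(j - k + 1);
    }
  }
};

// reusable DP workspace (single-threaded R session)
struct DpWork {
  std::vector<int> Mprev, Bprev, Fprev, Mcur, Bcur, Fcur;
  std::vector<uint8_t> tb;
};
static DpWork g_work;

// Banded DP over diagonals d = j - i (0-based) in [lo, hi].
// score_only skips traceback bookkeeping (used to pick the best
// window/strand before a single traceback pass).
// Returns best hit within the window, or ok=false.
static AlnHit banded_dp(const std::string& read, const std::string& ref,
                        const AlnParams& p, int lo, int hi,
                        bool score_only = false) {
  const int m = (int)read.size(), n = (int)ref.size();
  lo = std::max(lo, -(m - 1));
  hi = std::min(hi, n - 1);
  AlnHit out;
  if (lo > hi) return out;
  const int W = hi - lo + 1;
  // traceback codes: bits 0-1 source of M (0 fresh, 1 M, 2 E, 3 F);
  // bit 2: E extends E; bit 3: F extends F
  DpWork& w = g_work;
  // padded by one sentinel column on each side so c-1 / c+1 never branch
  const int WP = W + 2;
  if ((int)w.Mprev.size() < WP) {
    w.Mprev.resize(WP); w.Bprev.resize(WP); w.Fprev.resize(WP);
    w.Mcur.resize(WP); w.Bcur.resize(WP); w.Fcur.resize(WP);
  }
  std::vector<uint8_t>& tb = w.tb;
  if (!score_only && (int)tb.size() < m * W) tb.resize((size_t)m * W);
  int* Mprev = w.Mprev.data();
  int* Bprev = w.Bprev.data();
  int* Fprev = w.Fprev.data();
  int* Mcur = w.Mcur.data();
  int* Bcur = w.Bcur.data();
  int* Fcur = w.Fcur.data();
  std::fill(Mprev, Mprev + WP, NEG_INF);
  std::fill(Bprev, Bprev + WP, NEG_INF);
  std::fill(Fprev, Fprev + WP, NEG_INF);
  int best = NEG_INF, best_i = -1, best_c = -1;
  const int go_ge = p.gap_open + p.gap_extend;
  const int ge = p.gap_extend;

  for (int i = 0; i < m; ++i) {
    Mcur[0] = Bcur[0] = Fcur[0] = NEG_INF;
    const int jmin = std::max(0, i + lo), jmax = std::min(n - 1, i + hi);
    int cmin = jmin - i - lo, cmax = jmax - i - lo;
    if (jmin > jmax) { cmin = W; cmax = -1; }   // row outside the reference
    cmin = std::min(std::max(cmin, 0), W);
    cmax = std::min(cmax, W - 1);
    for (int c = 0; c < cmin; ++c) {
      Mcur[c + 1] = Bcur[c + 1] = Fcur[c + 1] = NEG_INF;
    }
    for (int c = cmax + 1; c < W; ++c) {
      Mcur[c + 1] = Bcur[c + 1] = Fcur[c + 1] = NEG_INF;
    }
    Mcur[W + 1] = Bcur[W + 1] = Fcur[W + 1] = NEG_INF;
    int E = NEG_INF;          // E(i, j-1) chain within the row
    const int start_val = (i == 0) ? 0 : -p.clip;
    const char ri = read[i];
    const int end_pen = (i == m - 1) ? 0 : -p.clip;
    if (score_only) {
      // two passes: the first has no intra-row dependency (vectorizable),
      // the second carries the deletion-state chain
      const char* refrow = ref.data() + i + lo;
      for (int c = cmin; c <= cmax; ++c) {
        const int sub = (ri == refrow[c]) ? p.match : -p.mismatch;
        const int bp = Bprev[c + 1];
        Mcur[c + 1] = (bp > start_val ? bp : start_val) + sub;
        const int Fopen = Mprev[c + 2] - go_ge;
        const int Fext = Fprev[c + 2] - ge;
        Fcur[c + 1] = Fopen > Fext ? Fopen : Fext;
      }
      for (int c = cmin; c <= cmax; ++c) {
        const int Eopen = Mcur[c] - go_ge;
        const int Eext = E - ge;
        E = Eopen > Eext ? Eopen : Eext;
        const int M = Mcur[c + 1];
        int B = M > E ? M : E;
        const int F = Fcur[c + 1];
        Bcur[c + 1] = B > F ? B : F;
        const int endv = M + end_pen;
        if (endv > best) { best = endv; best_i = i; best_c = c; }
      }
      std::swap(w.Mprev, w.Mcur);
      std::swap(w.Bprev, w.Bcur);
      std::swap(w.Fprev, w.Fcur);
      Mprev = w.Mprev.data(); Bprev = w.Bprev.data(); Fprev = w.Fprev.data();
      Mcur = w.Mcur.data(); Bcur = w.Bcur.data(); Fcur = w.Fcur.data();
      continue;
    }
    uint8_t* tbrow = &tb[(size_t)i * W];
    for (int c = cmin; c <= cmax; ++c) {
      const int j = i + c + lo;
      const int sub = (ri == ref[j]) ? p.match : -p.mismatch;
      const int bp = Bprev[c + 1];   // Best(i-1, j-1), same band column
      const int M = (bp > start_val ? bp : start_val) + sub;
      const int Eopen = Mcur[c] - go_ge;       // from (i, j-1) = col c-1
      const int Eext = E - ge;
      const int Enew = Eopen > Eext ? Eopen : Eext;
      const int Fopen = Mprev[c + 2] - go_ge;  // from (i-1, j) = col c+1
      const int Fext = Fprev[c + 2] - ge;
      const int F = Fopen > Fext ? Fopen : Fext;
      if (!score_only) {
        uint8_t code;
        if (bp <= start_val) code = 0;
        else if (bp == Mprev[c + 1]) code = 1;
        else if (bp == Fprev[c + 1]) code = 3;
        else code = 2;
        if (Eext > Eopen) code |= 4;
        if (Fext > Fopen) code |= 8;
        tbrow[c] = code;
      }
      E = Enew;
      Mcur[c + 1] = M;
      Fcur[c + 1] = F;
      int B = M > Enew ? M : Enew;
      Bcur[c + 1] = B > F ? B : F;
      const int endv = M + end_pen;
      if (endv > best) { best = endv; best_i = i; best_c = c; }
    }
    std::swap(w.Mprev, w.Mcur);
    std::swap(w.Bprev, w.Bcur);
    std::swap(w.Fprev, w.Fcur);
    Mprev = w.Mprev.data(); Bprev = w.Bprev.data(); Fprev = w.Fprev.data();
    Mcur = w.Mcur.data(); Bcur = w.Bcur.data(); Fcur = w.Fcur.data();
  }
  if (best_i < 0) return out;
  if (score_only) {
    out.ok = true;
    out.score = best;
    out.ref_start = best_i;       // best end cell, for the caller's
    out.read_start = best_c + lo; // gap-free reconstruction attempt
    return out;
  }

  // traceback
  int i = best_i, c = best_c;
  std::string ops;  // reversed stream of 'M','I','D'
  int mism = 0, ins = 0, del = 0;
  int state = 1;  // 1=M, 2=E, 3=F
  while (true) {
    uint8_t code = tb[(size_t)i * W + c];
    int j = i + c + lo;
    if (state == 1) {
      ops.push_back('M');
      if (read[i] != ref[j]) ++mism;
      int src = code & 3;
      if (src == 0) break;        // fresh start at (i, j)
      state = src;                 // move diagonally
      --i;                         // c unchanged on diagonal move
      if (i < 0) break;            // safety
    } else if (state == 2) {       // E consumed ref j as deletion
      ops.push_back('D');
      ++del;
      bool ext = (code & 4) != 0;
      --c;                         // to (i, j-1)
      state = ext ? 2 : 1;
    } else {                       // F consumed read i as insertion
      ops.push_back('I');
      ++ins;
      bool ext = (code & 8) != 0;
      --i;
      ++c;                         // to (i-1, j)
      state = ext ? 3 : 1;
    }
  }
  std::reverse(ops.begin(), ops.end());
  int i0 = i, j0 = i + c + lo;
  // compress ops into cigar with soft clips
  std::string cig;
  const int m_all = (int)read.size();
  auto addop = [&cig](int len, char op) {
    if (len > 0) cig += std::to_string(len) + op;
  };
  addop(i0, 'S');
  int runlen = 0; char runop = 0;
  for (char o : ops) {
    if (o == runop) ++runlen;
    else { addop(runlen, runop ? runop : 'M'); runop = o; runlen = 1; }
  }
  if (runlen > 0) addop(runlen, runop);
  addop(m_all - 1 - best_i, 'S');

  out.ok = true;
  out.score = best;
  out.ref_start = j0;
  out.read_start = i0;
  out.read_end = best_i + 1;
  out.edit_distance = mism + ins + del;
  out.cigar = cig;
  return out;
}

// One orientation: seed, merge diagonal windows, extend.
static AlnHit align_one_orient(const std::string& read, const std::string& ref,
                               const KmerIndex& idx, const AlnParams& p) {
  AlnHit best;
  const int m = (int)read.size(), n = (int)ref.size();
  if (m < p.seed_len || n < p.seed_len) return best;
  // collect seed diagonals
  std::vector<int> diags;
  uint64_t key = 0, mask = (p.seed_len < 32) ? ((1ULL << (2 * p.seed_len)) - 1) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < m; ++i) {
    int b = base2bits(read[i]);
    if (b < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++valid >= p.seed_len) {
      auto it = idx.pos.find(key);
      if (it != idx.pos.end()) {
        int rpos = i - p.seed_len + 1;
        for (int q : it->second) diags.push_back(q - rpos);
      }
    }
  }
  if (diags.empty()) return best;
  std::sort(diags.begin(), diags.end());
  diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
  // fast path: a full-length exact match attains the maximal possible
  // score; the smallest such diagonal also satisfies the tie rule
  for (int d : diags) {
    if (d < 0 || d + m > n) continue;
    if (std::memcmp(read.data(), ref.data() + d, m) == 0) {
      best.ok = true;
      best.score = m * p.match;
      best.ref_start = d;
      best.read_start = 0;
      best.read_end = m;
      best.edit_distance = 0;
      best.cigar = std::to_string(m) + "M";
      return best;
    }
  }
  // merge [d-band, d+band] windows
  std::vector<std::pair<int, int>> wins;
  for (int d : diags) {
    int lo = d - p.band, hi = d + p.band;
    if (!wins.empty() && lo <= wins.back().second + 1)
      wins.back().second = std::max(wins.back().second, hi);
    else
      wins.emplace_back(lo, hi);
  }
  // score-only pass to find the best window(s); traceback only for those
  std::vector<AlnHit> hs(wins.size());
  int smax = NEG_INF;
  for (size_t k = 0; k < wins.size(); ++k) {
    hs[k] = banded_dp(read, ref, p, wins[k].first, wins[k].second, true);
    if (hs[k].ok && hs[k].score > smax) smax = hs[k].score;
  }
  if (smax <= NEG_INF / 2) return best;
  for (size_t k = 0; k < wins.size(); ++k) {
    if (!hs[k].ok || hs[k].score != smax) continue;
    const AlnHit& h = hs[k];
    // gap-free reconstruction along the best end cell's diagonal: if an
    // ungapped sub-alignment ending there attains the DP optimum (the
    // typical case), the cigar follows without a traceback pass
    {
      const int ei = h.ref_start;          // end read position
      const int d = h.read_start;          // end diagonal
      bool done = false;
      if (d >= 0 || ei + d >= 0) {
        const int i0 = std::max(0, -d);    // first read pos on diagonal
        const int end_pen = (ei == m - 1) ? 0 : -p.clip;
        int run = 0, bestsum = NEG_INF, bests = -1, mmrun = 0, bestmm = 0;
        // scan backwards from ei for the best start (smallest on ties)
        int sum = 0, mm = 0;
        for (int s = ei; s >= i0; --s) {
          const int j = s + d;
          if (j >= n) { break; }
          if (read[s] == ref[j]) sum += p.match;
          else { sum -= p.mismatch; ++mm; }
          const int tot = sum + (s == 0 ? 0 : -p.clip) + end_pen;
          if (tot >= bestsum) { bestsum = tot; bests = s; bestmm = mm; }
        }
        (void)run; (void)mmrun;
        if (bests >= 0 && bestsum == h.score) {
          AlnHit g;
          g.ok = true;
          g.score = h.score;
          g.ref_start = bests + d;
          g.read_start = bests;
          g.read_end = ei + 1;
          g.edit_distance = bestmm;
          std::string cig;
          if (bests > 0) cig += std::to_string(bests) + "S";
          cig += std::to_string(ei - bests + 1) + "M";
          if (ei < m - 1) cig += std::to_string(m - 1 - ei) + "S";
          g.cigar = cig;
          if (!best.ok || g.score > best.score ||
              (g.score == best.score && g.ref_start < best.ref_start))
            best = g;
          done = true;
        }
      }
      if (done) continue;
    }
    AlnHit hf = banded_dp(read, ref, p, wins[k].first, wins[k].second, false);
    if (hf.ok && (!best.ok || hf.score > best.score ||
                  (hf.score == best.score && hf.ref_start < best.ref_start)))
      best = hf;
  }
  return best;
}

struct StrandedHit {
  AlnHit hit;
  bool reverse = false;
};

// Both strands; ties: smaller ref_start, then forward strand.
static StrandedHit align_both(const std::string& read, const std::string& ref,
                              const KmerIndex& idx, const AlnParams& p) {
  StrandedHit out;
  AlnHit f = align_one_orient(read, ref, idx, p);
  AlnHit r = align_one_orient(revcomp_str(read), ref, idx, p);
  bool fo = f.ok && f.score >= p.min_score;
  bool ro = r.ok && r.score >= p.min_score;
  if (!fo && !ro) return out;
  if (fo && (!ro || f.score > r.score ||
             (f.score == r.score && f.ref_start <= r.ref_start))) {
    out.hit = f; out.reverse = false;
  } else {
    out.hit = r; out.reverse = true;
  }
  return out;
}

static List hit_to_list(const StrandedHit& sh) {
  return List::create(
    _["score"] = sh.hit.score,
    _["ref_start"] = sh.hit.ref_start,
    _["cigar"] = sh.hit.cigar,
    _["strand"] = sh.reverse ? "-" : "+",
    _["edit_distance"] = sh.hit.edit_distance,
    _["read_start"] = sh.hit.read_start,
    _["read_end"] = sh.hit.read_end);
}

// [[Rcpp::export(name = ".align_read_cpp")]]
SEXP align_read_cpp(std::string read, std::string ref,
                    int match, int mismatch, int gap_open, int gap_extend,
                    int band, int clip, int seed_len, int min_score) {
  AlnParams p{match, mismatch, gap_open, gap_extend, band, clip, seed_len, min_score};
  if ((int)ref.size() < seed_len || (int)read.size() < seed_len) return R_NilValue;
  KmerIndex idx;
  idx.build(ref, seed_len);
  StrandedHit sh = align_both(read, ref, idx, p);
  if (!sh.hit.ok) return R_NilValue;
  return hit_to_list(sh);
}

// Independent oracle: full unbanded DP, same scoring, score only.
// Deliberately a plain O(m*n) triple-state matrix recurrence with no seeding,
// banding or traceback, kept separate from the heuristic path.
// [[Rcpp::export(name = ".sw_clip_oracle_cpp")]]
int sw_clip_oracle_cpp(std::string read, std::string ref,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int clip) {
  const int m = (int)read.size(), n = (int)ref.size();
  std::vector<std::vector<int>> M(m + 1, std::vector<int>(n + 1, NEG_INF));
  std::vector<std::vector<int>> E(m + 1, std::vector<int>(n + 1, NEG_INF));
  std::vector<std::vector<int>> F(m + 1, std::vector<int>(n + 1, NEG_INF));
  int best = NEG_INF;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int sub = (read[i - 1] == ref[j - 1]) ? match : -mismatch;
      int start_val = (i == 1) ? 0 : -clip;
      int prev = std::max(std::max(M[i - 1][j - 1], E[i - 1][j - 1]), F[i - 1][j - 1]);
      M[i][j] = sub + std::max(start_val, prev);
      E[i][j] = std::max(M[i][j - 1] - gap_open - gap_extend,
                         E[i][j - 1] == NEG_INF ? NEG_INF : E[i][j - 1] - gap_extend);
      F[i][j] = std::max(M[i - 1][j] - gap_open - gap_extend,
                         F[i - 1][j] == NEG_INF ? NEG_INF : F[i - 1][j] - gap_extend);
      int endv = M[i][j] + ((i == m) ? 0 : -clip);
      if (endv > best) best = endv;
    }
  }
  return best;
}

// Paired-end mapping engine: every pair against every allele, proper-pair
// detection, pair scoring with an unpaired penalty, and emission of records
// for every allele tying the maximal pair score.
// [[Rcpp::export(name = ".map_pairs_cpp")]]
DataFrame map_pairs_cpp(CharacterVector r1, CharacterVector r2,
                        CharacterVector alleles,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int band, int clip, int seed_len, int min_score,
                        int unpaired_penalty, int max_frag,
                        bool emit_all = false) {
  AlnParams p{match, mismatch, gap_open, gap_extend, band, clip, seed_len, min_score};
  const int na = alleles.size(), np = r1.size();
  std::vector<std::string> refs(na);
  std::vector<KmerIndex> idx(na);
  for (int a = 0; a < na; ++a) {
    refs[a] = as<std::string>(alleles[a]);
    idx[a].build(refs[a], p.seed_len);
  }
  // memoised per-allele alignment of a read sequence (both strands resolved)
  std::vector<std::unordered_map<std::string, StrandedHit>> cache(na);
  auto get = [&](const std::string& s, int a) -> const StrandedHit& {
    auto it = cache[a].find(s);
    if (it != cache[a].end()) return it->second;
    StrandedHit sh;
    if ((int)refs[a].size() >= p.seed_len && (int)s.size() >= p.seed_len)
      sh = align_both(s, refs[a], idx[a], p);
    return cache[a].emplace(s, sh).first->second;
  };

  std::vector<int> o_pair, o_mate, o_allele, o_start, o_score, o_nm, o_pscore;
  std::vector<std::string> o_cigar;
  std::vector<bool> o_rev, o_proper;

  std::vector<int> pscore(na);
  std::vector<bool> proper(na);
  for (int i = 0; i < np; ++i) {
    const std::string s1 = as<std::string>(r1[i]);
    const std::string s2 = as<std::string>(r2[i]);
    const int minfrag = std::max((int)s1.size(), (int)s2.size());
    int best = NEG_INF;
    for (int a = 0; a < na; ++a) {
      const StrandedHit& h1 = get(s1, a);
      const StrandedHit& h2 = get(s2, a);
      int sc = NEG_INF;
      bool prop = false;
      if (h1.hit.ok && h2.hit.ok) {
        int lo = std::min(h1.hit.ref_start, h2.hit.ref_start);
        int e1 = h1.hit.ref_start + (h1.hit.read_end - h1.hit.read_start); // approx ref span
        // reference-consuming length from cigar is exact; recompute:
        // (read_end-read_start) differs from ref span only by indels; use cigar walk
        int hi_end = 0;
        for (const StrandedHit* h : {&h1, &h2}) {
          int len = 0, num = 0;
          for (char c : h->hit.cigar) {
            if (c >= '0' && c <= '9') num = num * 10 + (c - '0');
            else {
              if (c == 'M' || c == 'D') len += num;
              num = 0;
            }
          }
          hi_end = std::max(hi_end, h->hit.ref_start + len);
        }
        (void)e1;
        int frag = hi_end - lo;
        prop = (h1.reverse != h2.reverse) && frag >= minfrag && frag <= max_frag;
        sc = h1.hit.score + h2.hit.score - (prop ? 0 : unpaired_penalty);
      } else if (h1.hit.ok || h2.hit.ok) {
        sc = (h1.hit.ok ? h1.hit.score : h2.hit.score) - unpaired_penalty;
      }
      pscore[a] = sc;
      proper[a] = prop;
      if (sc > best) best = sc;
    }
    if (best <= NEG_INF / 2) continue;
    for (int a = 0; a < na; ++a) {
      if (emit_all ? (pscore[a] <= NEG_INF / 2) : (pscore[a] != best)) continue;
      const StrandedHit& h1 = get(s1, a);
      const StrandedHit& h2 = get(s2, a);
      for (int mate = 1; mate <= 2; ++mate) {
        const StrandedHit& h = (mate == 1) ? h1 : h2;
        if (!h.hit.ok) continue;
        o_pair.push_back(i + 1);
        o_mate.push_back(mate);
        o_allele.push_back(a + 1);
        o_start.push_back(h.hit.ref_start);
        o_cigar.push_back(h.hit.cigar);
        o_score.push_back(h.hit.score);
        o_rev.push_back(h.reverse);
        o_proper.push_back(proper[a]);
        o_nm.push_back(h.hit.edit_distance);
        o_pscore.push_back(pscore[a]);
      }
    }
  }
  return DataFrame::create(
    _["pair"] = o_pair, _["mate"] = o_mate, _["allele"] = o_allele,
    _["ref_start"] = o_start, _["cigar"] = o_cigar, _["score"] = o_score,
    _["reverse"] = LogicalVector(o_rev.begin(), o_rev.end()),
    _["proper_pair"] = LogicalVector(o_proper.begin(), o_proper.end()),
    _["edit_distance"] = o_nm, _["pair_score"] = o_pscore,
    _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".cigar_lens_cpp")]]
List cigar_lens_cpp(CharacterVector cigar) {
  const R_xlen_t n = cigar.size();
  IntegerVector reflen(n), readlen(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(cigar, i));
    int num = 0, rf = 0, rd = 0;
    for (; *s; ++s) {
      if (*s >= '0' && *s <= '9') { num = num * 10 + (*s - '0'); continue; }
      switch (*s) {
      case 'M': rf += num; rd += num; break;
      case 'D': rf += num; break;
      case 'I': case 'S': rd += num; break;
      default: break;
      }
      num = 0;
    }
    reflen[i] = rf;
    readlen[i] = rd;
  }
  return List::create(_["ref_len"] = reflen, _["read_len"] = readlen);
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}

// Per-position tallies from cigar walks. Sequences must be passed in
// reference orientation (reverse-strand reads already complemented).
// Returns a 5 x L count matrix (A, C, G, T, del), the number of inserted
// bases, and the total of tallied aligned bases.
// [[Rcpp::export(name = ".pileup_cpp")]]
List pileup_cpp(int ref_len, IntegerVector ref_start, CharacterVector cigar,
                CharacterVector oriented_seq) {
  IntegerMatrix counts(5, ref_len);
  long ins_bases = 0, tallied = 0;
  const int nrec = ref_start.size();
  for (int r = 0; r < nrec; ++r) {
    const std::string cig = as<std::string>(cigar[r]);
    const std::string seq = as<std::string>(oriented_seq[r]);
    int rp = ref_start[r];       // 0-based ref cursor
    size_t qp = 0;               // read cursor
    int num = 0;
    for (char c : cig) {
      if (c >= '0' && c <= '9') { num = num * 10 + (c - '0'); continue; }
      if (c == 'S') { qp += num; }
      else if (c == 'M') {
        for (int t = 0; t < num; ++t, ++rp, ++qp) {
          if (rp < 0 || rp >= ref_len || qp >= seq.size()) continue;
          int b = base2bits(seq[qp]);
          if (b >= 0) { counts(b, rp) += 1; ++tallied; }
        }
      } else if (c == 'D') {
        for (int t = 0; t < num; ++t, ++rp)
          if (rp >= 0 && rp < ref_len) counts(4, rp) += 1;
      } else if (c == 'I') { qp += num; ins_bases += num; }
      num = 0;
    }
  }
  return List::create(_["counts"] = counts,
                      _["ins_bases"] = (double)ins_bases,
                      _["tallied_bases"] = (double)tallied);
}
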