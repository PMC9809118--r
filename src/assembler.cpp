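// Greedy overlap-layout-consensus micro-assembly of candidate read subsets.
//
// All pairwise read overlaps (both orientations) are found via a shared
// k-mer index, evaluated ungapped at the k-mer-implied diagonal, gated on
// length / identity / score, then merged best-first into layouts. A merge
// joining two multi-read layouts must also agree at >= the identity gate
// over the full implied consensus overlap (this is what keeps reads from
// two co-extracted alleles in separate contigs). Consensus is per-column
// majority; a final polish drops reads below the identity gate against
// their own consensus.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

std::string revcomp_str(const std::string& s);  // from aligner.cpp

namespace {

struct Member {
  int read;     // index into reads
  int offset;   // placement of oriented read in unit frame
  int strand;   // 0 forward, 1 reverse-complemented
};

struct Unit {
  std::vector<Member> members;
  std::string consensus;
  std::vector<int> depth;  // per consensus column
  std::vector<int> cnt;    // 4 x span base counts, incrementally maintained
  int cons_off = 0;        // frame coordinate of consensus[0]
  bool dirty = true;
};

struct Overlap {
  int i, j;      // read indices, i < j by id order handled via sort keys
  int orient;    // orientation of j relative to i-forward
  int diag;      // offset of oriented j in i-forward coordinates
  int ov_len;
  int score;
};

inline char maj_base(const int* cnt) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  int bi = -1, bc = 0;
  for (int b = 0; b < 4; ++b)
    if (cnt[b] > bc) { bc = cnt[b]; bi = b; }
  return bi < 0 ? 'N' : B[bi];
}

// refresh consensus/depth strings from the count matrix
void refresh_from_counts(Unit& u) {
  const int span = (int)u.cnt.size() / 4;
  u.consensus.assign(span, 'N');
  u.depth.assign(span, 0);
  for (int p = 0; p < span; ++p) {
    u.consensus[p] = maj_base(&u.cnt[(size_t)p * 4]);
    u.depth[p] = u.cnt[(size_t)p * 4] + u.cnt[(size_t)p * 4 + 1] +
                 u.cnt[(size_t)p * 4 + 2] + u.cnt[(size_t)p * 4 + 3];
  }
  u.dirty = false;
}

void add_to_counts(Unit& u, const Member& m,
                   const std::vector<std::string>& oriented) {
  const std::string& s = oriented[2 * m.read + m.strand];
  const int lo = u.cons_off, span = (int)u.cnt.size() / 4;
  for (size_t t = 0; t < s.size(); ++t) {
    int b;
    switch (s[t]) {
    case 'A': b = 0; break; case 'C': b = 1; break;
    case 'G': b = 2; break; case 'T': b = 3; break;
    default: continue;
    }
    int p = m.offset - lo + (int)t;
    if (p >= 0 && p < span) u.cnt[(size_t)p * 4 + b]++;
  }
}

void rebuild_consensus(Unit& u, const std::vector<std::string>& oriented) {
  int lo = INT32_MAX, hi = INT32_MIN;
  for (const Member& m : u.members) {
    lo = std::min(lo, m.offset);
    hi = std::max(hi, m.offset + (int)oriented[2 * m.read + m.strand].size());
  }
  const int span = hi - lo;
  u.cnt.assign((size_t)span * 4, 0);
  u.cons_off = lo;
  for (const Member& m : u.members) add_to_counts(u, m, oriented);
  refresh_from_counts(u);
}

// grow the count matrix so frame interval [lo, hi) is covered
void grow_counts(Unit& u, int lo, int hi) {
  int cur_lo = u.cons_off, cur_hi = u.cons_off + (int)u.cnt.size() / 4;
  if (lo >= cur_lo && hi <= cur_hi) return;
  int new_lo = std::min(lo, cur_lo), new_hi = std::max(hi, cur_hi);
  std::vector<int> nc((size_t)(new_hi - new_lo) * 4, 0);
  std::copy(u.cnt.begin(), u.cnt.end(),
            nc.begin() + (size_t)(cur_lo - new_lo) * 4);
  u.cnt = std::move(nc);
  u.cons_off = new_lo;
}

}  // namespace

// [[Rcpp::export(name = ".assemble_cpp")]]
List assemble_cpp(CharacterVector reads_in, CharacterVector ids_in,
                  int min_ov_len, double min_ov_ident, int min_ov_score,
                  int min_reads, int kmer, bool verbose = false) {
  int dbg_guard_len = 0, dbg_guard_ident = 0, dbg_merged = 0, dbg_same = 0;
  const int n = reads_in.size();
  std::vector<std::string> reads(n), ids(n);
  for (int i = 0; i < n; ++i) {
    reads[i] = as<std::string>(reads_in[i]);
    ids[i] = as<std::string>(ids_in[i]);
  }
  // oriented[2*i] = forward, oriented[2*i+1] = reverse complement
  std::vector<std::string> oriented(2 * n);
  for (int i = 0; i < n; ++i) {
    oriented[2 * i] = reads[i];
    oriented[2 * i + 1] = revcomp_str(reads[i]);
  }
  // forward k-mer index over all reads
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  const uint64_t mask = (kmer < 32) ? ((1ULL << (2 * kmer)) - 1) : ~0ULL;
  auto kmers_of = [&](const std::string& s, auto&& fn) {
    uint64_t key = 0; int valid = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int b;
      switch (s[p]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: valid = 0; key = 0; continue;
      }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++valid >= kmer) fn(key, p - kmer + 1);
    }
  };
  for (int i = 0; i < n; ++i)
    kmers_of(reads[i], [&](uint64_t key, int p) { index[key].emplace_back(i, p); });

  // candidate (i, j, orient, diag) tuples
  std::vector<Overlap> cands;
  {
    std::vector<uint64_t> seen;  // encoded dedupe per query read
    for (int j = 0; j < n; ++j) {
      seen.clear();
      for (int o = 0; o < 2; ++o) {
        const std::string& q = oriented[2 * j + o];
        // query k-mers at stride 4: a minimal 40 bp overlap still shares
        // several sampled k-mers with the indexed read
        int phase = 0;
        kmers_of(q, [&](uint64_t key, int p) {
          if ((phase++ & 3) != 0) return;
          auto it = index.find(key);
          if (it == index.end()) return;
          for (auto& hit : it->second) {
            const int i = hit.first;
            if (i >= j) continue;  // each unordered pair once
            const int d = hit.second - p;  // oriented j offset in i coords
            seen.push_back(((uint64_t)i << 33) | ((uint64_t)o << 32) |
                           (uint64_t)(uint32_t)(d + (1 << 30)));
          }
        });
      }
      std::sort(seen.begin(), seen.end());
      seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
      for (uint64_t code : seen) {
        Overlap ov;
        ov.i = (int)(code >> 33);
        ov.orient = (int)((code >> 32) & 1);
        ov.diag = (int)(uint32_t)(code & 0xFFFFFFFFULL) - (1 << 30);
        ov.j = j;
        const std::string& a = reads[ov.i];
        const std::string& b = oriented[2 * j + ov.orient];
        const int la = (int)a.size(), lb = (int)b.size();
        const int s = std::max(0, ov.diag), e = std::min(la, ov.diag + lb);
        const int len = e - s;
        if (len < min_ov_len) continue;
        const int max_mm = (int)((1.0 - min_ov_ident) * len + 1e-9);
        int mm = 0;
        for (int t = s; t < e; ++t) {
          if (a[t] != b[t - ov.diag] && ++mm > max_mm) break;
        }
        if (mm > max_mm) continue;
        ov.ov_len = len;
        ov.score = 3 * (len - mm) - 5 * mm;
        if (ov.score < min_ov_score) continue;
        cands.push_back(ov);
      }
    }
  }
  // best-first; ties: longer overlap, then lexicographic read ids
  std::sort(cands.begin(), cands.end(), [&](const Overlap& a, const Overlap& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.ov_len != b.ov_len) return a.ov_len > b.ov_len;
    const std::string &ai = ids[a.i], &bi = ids[b.i];
    if (ai != bi) return ai < bi;
    const std::string &aj = ids[a.j], &bj = ids[b.j];
    if (aj != bj) return aj < bj;
    if (a.orient != b.orient) return a.orient < b.orient;
    return a.diag < b.diag;
  });

  std::vector<int> unit_of(n);
  std::vector<Unit> units(n);
  for (int i = 0; i < n; ++i) {
    unit_of[i] = i;
    units[i].members.push_back({i, 0, 0});
    rebuild_consensus(units[i], oriented);
  }
  std::vector<std::pair<int, int>> place(n);  // (offset, strand) of read in its unit
  for (int i = 0; i < n; ++i) place[i] = {0, 0};

  for (const Overlap& ov : cands) {
    int u = unit_of[ov.i], v = unit_of[ov.j];
    if (u == v) { ++dbg_same; continue; }
    const int li = (int)reads[ov.i].size();
    const int lj = (int)reads[ov.j].size();
    const auto [oi, si] = place[ov.i];
    const auto [oj, sj] = place[ov.j];
    // placement of oriented-j in u coordinates
    int sj_u = ov.orient ^ si;
    int oj_u = (si == 0) ? oi + ov.diag : oi + li - ov.diag - lj;
    // transform v frame -> u frame via read j
    bool flip = (sj_u != sj);
    int shift = 0, K = 0;
    if (!flip) shift = oj_u - oj;
    else K = oj_u + oj + lj - 1;
    // chimera guard: consensus agreement over the implied layout overlap.
    // Only columns with depth >= 3 in both units are compared: there the
    // majority consensus is robust to isolated read errors, whereas thin
    // staircase tails (depth 1-2, possibly shifted by a rare error indel)
    // would deadlock legitimate merges. When the overlap has no such
    // columns, the read-level overlap gates are the only evidence and the
    // merge proceeds on them.
    if (units[u].members.size() > 1 || units[v].members.size() > 1) {
      const std::string& cu = units[u].consensus;
      std::string cv = units[v].consensus;
      std::vector<int> dv = units[v].depth;
      int cv_off;
      if (!flip) cv_off = units[v].cons_off + shift;
      else {
        cv = revcomp_str(cv);
        std::reverse(dv.begin(), dv.end());
        cv_off = K - (units[v].cons_off + (int)units[v].consensus.size() - 1);
      }
      const int s0 = std::max(units[u].cons_off, cv_off);
      const int e0 = std::min(units[u].cons_off + (int)cu.size(),
                              cv_off + (int)cv.size());
      const int len = e0 - s0;
      if (len < min_ov_len) { ++dbg_guard_len; continue; }
      int mm = 0, cmp = 0;
      for (int t = s0; t < e0; ++t) {
        const int iu = t - units[u].cons_off, iv = t - cv_off;
        if (units[u].depth[iu] < 3 || dv[iv] < 3) continue;
        char a = cu[iu], b = cv[iv];
        if (a == 'N' || b == 'N') continue;
        ++cmp;
        if (a != b) ++mm;
      }
      if (cmp > 0 && (double)(cmp - mm) / cmp < min_ov_ident) {
        ++dbg_guard_ident;
        if (verbose && units[u].members.size() > 20 && units[v].members.size() > 20)
          Rprintf("guard reject: units %zu x %zu, overlap %d, mm %d/%d\n",
                  units[u].members.size(), units[v].members.size(), len, mm, cmp);
        continue;
      }
    }
    ++dbg_merged;
    // commit: move the smaller unit's members into the larger one,
    // updating its base counts incrementally (the v->u transform is a
    // shift or an involution, so the inverse is immediate)
    int src = v, dst = u;
    bool inverse = false;
    if (units[v].members.size() > units[u].members.size()) {
      src = u; dst = v; inverse = true;
    }
    std::vector<Member> moved;
    moved.reserve(units[src].members.size());
    for (Member m : units[src].members) {
      const int lm = (int)reads[m.read].size();
      Member nm = m;
      if (!flip) nm.offset = m.offset + (inverse ? -shift : shift);
      else {
        nm.offset = K - m.offset - lm + 1;
        nm.strand = 1 - m.strand;
      }
      moved.push_back(nm);
    }
    int lo = INT32_MAX, hi = INT32_MIN;
    for (const Member& nm : moved) {
      lo = std::min(lo, nm.offset);
      hi = std::max(hi, nm.offset + (int)reads[nm.read].size());
    }
    grow_counts(units[dst], lo, hi);
    for (const Member& nm : moved) {
      units[dst].members.push_back(nm);
      unit_of[nm.read] = dst;
      place[nm.read] = {nm.offset, nm.strand};
      add_to_counts(units[dst], nm, oriented);
    }
    refresh_from_counts(units[dst]);
    units[src].members.clear();
    units[src].consensus.clear();
    units[src].cnt.clear();
  }

  if (verbose)
    Rprintf("overlaps %zu: merged %d, same-unit %d, guard-len %d, guard-ident %d\n",
            cands.size(), dbg_merged, dbg_same, dbg_guard_len, dbg_guard_ident);
  // finalize: consensus, per-read identity polish, filters
  struct OutContig {
    std::string seq;
    std::vector<Member> members;
  };
  std::vector<OutContig> out;
  for (int u = 0; u < n; ++u) {
    Unit& un = units[u];
    if (un.members.size() < 2) continue;
    rebuild_consensus(un, oriented);
    // polish: drop reads below the identity gate against the consensus
    std::vector<Member> kept;
    for (const Member& m : un.members) {
      const std::string& s = oriented[2 * m.read + m.strand];
      int mm = 0, cmp = 0;
      for (size_t t = 0; t < s.size(); ++t) {
        int p = m.offset - un.cons_off + (int)t;
        if (p < 0 || p >= (int)un.consensus.size()) { ++mm; ++cmp; continue; }
        ++cmp;
        if (s[t] != un.consensus[p]) ++mm;
      }
      if (cmp > 0 && (double)(cmp - mm) / cmp >= min_ov_ident) kept.push_back(m);
    }
    if ((int)kept.size() < std::max(min_reads, 2)) continue;
    if (kept.size() != un.members.size()) {
      un.members = kept;
      rebuild_consensus(un, oriented);
    }
    OutContig oc;
    oc.seq = un.consensus;
    for (Member m : un.members) { m.offset -= un.cons_off; oc.members.push_back(m); }
    out.push_back(std::move(oc));
  }
  std::sort(out.begin(), out.end(), [](const OutContig& a, const OutContig& b) {
    if (a.members.size() != b.members.size()) return a.members.size() > b.members.size();
    if (a.seq.size() != b.seq.size()) return a.seq.size() > b.seq.size();
    return a.seq < b.seq;
  });

  CharacterVector seqs(out.size());
  IntegerVector nreads(out.size());
  std::vector<std::string> lay_read;
  std::vector<int> lay_contig, lay_off, lay_strand;
  for (size_t c = 0; c < out.size(); ++c) {
    seqs[c] = out[c].seq;
    nreads[c] = (int)out[c].members.size();
    for (const Member& m : out[c].members) {
      lay_read.push_back(ids[m.read]);
      lay_contig.push_back((int)c + 1);
      lay_off.push_back(m.offset);
      lay_strand.push_back(m.strand);
    }
  }
  DataFrame layout = DataFrame::create(
    _["read_id"] = lay_read, _["contig"] = lay_contig,
    _["offset"] = lay_off, _["strand"] = lay_strand,
    _["stringsAsFactors"] = false);
  return List::create(_["seq"] = seqs, _["n_reads"] = nreads, _["layout"] = layout);
}
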