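// Seed-and-extend aligner on an exact k-mer index with banded edit-distance
// extension.  Alignments are read-anchored and semi-global: the first read
// base sits at the reported reference offset, the whole read is consumed,
// and the reference end is free within the band.  With band >= edit budget
// this finds every offset whose edit distance is within budget (any <=e-edit
// path stays within e diagonals of the anchor), which is what the R-side
// oracle tests rely on.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> map;
};

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  bool any_long_enough = false;
  const uint64_t mask = (k == 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
  for (int r = 0; r < names.size(); ++r) {
    idx->names.push_back(as<std::string>(names[r]));
    std::string s = as<std::string>(seqs[r]);
    idx->seqs.push_back(s);
    if ((int)s.size() >= k) any_long_enough = true;
    uint64_t code = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) {
        valid = 0;
        code = 0;
        continue;
      }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        idx->map[code].push_back({(int32_t)r, (int32_t)(i - k + 1)});
      }
    }
  }
  if (!any_long_enough) {
    delete idx;
    stop("k exceeds the length of every reference sequence");
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  IntegerVector lens(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) lens[i] = idx->seqs[i].size();
  return List::create(_["names"] = wrap(idx->names), _["k"] = idx->k,
                      _["lengths"] = lens);
}

// Number of query k-mer positions (forward orientation of `seq`) present in
// the index; used by the simulator for cross-compartment k-mer rejection.
// [[Rcpp::export(name = ".cpp_kmer_hit_positions")]]
IntegerVector cpp_kmer_hit_positions(SEXP xp, std::string seq) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  const uint64_t mask = (uint64_t(1) << (2 * k)) - 1;
  std::vector<int> out;
  uint64_t code = 0;
  int valid = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base_code(seq[i]);
    if (b < 0) {
      valid = 0;
      code = 0;
      continue;
    }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++valid >= k && idx->map.count(code)) out.push_back((int)(i - k + 1));
  }
  return wrap(out);
}

struct Aln {
  int ref;
  int offset;   // 0-based reference start
  int ref_end;  // 0-based half-open reference end
  int nm;
  std::string cigar;
  char strand;
};

// Banded anchored DP. Returns edit distance or budget+1 if none; fills
// traceback products (ref_end, cigar) when requested.
// dp layout: row i (read consumed), column c = j - (i - b), c in [0, 2b].
static int banded_align(const std::string &q, const std::string &ref, int o,
                        int budget, bool want_cigar, int *ref_end_out,
                        std::string *cigar_out,
                        std::vector<int32_t> &dp /* scratch */) {
  const int len = (int)q.size();
  const int b = budget;
  const int W = 2 * b + 1;
  const int wmax = std::min((int)ref.size() - o, len + b);
  if (wmax < len - b) return budget + 1;
  const int32_t INF = 1 << 29;
  dp.assign((size_t)(len + 1) * W, INF);
  auto at = [&](int i, int c) -> int32_t & { return dp[(size_t)i * W + c]; };
  for (int j = 0; j <= std::min(b, wmax); ++j) at(0, j - (0 - b)) = j;
  for (int i = 1; i <= len; ++i) {
    const int jlo = std::max(0, i - b);
    const int jhi = std::min(wmax, i + b);
    if (jlo > jhi) return budget + 1;
    char qc = q[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const int c = j - (i - b);
      int32_t best = INF;
      if (j >= 1) {  // diagonal: consume one read + one ref base
        int32_t d = at(i - 1, c);  // (i-1, j-1) -> same c
        if (d < INF) {
          d += (qc == ref[o + j - 1]) ? 0 : 1;
          if (d < best) best = d;
        }
      }
      if (c + 1 < W) {  // up: consume read base (gap in ref; CIGAR I)
        int32_t d = at(i - 1, c + 1);
        if (d < INF && d + 1 < best) best = d + 1;
      }
      if (c - 1 >= 0 && j >= 1) {  // left: consume ref base (CIGAR D)
        int32_t d = at(i, c - 1);
        if (d < INF && d + 1 < best) best = d + 1;
      }
      at(i, c) = best;
    }
  }
  // pick end column: minimal distance; ties resolved toward j == len, then
  // the larger j (consume more reference) for determinism
  int best_j = -1;
  int32_t best_d = INF;
  const int jlo = std::max(0, len - b), jhi = std::min(wmax, len + b);
  for (int j = jlo; j <= jhi; ++j) {
    int32_t d = at(len, j - (len - b));
    if (d < best_d ||
        (d == best_d && best_j >= 0 &&
         (std::abs(j - len) < std::abs(best_j - len) ||
          (std::abs(j - len) == std::abs(best_j - len) && j > best_j)))) {
      best_d = d;
      best_j = j;
    }
  }
  if (best_d > budget) return budget + 1;
  if (ref_end_out) *ref_end_out = o + best_j;
  if (want_cigar && cigar_out) {
    // traceback, preferring diagonal, then D (ref gap consumption), then I
    std::string ops;
    int i = len, j = best_j;
    while (i > 0 || j > 0) {
      const int c = j - (i - b);
      int32_t cur = at(i, c);
      if (i > 0 && j > 0) {
        int32_t d = at(i - 1, c);
        if (d < INF && d + ((q[i - 1] == ref[o + j - 1]) ? 0 : 1) == cur) {
          ops.push_back('M');
          --i;
          --j;
          continue;
        }
      }
      if (j > 0 && c - 1 >= 0 && at(i, c - 1) < INF && at(i, c - 1) + 1 == cur) {
        ops.push_back('D');
        --j;
        continue;
      }
      if (i > 0 && c + 1 < 2 * b + 1 && at(i - 1, c + 1) < INF &&
          at(i - 1, c + 1) + 1 == cur) {
        ops.push_back('I');
        --i;
        continue;
      }
      break;  // unreachable for consistent tables
    }
    std::reverse(ops.begin(), ops.end());
    std::string cig;
    for (size_t p = 0; p < ops.size();) {
      size_t e = p;
      while (e < ops.size() && ops[e] == ops[p]) ++e;
      cig += std::to_string(e - p);
      cig.push_back(ops[p]);
      p = e;
    }
    *cigar_out = cig;
  }
  return best_d;
}

// candidate anchored offsets per reference, from exact k-mer seed hits,
// widened by +-budget
static void collect_candidates(const KmerIndex &idx, const std::string &q,
                               int budget, int max_per_kmer, int min_consume,
                               std::vector<std::pair<int, int>> &out) {
  const int k = idx.k;
  const int len = (int)q.size();
  (void)len;
  const uint64_t mask = (uint64_t(1) << (2 * k)) - 1;
  std::unordered_set<int64_t> seen;
  uint64_t code = 0;
  int valid = 0;
  for (int i = 0; i < len; ++i) {
    int bc = base_code(q[i]);
    if (bc < 0) {
      valid = 0;
      code = 0;
      continue;
    }
    code = ((code << 2) | (uint64_t)bc) & mask;
    if (++valid < k) continue;
    auto it = idx.map.find(code);
    if (it == idx.map.end()) continue;
    const auto &hits = it->second;
    if ((int)hits.size() > max_per_kmer) continue;
    const int p = i - k + 1;
    for (const auto &h : hits) {
      const int diag = h.second - p;
      const int rlen = (int)idx.seqs[h.first].size();
      for (int o = diag - budget; o <= diag + budget; ++o) {
        if (o < 0) continue;
        if (o + min_consume > rlen) continue;
        int64_t key = ((int64_t)h.first << 33) | (int64_t)(o + 1);
        if (seen.insert(key).second) out.push_back({h.first, o});
      }
    }
  }
  std::sort(out.begin(), out.end());
}

// [[Rcpp::export(name = ".cpp_align")]]
DataFrame cpp_align(SEXP xp, CharacterVector reads, int budget,
                    std::string strand_mode, int max_per_kmer,
                    int max_candidates) {
  XPtr<KmerIndex> idx(xp);
  std::vector<int> o_query, o_ref, o_start, o_end, o_nm;
  std::vector<std::string> o_cigar;
  std::vector<std::string> o_strand;
  std::vector<int32_t> dp;
  const bool both = (strand_mode == "both");
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    for (int s = 0; s < (both ? 2 : 1); ++s) {
      const std::string q = (s == 0) ? fwd : revcomp(fwd);
      std::vector<std::pair<int, int>> cand;
      collect_candidates(*idx, q, budget, max_per_kmer, (int)q.size() - budget,
                         cand);
      if ((int)cand.size() > max_candidates) cand.resize(max_candidates);
      for (const auto &co : cand) {
        int ref_end = 0;
        std::string cig;
        int d = banded_align(q, idx->seqs[co.first], co.second, budget, true,
                             &ref_end, &cig, dp);
        if (d <= budget) {
          o_query.push_back(r + 1);
          o_ref.push_back(co.first + 1);
          o_start.push_back(co.second);
          o_end.push_back(ref_end);
          o_nm.push_back(d);
          o_cigar.push_back(cig);
          o_strand.push_back(s == 0 ? "+" : "-");
        }
      }
    }
  }
  return DataFrame::create(
      _["query"] = wrap(o_query), _["ref"] = wrap(o_ref),
      _["strand"] = wrap(o_strand), _["ref_start"] = wrap(o_start),
      _["ref_end"] = wrap(o_end), _["edit_distance"] = wrap(o_nm),
      _["cigar"] = wrap(o_cigar), _["stringsAsFactors"] = false);
}

// prefix edit-distance profile: P[bp] = best edits aligning q[0..bp) anchored
// at `o`; jend[bp] = reference columns consumed at that optimum
static void prefix_profile(const std::string &q, const std::string &ref, int o,
                           int budget, std::vector<int> &P,
                           std::vector<int> &jend,
                           std::vector<int32_t> &dp) {
  const int len = (int)q.size();
  const int b = budget;
  const int W = 2 * b + 1;
  const int wmax = std::min((int)ref.size() - o, len + b);
  const int32_t INF = 1 << 29;
  P.assign(len + 1, budget + 1);
  jend.assign(len + 1, -1);
  if (wmax < 0) return;
  dp.assign((size_t)(len + 1) * W, INF);
  auto at = [&](int i, int c) -> int32_t & { return dp[(size_t)i * W + c]; };
  for (int j = 0; j <= std::min(b, wmax); ++j) at(0, j + b) = j;
  for (int i = 0; i <= len; ++i) {
    if (i > 0) {
      const int jlo = std::max(0, i - b), jhi = std::min(wmax, i + b);
      char qc = q[i - 1];
      for (int j = jlo; j <= jhi; ++j) {
        const int c = j - (i - b);
        int32_t best = INF;
        if (j >= 1) {
          int32_t d = at(i - 1, c);
          if (d < INF) {
            d += (qc == ref[o + j - 1]) ? 0 : 1;
            if (d < best) best = d;
          }
        }
        if (c + 1 < W) {
          int32_t d = at(i - 1, c + 1);
          if (d < INF && d + 1 < best) best = d + 1;
        }
        if (c - 1 >= 0 && j >= 1) {
          int32_t d = at(i, c - 1);
          if (d < INF && d + 1 < best) best = d + 1;
        }
        at(i, c) = best;
      }
    }
    const int jlo = std::max(0, i - b), jhi = std::min(wmax, i + b);
    int bestj = -1;
    int32_t bestd = INF;
    for (int j = jlo; j <= jhi; ++j) {
      int32_t d = at(i, j - (i - b));
      if (d < bestd || (d == bestd && bestj >= 0 &&
                        (std::abs(j - i) < std::abs(bestj - i) ||
                         (std::abs(j - i) == std::abs(bestj - i) && j > bestj)))) {
        bestd = d;
        bestj = j;
      }
    }
    if (bestd <= budget) {
      P[i] = bestd;
      jend[i] = bestj;
    }
  }
}

// Two-segment split alignment: best pair (prefix anchor, suffix anchor) with
// read split at b1 (prefix covers [0,b1)) and suffix covering [b2,len),
// b1 - b2 in [0, max_overlap], both segments >= min_seg, combined edits
// <= budget.  Returns two rows per solved read, in query orientation.
// [[Rcpp::export(name = ".cpp_split_align")]]
DataFrame cpp_split_align(SEXP xp, CharacterVector reads, int budget,
                          int min_seg, int max_overlap,
                          std::string strand_mode, int max_per_kmer,
                          int max_candidates) {
  XPtr<KmerIndex> idx(xp);
  const bool both = (strand_mode == "both");
  std::vector<int> o_query, o_seg, o_ref, o_start, o_end, o_qstart, o_qend,
      o_nm, o_total;
  std::vector<std::string> o_strand;
  std::vector<int32_t> dp;
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int len = (int)fwd.size();
    if (len < 2 * min_seg - max_overlap) continue;

    struct Best {
      int cost = -1, b1 = -1, b2 = -1;
      int ref1 = -1, o1 = -1, e1 = -1, ref2 = -1, s2 = -1, e2 = -1;
    } best[2];

    for (int s = 0; s < (both ? 2 : 1); ++s) {
      const std::string q = (s == 0) ? fwd : revcomp(fwd);
      const std::string qr(q.rbegin(), q.rend());
      // prefix candidates (anchored left) and suffix candidates (anchored
      // right, realised as prefix anchors of the reversed query on the
      // reversed reference)
      std::vector<std::pair<int, int>> pc;
      collect_candidates(*idx, q, budget, max_per_kmer, min_seg - budget, pc);
      if ((int)pc.size() > max_candidates) pc.resize(max_candidates);

      // suffix candidates: seed hits give implied reference *end* positions
      std::vector<std::pair<int, int>> sc;  // (ref, end)
      {
        const int k = idx->k;
        const uint64_t mask = (uint64_t(1) << (2 * k)) - 1;
        std::unordered_set<int64_t> seen;
        uint64_t code = 0;
        int valid = 0;
        for (int i = 0; i < len; ++i) {
          int bc = base_code(q[i]);
          if (bc < 0) {
            valid = 0;
            code = 0;
            continue;
          }
          code = ((code << 2) | (uint64_t)bc) & mask;
          if (++valid < k) continue;
          auto it = idx->map.find(code);
          if (it == idx->map.end()) continue;
          if ((int)it->second.size() > max_per_kmer) continue;
          const int p = i - k + 1;
          for (const auto &h : it->second) {
            const int e0 = h.second + (len - p);
            const int rlen = (int)idx->seqs[h.first].size();
            for (int e = e0 - budget; e <= e0 + budget; ++e) {
              if (e < min_seg - budget || e > rlen) continue;
              int64_t key = ((int64_t)h.first << 33) | (int64_t)(e + 1);
              if (seen.insert(key).second) sc.push_back({h.first, e});
            }
          }
        }
        std::sort(sc.begin(), sc.end());
        if ((int)sc.size() > max_candidates) sc.resize(max_candidates);
      }
      if (pc.empty() || sc.empty()) continue;

      const int NONE = budget + 1;
      // best prefix cost over candidates, per split point
      std::vector<int> Pb(len + 1, NONE), Pc(len + 1, -1), Pe(len + 1, -1);
      std::vector<int> P, jend;
      for (size_t ci = 0; ci < pc.size(); ++ci) {
        prefix_profile(q, idx->seqs[pc[ci].first], pc[ci].second, budget, P,
                       jend, dp);
        for (int bp = min_seg; bp <= len - (min_seg - max_overlap); ++bp) {
          if (P[bp] < Pb[bp]) {
            Pb[bp] = P[bp];
            Pc[bp] = (int)ci;
            Pe[bp] = pc[ci].second + jend[bp];
          }
        }
      }
      // best suffix cost per start position: suffix q[b2..len) ending at e;
      // equals prefix of reversed query anchored at reversed offset
      std::vector<int> Sb(len + 1, NONE), Sc(len + 1, -1), Ss(len + 1, -1);
      for (size_t ci = 0; ci < sc.size(); ++ci) {
        const std::string &ref = idx->seqs[sc[ci].first];
        const std::string rref(ref.rbegin(), ref.rend());
        prefix_profile(qr, rref, (int)ref.size() - sc[ci].second, budget, P,
                       jend, dp);
        for (int b2 = 0; b2 <= len - min_seg; ++b2) {
          const int m = len - b2;  // suffix length
          if (P[m] < Sb[b2]) {
            Sb[b2] = P[m];
            Sc[b2] = (int)ci;
            Ss[b2] = sc[ci].second - jend[m];  // ref start of segment 2
          }
        }
      }
      // combine
      Best bb;
      for (int b1 = min_seg; b1 <= len; ++b1) {
        if (Pb[b1] > budget) continue;
        for (int b2 = std::max(0, b1 - max_overlap); b2 <= b1; ++b2) {
          if (len - b2 < min_seg || b2 > len) continue;
          if (Sb[b2] > budget) continue;
          const int cost = Pb[b1] + Sb[b2];
          if (cost > budget) continue;
          if (bb.cost < 0 || cost < bb.cost ||
              (cost == bb.cost && (b1 < bb.b1 ||
                                   (b1 == bb.b1 && (b1 - b2) < (bb.b1 - bb.b2))))) {
            bb.cost = cost;
            bb.b1 = b1;
            bb.b2 = b2;
            bb.ref1 = pc[Pc[b1]].first;
            bb.o1 = pc[Pc[b1]].second;
            bb.e1 = Pe[b1];
            bb.ref2 = sc[Sc[b2]].first;
            bb.s2 = Ss[b2];
            bb.e2 = sc[Sc[b2]].second;
          }
        }
      }
      best[s] = bb;
    }

    int pick = -1;
    if (best[0].cost >= 0 &&
        (best[1].cost < 0 || best[0].cost <= best[1].cost))
      pick = 0;
    else if (best[1].cost >= 0)
      pick = 1;
    if (pick < 0) continue;
    const Best &bb = best[pick];
    // report segments in ORIGINAL read order; for the reverse-complement
    // orientation the query suffix is the original read's prefix
    if (pick == 0) {
      int qs[2] = {0, bb.b2}, qe[2] = {bb.b1, len};
      int rs[2] = {bb.o1, bb.s2}, re[2] = {bb.e1, bb.e2};
      int rf[2] = {bb.ref1, bb.ref2};
      int nm[2] = {-1, -1};
      for (int i = 0; i < 2; ++i) {
        o_query.push_back(r + 1);
        o_seg.push_back(i + 1);
        o_ref.push_back(rf[i] + 1);
        o_strand.push_back("+");
        o_start.push_back(rs[i]);
        o_end.push_back(re[i]);
        o_qstart.push_back(qs[i]);
        o_qend.push_back(qe[i]);
        o_nm.push_back(nm[i]);
        o_total.push_back(bb.cost);
      }
    } else {
      // query coords on revcomp; original read interval [len-qe, len-qs)
      int qs[2] = {len - len, len - bb.b1};         // from suffix, prefix
      int qe[2] = {len - bb.b2, len - 0};
      int rs[2] = {bb.s2, bb.o1}, re[2] = {bb.e2, bb.e1};
      int rf[2] = {bb.ref2, bb.ref1};
      for (int i = 0; i < 2; ++i) {
        o_query.push_back(r + 1);
        o_seg.push_back(i + 1);
        o_ref.push_back(rf[i] + 1);
        o_strand.push_back("-");
        o_start.push_back(rs[i]);
        o_end.push_back(re[i]);
        o_qstart.push_back(qs[i]);
        o_qend.push_back(qe[i]);
        o_nm.push_back(-1);
        o_total.push_back(bb.cost);
      }
    }
  }
  return DataFrame::create(
      _["query"] = wrap(o_query), _["segment"] = wrap(o_seg),
      _["ref"] = wrap(o_ref), _["strand"] = wrap(o_strand),
      _["ref_start"] = wrap(o_start), _["ref_end"] = wrap(o_end),
      _["read_start"] = wrap(o_qstart), _["read_end"] = wrap(o_qend),
      _["edit_distance"] = wrap(o_nm), _["total_edit_distance"] = wrap(o_total),
      _["stringsAsFactors"] = false);
}

// Ungapped V-suffix / J-prefix spanning scan for V(D)J junction reads.
// The read prefix [0, lv) is compared against the 3' end of each V segment
// and the read suffix [s, len) against the 5' start of each J segment of the
// same locus; the read must end inside J.  Best combination by total
// matches, ties by fewer mismatches then segment order.
// [[Rcpp::export(name = ".cpp_vj_scan")]]
DataFrame cpp_vj_scan(CharacterVector reads, CharacterVector v_seqs,
                      IntegerVector v_locus, CharacterVector j_seqs,
                      IntegerVector j_locus, int min_overlap,
                      double max_mismatch_rate, int max_insert) {
  std::vector<std::string> V, J;
  for (int i = 0; i < v_seqs.size(); ++i) V.push_back(as<std::string>(v_seqs[i]));
  for (int i = 0; i < j_seqs.size(); ++i) J.push_back(as<std::string>(j_seqs[i]));
  std::vector<int> o_read, o_v, o_j, o_vo, o_jo, o_vmm, o_jmm, o_ins, o_match;
  for (int r = 0; r < reads.size(); ++r) {
    const std::string q = as<std::string>(reads[r]);
    const int len = (int)q.size();
    // V candidates: (v, lv, mm)
    struct Cand { int seg, olap, mm; };
    std::vector<Cand> vc;
    for (size_t v = 0; v < V.size(); ++v) {
      const std::string &vs = V[v];
      const int lmax = std::min(len, (int)vs.size());
      for (int l = min_overlap; l <= lmax; ++l) {
        int mm = 0;
        const int voff = (int)vs.size() - l;
        for (int i = 0; i < l; ++i) mm += (q[i] != vs[voff + i]);
        if (mm <= max_mismatch_rate * l) vc.push_back({(int)v, l, mm});
      }
    }
    if (vc.empty()) continue;
    // J candidates keyed by read start s: read[s..len) vs J[0..len-s)
    std::vector<Cand> jc;  // seg, olap = len - s, mm
    for (size_t j = 0; j < J.size(); ++j) {
      const std::string &js = J[j];
      for (int s = std::max(0, len - (int)js.size()); s <= len - min_overlap;
           ++s) {
        const int l = len - s;
        int mm = 0;
        for (int i = 0; i < l; ++i) mm += (q[s + i] != js[i]);
        if (mm <= max_mismatch_rate * l) jc.push_back({(int)j, l, mm});
      }
    }
    if (jc.empty()) continue;
    int b_match = -1, b_mm = 0, b_v = -1, b_j = -1, b_vo = 0, b_jo = 0,
        b_vmm = 0, b_jmm = 0, b_ins = 0;
    for (const auto &a : vc) {
      for (const auto &b : jc) {
        if (v_locus[a.seg] != j_locus[b.seg]) continue;
        const int ins = (len - b.olap) - a.olap;  // bases between V and J
        if (ins < 0 || ins > max_insert) continue;
        const int match = (a.olap - a.mm) + (b.olap - b.mm);
        const int mm = a.mm + b.mm;
        bool better = false;
        if (match > b_match) better = true;
        else if (match == b_match) {
          if (mm < b_mm) better = true;
          else if (mm == b_mm && (a.seg < b_v || (a.seg == b_v && b.seg < b_j)))
            better = true;
        }
        if (better) {
          b_match = match;
          b_mm = mm;
          b_v = a.seg;
          b_j = b.seg;
          b_vo = a.olap;
          b_jo = b.olap;
          b_vmm = a.mm;
          b_jmm = b.mm;
          b_ins = ins;
        }
      }
    }
    if (b_match >= 0) {
      o_read.push_back(r + 1);
      o_v.push_back(b_v + 1);
      o_j.push_back(b_j + 1);
      o_vo.push_back(b_vo);
      o_jo.push_back(b_jo);
      o_vmm.push_back(b_vmm);
      o_jmm.push_back(b_jmm);
      o_ins.push_back(b_ins);
      o_match.push_back(b_match);
    }
  }
  return DataFrame::create(
      _["query"] = wrap(o_read), _["v"] = wrap(o_v), _["j"] = wrap(o_j),
      _["v_overlap"] = wrap(o_vo), _["j_overlap"] = wrap(o_jo),
      _["v_mismatch"] = wrap(o_vmm), _["j_mismatch"] = wrap(o_jmm),
      _["insert_length"] = wrap(o_ins), _["matches"] = wrap(o_match),
      _["stringsAsFactors"] = false);
}
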