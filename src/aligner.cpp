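// Seed-and-extend nucleotide aligner: k-mer index over targets, diagonal
// clustering of seed hits into chains, banded affine-gap DP over each
// chained window, ungapped X-drop extension of the window ends.
// When band_width >= query length the full (unbanded) fit DP is run
// instead, so small-instance scores equal the unrestricted optimum.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = -1000000000;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }

// ---------------------------------------------------------------------------
// k-mer index
// ---------------------------------------------------------------------------

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;              // uppercase target sequences
  std::vector<uint64_t> codes;                // sorted k-mer codes
  std::vector<uint64_t> tidpos;               // parallel (tid << 32) | pos
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector targets, int k) {
  if (k < 8 || k > 31) stop("k must be between 8 and 31");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  size_t n_entries = 0;
  std::vector<std::pair<uint64_t, uint64_t>> ent;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (int t = 0; t < targets.size(); ++t) {
    std::string s = as<std::string>(targets[t]);
    idx->seqs.push_back(s);
    const int L = (int)s.size();
    uint64_t code = 0;
    int run = 0;  // consecutive valid bases ending here
    for (int i = 0; i < L; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        ent.emplace_back(code, ((uint64_t)t << 32) | (uint64_t)(i - k + 1));
      }
    }
  }
  std::sort(ent.begin(), ent.end());
  n_entries = ent.size();
  idx->codes.resize(n_entries);
  idx->tidpos.resize(n_entries);
  for (size_t i = 0; i < n_entries; ++i) {
    idx->codes[i] = ent[i].first;
    idx->tidpos[i] = ent[i].second;
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  IntegerVector lens(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) lens[i] = (int)idx->seqs[i].size();
  return List::create(_["k"] = idx->k,
                      _["n_targets"] = (int)idx->seqs.size(),
                      _["target_lengths"] = lens,
                      _["n_kmers"] = (double)idx->codes.size());
}

// Positions of one literal k-mer (0-based), for verification.
// [[Rcpp::export]]
IntegerMatrix cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("kmer length must equal index k");
  uint64_t code = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b < 0) return IntegerMatrix(0, 2);
    code = (code << 2) | (uint64_t)b;
  }
  auto lo = std::lower_bound(idx->codes.begin(), idx->codes.end(), code);
  auto hi = std::upper_bound(idx->codes.begin(), idx->codes.end(), code);
  int n = (int)(hi - lo);
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    uint64_t tp = idx->tidpos[(lo - idx->codes.begin()) + i];
    out(i, 0) = (int)(tp >> 32);
    out(i, 1) = (int)(tp & 0xffffffffULL);
  }
  return out;
}

// ---------------------------------------------------------------------------
// banded affine-gap DP
// ---------------------------------------------------------------------------

struct Scoring {
  int match, mismatch, gap_open, gap_extend;  // gap of len L costs open + L*extend
};

struct Ops {
  // run-length encoded alignment: 'M' both, 'D' target only (deletion from
  // the query), 'I' query only (insertion in the query)
  std::vector<std::pair<char, int>> runs;
};

struct AlnResult {
  bool ok = false;
  int qs = 0, qe = 0, ts = 0, te = 0;  // strand-local query coords, target coords
  Ops ops;
  long score = 0;
};

// Align q[qs,qe) vs t[ts,te); band on window diagonals j - i in [lo, hi].
// fit = true frees the target ends (query aligned end to end).
static bool banded_dp(const std::string& q, const std::string& t,
                      int qs, int qe, int ts, int te,
                      int lo, int hi, const Scoring& sc, bool fit,
                      AlnResult& out) {
  const int Lq = qe - qs, Lt = te - ts;
  if (Lq <= 0 || Lt <= 0) return false;
  if (lo > 0) lo = 0;
  if (hi < Lt - Lq) hi = Lt - Lq;
  const int W = hi - lo + 1;
  if ((double)(Lq + 1) * (double)W > 1.5e9) stop("alignment window too large");

  std::vector<int> H(W, NEG_INF), F(W, NEG_INF), Hprev(W, NEG_INF), Fprev(W, NEG_INF);
  std::vector<uint8_t> tb((size_t)(Lq + 1) * W, 0xFF);
  // tb bits 0-1: H source (0 diag, 1 E, 2 F, 3 boundary); bit2: E extends; bit3: F extends

  // row 0
  {
    int j0 = std::max(0, lo), j1 = std::min(Lt, hi);
    for (int j = j0; j <= j1; ++j) {
      int o = j - lo;
      H[o] = fit ? 0 : (j == 0 ? 0 : sc.gap_open + sc.gap_extend * j);
      F[o] = NEG_INF;
      tb[o] = 3;  // boundary
    }
  }

  for (int i = 1; i <= Lq; ++i) {
    std::swap(H, Hprev);
    std::swap(F, Fprev);
    std::fill(H.begin(), H.end(), NEG_INF);
    std::fill(F.begin(), F.end(), NEG_INF);
    const int j0 = std::max(0, i + lo), j1 = std::min(Lt, i + hi);
    if (j0 > j1) return false;
    int E = NEG_INF;
    const char qc = q[qs + i - 1];
    uint8_t* tbrow = &tb[(size_t)i * W];
    for (int j = j0; j <= j1; ++j) {
      const int o = j - (i + lo);
      uint8_t cell = 0;
      if (j == 0) {
        H[o] = sc.gap_open + sc.gap_extend * i;
        F[o] = H[o];
        E = NEG_INF;
        tbrow[o] = 3;
        continue;
      }
      // F from previous row, same j -> offset o + 1
      int f_open = (o + 1 < W && Hprev[o + 1] > NEG_INF / 2)
                       ? Hprev[o + 1] + sc.gap_open + sc.gap_extend : NEG_INF;
      int f_ext = (o + 1 < W && Fprev[o + 1] > NEG_INF / 2)
                      ? Fprev[o + 1] + sc.gap_extend : NEG_INF;
      int f = f_open;
      if (f_ext > f) { f = f_ext; cell |= 8; }
      F[o] = f;
      // E from same row, previous j -> previous o (E carried in scalar)
      int h_left = (o - 1 >= 0 && j - 1 >= j0 && H[o - 1] > NEG_INF / 2)
                       ? H[o - 1] : NEG_INF;
      int e_open = (h_left > NEG_INF / 2) ? h_left + sc.gap_open + sc.gap_extend : NEG_INF;
      int e_ext = (E > NEG_INF / 2 && j - 1 >= j0) ? E + sc.gap_extend : NEG_INF;
      int e = e_open;
      if (e_ext > e) { e = e_ext; cell |= 4; }
      E = e;
      // H
      const char tc = t[ts + j - 1];
      int sdiag = (Hprev[o] > NEG_INF / 2)
                      ? Hprev[o] + ((qc == tc && qc != 'N') ? sc.match : sc.mismatch)
                      : NEG_INF;
      int h = sdiag;
      uint8_t src = 0;
      if (e > h) { h = e; src = 1; }
      if (f > h) { h = f; src = 2; }
      if (h <= NEG_INF / 2) { tbrow[o] = 0xFF; continue; }
      H[o] = h;
      tbrow[o] = (uint8_t)(cell | src);
    }
  }

  // end cell
  int end_j;
  long best;
  if (fit) {
    end_j = -1;
    best = NEG_INF;
    const int j0 = std::max(0, Lq + lo), j1 = std::min(Lt, Lq + hi);
    for (int j = j0; j <= j1; ++j) {
      int o = j - (Lq + lo);
      if (H[o] > best) { best = H[o]; end_j = j; }
    }
    if (end_j < 0) return false;
  } else {
    end_j = Lt;
    int o = Lt - (Lq + lo);
    if (o < 0 || o >= W || H[o] <= NEG_INF / 2) return false;
    best = H[o];
  }

  // traceback
  std::vector<std::pair<char, int>> rev;
  auto push = [&rev](char op) {
    if (!rev.empty() && rev.back().first == op) rev.back().second++;
    else rev.emplace_back(op, 1);
  };
  int i = Lq, j = end_j;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    if (i == 0) {
      if (fit) break;
      push('D'); --j; continue;
    }
    if (j == 0) { push('I'); --i; continue; }
    const int o = j - (i + lo);
    if (o < 0 || o >= W) return false;
    uint8_t cell = tb[(size_t)i * W + o];
    if (cell == 0xFF) return false;
    if (state == 0) {
      uint8_t src = cell & 3;
      if (src == 0) { push('M'); --i; --j; }
      else if (src == 1) state = 1;
      else if (src == 2) state = 2;
      else {  // boundary row reached with i == 0 handled above
        if (fit) { i = 0; j = 0; break; }
        return false;
      }
    } else if (state == 1) {
      push('D');
      bool ext = (cell & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else {
      push('I');
      bool ext = (cell & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  int lead_t = j;  // unaligned leading target bases in fit mode

  out.ok = true;
  out.qs = qs;
  out.qe = qe;
  out.ts = ts + lead_t;
  out.te = ts + end_j;
  out.score = best;
  out.ops.runs.assign(rev.rbegin(), rev.rend());
  return true;
}

// Left-shift gap runs through homopolymers so equivalent optimal alignments
// produce identical discrepancy coordinates.
static void normalize_gaps(Ops& ops, const std::string& q, const std::string& t,
                           int qs, int ts) {
  auto& r = ops.runs;
  int qp = qs, tp = ts;
  std::vector<std::array<int, 3>> pos;  // start q, start t per run
  for (size_t idx = 0; idx < r.size(); ++idx) {
    if (idx > 0 && r[idx - 1].first == 'M' && r[idx].first != 'M') {
      char op = r[idx].first;
      int len = r[idx].second;
      int shift = 0;
      int maxshift = r[idx - 1].second;
      if (op == 'D') {
        while (shift < maxshift && tp - shift - 1 >= 0 &&
               t[tp - shift - 1] == t[tp + len - shift - 1])
          ++shift;
      } else if (op == 'I') {
        while (shift < maxshift && qp - shift - 1 >= 0 &&
               q[qp - shift - 1] == q[qp + len - shift - 1])
          ++shift;
      }
      if (shift > 0) {
        r[idx - 1].second -= shift;
        // move the shifted M columns to after the gap
        if (idx + 1 < r.size() && r[idx + 1].first == 'M') {
          r[idx + 1].second += shift;
        } else {
          r.insert(r.begin() + idx + 1, std::make_pair('M', shift));
        }
        qp -= shift;
        tp -= shift;
      }
    }
    if (r[idx].first == 'M') { qp += r[idx].second; tp += r[idx].second; }
    else if (r[idx].first == 'D') { tp += r[idx].second; }
    else { qp += r[idx].second; }
  }
  // drop empty runs created by full shifts
  r.erase(std::remove_if(r.begin(), r.end(),
                         [](const std::pair<char, int>& p) { return p.second == 0; }),
          r.end());
}

// Ungapped X-drop extension. Returns extension length.
static int xdrop_extend(const std::string& q, const std::string& t,
                        int qstart, int tstart, int dir, int xdrop,
                        const Scoring& sc, long& score_add) {
  int best = 0, cur = 0, best_len = 0, len = 0;
  int qp = qstart, tp = tstart;
  const int Lq = (int)q.size(), Lt = (int)t.size();
  while (qp >= 0 && tp >= 0 && qp < Lq && tp < Lt) {
    cur += (q[qp] == t[tp] && q[qp] != 'N') ? sc.match : sc.mismatch;
    ++len;
    if (cur > best) { best = cur; best_len = len; }
    if (cur < best - xdrop) break;
    qp += dir;
    tp += dir;
  }
  score_add = best;
  return best_len;
}

struct Anchor {
  int tid;
  int64_t diag;
  int qpos, tpos;
};

// Split a window alignment at score valleys: any internal stretch whose
// running score falls more than split_drop below the preceding maximum
// ends the current piece (Smith-Waterman-like local behaviour on top of
// the global window DP), so a chain that bridged non-homologous sequence
// does not report the bridge as aligned.
static std::vector<AlnResult> split_at_valleys(const AlnResult& res,
                                               const std::string& q,
                                               const std::string& t,
                                               const Scoring& sc,
                                               int split_drop) {
  struct Item { char op; int len; long score; };
  std::vector<Item> items;
  {
    int qp = res.qs, tp = res.ts;
    for (auto& run : res.ops.runs) {
      if (run.first == 'M') {
        for (int x = 0; x < run.second; ++x) {
          bool m = (q[qp + x] == t[tp + x] && q[qp + x] != 'N');
          items.push_back({'M', 1, m ? (long)sc.match : (long)sc.mismatch});
        }
        qp += run.second; tp += run.second;
      } else {
        items.push_back({run.first, run.second,
                         (long)sc.gap_open + (long)sc.gap_extend * run.second});
        if (run.first == 'D') tp += run.second; else qp += run.second;
      }
    }
  }
  // segmentation
  std::vector<std::pair<int, int>> pieces;  // [start, end) item ranges
  long S = 0, best = 0;
  int start = 0, best_end = 0;
  for (int i = 0; i < (int)items.size(); ++i) {
    S += items[i].score;
    if (S > best) { best = S; best_end = i + 1; }
    if (S < best - split_drop) {
      if (best_end > start) pieces.emplace_back(start, best_end);
      start = i + 1;
      S = 0; best = 0; best_end = i + 1;
    }
  }
  if (best_end > start) pieces.emplace_back(start, best_end);

  std::vector<AlnResult> out;
  // prefix q/t offsets per item
  std::vector<int> qoff(items.size() + 1, 0), toff(items.size() + 1, 0);
  for (size_t i = 0; i < items.size(); ++i) {
    qoff[i + 1] = qoff[i] + ((items[i].op == 'D') ? 0 : items[i].len);
    toff[i + 1] = toff[i] + ((items[i].op == 'I') ? 0 : items[i].len);
  }
  for (auto& pc : pieces) {
    int s = pc.first, e = pc.second;
    while (s < e && items[s].op != 'M') ++s;  // no leading/trailing gaps
    while (e > s && items[e - 1].op != 'M') --e;
    if (s >= e) continue;
    AlnResult piece;
    piece.ok = true;
    piece.qs = res.qs + qoff[s];
    piece.ts = res.ts + toff[s];
    piece.qe = res.qs + qoff[e];
    piece.te = res.ts + toff[e];
    long score = 0;
    for (int i = s; i < e; ++i) {
      score += items[i].score;
      if (!piece.ops.runs.empty() && piece.ops.runs.back().first == items[i].op)
        piece.ops.runs.back().second += items[i].len;
      else
        piece.ops.runs.emplace_back(items[i].op, items[i].len);
    }
    piece.score = score;
    out.push_back(piece);
  }
  return out;
}

// Assemble alignment statistics from ops.
static List finish_alignment(const std::string& q, const std::string& t,
                             int tid, char strand, int qlen,
                             const AlnResult& res) {
  int matches = 0, mismatches = 0, qgap = 0, tgap = 0;
  std::vector<std::array<int, 3>> blocks;   // qstart, tstart, len (strand-local)
  std::vector<int> mm_tpos;
  std::vector<std::array<int, 2>> del_runs; // tstart, len
  std::vector<std::array<int, 3>> ins_runs; // tpos, qstart, len
  int qp = res.qs, tp = res.ts;
  for (auto& run : res.ops.runs) {
    if (run.first == 'M') {
      blocks.push_back({qp, tp, run.second});
      for (int x = 0; x < run.second; ++x) {
        if (q[qp + x] == t[tp + x] && q[qp + x] != 'N') ++matches;
        else { ++mismatches; mm_tpos.push_back(tp + x); }
      }
      qp += run.second;
      tp += run.second;
    } else if (run.first == 'D') {
      qgap += run.second;
      del_runs.push_back({tp, run.second});
      tp += run.second;
    } else {
      tgap += run.second;
      ins_runs.push_back({tp, qp, run.second});
      qp += run.second;
    }
  }
  IntegerMatrix bl(blocks.size(), 3), dr(del_runs.size(), 2), ir(ins_runs.size(), 3);
  for (size_t i = 0; i < blocks.size(); ++i)
    for (int j = 0; j < 3; ++j) bl(i, j) = blocks[i][j];
  for (size_t i = 0; i < del_runs.size(); ++i)
    for (int j = 0; j < 2; ++j) dr(i, j) = del_runs[i][j];
  for (size_t i = 0; i < ins_runs.size(); ++i)
    for (int j = 0; j < 3; ++j) ir(i, j) = ins_runs[i][j];
  // plus-strand query interval
  int pq_start = (strand == '+') ? res.qs : qlen - res.qe;
  int pq_end = (strand == '+') ? res.qe : qlen - res.qs;
  return List::create(
      _["tid"] = tid + 1, _["strand"] = std::string(1, strand),
      _["qstart"] = pq_start, _["qend"] = pq_end,
      _["tstart"] = res.ts, _["tend"] = res.te,
      _["blocks"] = bl,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["query_gap_bases"] = qgap, _["target_gap_bases"] = tgap,
      _["score"] = (double)res.score,
      _["mm_tpos"] = wrap(mm_tpos),
      _["del_runs"] = dr, _["ins_runs"] = ir);
}

static void align_one_strand(const std::string& q, char strand,
                             const KmerIndex& idx, const Scoring& sc,
                             int band_width, int min_chain_seeds,
                             int max_hits, int xdrop, int chain_gap,
                             int max_chains, int split_drop,
                             std::vector<List>& out) {
  const int k = idx.k;
  const int qlen_orig = (int)q.size();
  const std::string qq = (strand == '+') ? q : revcomp_str(q);
  const int Lq = (int)qq.size();
  if (Lq < k) return;

  // seed
  std::vector<Anchor> anchors;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  uint64_t code = 0;
  int run = 0;
  for (int i = 0; i < Lq; ++i) {
    int b = base_code(qq[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      int qpos = i - k + 1;
      auto lo = std::lower_bound(idx.codes.begin(), idx.codes.end(), code);
      auto hi = std::upper_bound(lo, idx.codes.end(), code);
      if (hi - lo == 0 || (int)(hi - lo) > max_hits) continue;
      for (auto it = lo; it != hi; ++it) {
        uint64_t tp = idx.tidpos[it - idx.codes.begin()];
        int tid = (int)(tp >> 32);
        int tpos = (int)(tp & 0xffffffffULL);
        anchors.push_back({tid, (int64_t)tpos - qpos, qpos, tpos});
      }
    }
  }
  if (anchors.empty()) return;

  // When the band covers the whole query, run the exact (unbanded) fit DP
  // against each seeded target small enough for a full matrix; larger
  // targets fall through to the chained banded path.
  int band_eff = band_width;
  if (band_width >= Lq) {
    std::vector<int> tids;
    for (auto& a : anchors) tids.push_back(a.tid);
    std::sort(tids.begin(), tids.end());
    tids.erase(std::unique(tids.begin(), tids.end()), tids.end());
    std::vector<bool> fitted(idx.seqs.size(), false);
    for (int tid : tids) {
      const std::string& t = idx.seqs[tid];
      const double cells = (double)(Lq + 1) * ((double)t.size() + Lq + 1);
      if (cells > 6e7) continue;
      AlnResult res;
      if (!banded_dp(qq, t, 0, Lq, 0, (int)t.size(), -Lq, (int)t.size(), sc,
                     true, res))
        continue;
      fitted[tid] = true;
      normalize_gaps(res.ops, qq, t, res.qs, res.ts);
      out.push_back(finish_alignment(qq, t, tid, strand, qlen_orig, res));
    }
    anchors.erase(std::remove_if(anchors.begin(), anchors.end(),
                                 [&fitted](const Anchor& a) { return fitted[a.tid]; }),
                  anchors.end());
    if (anchors.empty()) return;
    band_eff = std::min(band_width, 256);
  }

  // cluster anchors by (tid, diagonal window)
  std::sort(anchors.begin(), anchors.end(), [](const Anchor& a, const Anchor& b) {
    if (a.tid != b.tid) return a.tid < b.tid;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qpos < b.qpos;
  });
  std::vector<std::pair<size_t, size_t>> clusters;
  size_t start = 0;
  for (size_t i = 1; i <= anchors.size(); ++i) {
    bool brk = (i == anchors.size()) || anchors[i].tid != anchors[start].tid ||
               anchors[i].diag - anchors[start].diag > band_eff;
    if (brk) { clusters.emplace_back(start, i); start = i; }
  }

  // build all candidate chains, then evaluate the largest ones first so a
  // cap on evaluated chains never drops the dominant alignment
  std::vector<std::vector<Anchor>> all_chains;
  for (auto& cl : clusters) {
    std::vector<Anchor> ch(anchors.begin() + cl.first, anchors.begin() + cl.second);
    std::sort(ch.begin(), ch.end(), [](const Anchor& a, const Anchor& b) {
      if (a.qpos != b.qpos) return a.qpos < b.qpos;
      return a.tpos < b.tpos;
    });
    // monotone filter + split on large query gaps
    std::vector<Anchor> cur;
    for (auto& a : ch) {
      if (cur.empty()) { cur.push_back(a); continue; }
      const Anchor& p = cur.back();
      if (a.qpos <= p.qpos || a.tpos <= p.tpos) continue;
      if (a.qpos - p.qpos > chain_gap) {
        if ((int)cur.size() >= min_chain_seeds) all_chains.push_back(cur);
        cur.clear();
      }
      cur.push_back(a);
    }
    if ((int)cur.size() >= min_chain_seeds) all_chains.push_back(cur);
  }
  std::stable_sort(all_chains.begin(), all_chains.end(),
                   [](const std::vector<Anchor>& a, const std::vector<Anchor>& b) {
                     return a.size() > b.size();
                   });
  if ((int)all_chains.size() > max_chains) all_chains.resize(max_chains);
  {
    for (auto& chain : all_chains) {
      const Anchor& a0 = chain.front();
      const Anchor& a1 = chain.back();
      int qs = a0.qpos, qe = a1.qpos + k, ts = a0.tpos, te = a1.tpos + k;
      // window diagonal range
      int wlo = 0, whi = 0;
      for (auto& a : chain) {
        int wd = (int)((a.tpos - ts) - (a.qpos - qs));
        wlo = std::min(wlo, wd);
        whi = std::max(whi, wd);
      }
      int pad = std::max(8, band_eff / 2);
      const std::string& t = idx.seqs[a0.tid];
      AlnResult res;
      if (!banded_dp(qq, t, qs, qe, ts, te, wlo - pad, whi + pad, sc, false, res))
        continue;
      // extend ends (ungapped, X-drop)
      long addl = 0, addr = 0;
      int el = xdrop_extend(qq, t, res.qs - 1, res.ts - 1, -1, xdrop, sc, addl);
      int er = xdrop_extend(qq, t, res.qe, res.te, +1, xdrop, sc, addr);
      if (el > 0) {
        res.qs -= el; res.ts -= el;
        res.ops.runs.insert(res.ops.runs.begin(), std::make_pair('M', el));
      }
      if (er > 0) {
        res.qe += er; res.te += er;
        res.ops.runs.emplace_back('M', er);
      }
      // merge adjacent M runs
      Ops merged;
      for (auto& r : res.ops.runs) {
        if (!merged.runs.empty() && merged.runs.back().first == r.first)
          merged.runs.back().second += r.second;
        else
          merged.runs.push_back(r);
      }
      res.ops = merged;
      res.score += addl + addr;
      for (AlnResult& piece : split_at_valleys(res, qq, t, sc, split_drop)) {
        normalize_gaps(piece.ops, qq, t, piece.qs, piece.ts);
        out.push_back(finish_alignment(qq, t, a0.tid, strand, qlen_orig, piece));
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector queries, SEXP xp, List params) {
  XPtr<KmerIndex> idx(xp);
  Scoring sc;
  sc.match = as<int>(params["match"]);
  sc.mismatch = as<int>(params["mismatch"]);
  sc.gap_open = as<int>(params["gap_open"]);
  sc.gap_extend = as<int>(params["gap_extend"]);
  const int band_width = as<int>(params["band_width"]);
  const int min_chain_seeds = as<int>(params["min_chain_seeds"]);
  const int max_hits = as<int>(params["max_hits"]);
  const int xdrop = as<int>(params["xdrop"]);
  const int chain_gap = as<int>(params["chain_gap"]);
  const int max_chains = as<int>(params["max_chains"]);
  const int split_drop = as<int>(params["split_drop"]);
  const double min_identity = as<double>(params["min_identity"]);
  const int min_align_length = as<int>(params["min_align_length"]);

  List out(queries.size());
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    std::vector<List> alns;
    if ((int)q.size() >= idx->k) {
      align_one_strand(q, '+', *idx, sc, band_width, min_chain_seeds, max_hits,
                       xdrop, chain_gap, max_chains, split_drop, alns);
      align_one_strand(q, '-', *idx, sc, band_width, min_chain_seeds, max_hits,
                       xdrop, chain_gap, max_chains, split_drop, alns);
    }
    // filter + deterministic sort by score desc, matches desc, tid, tstart
    std::vector<std::pair<std::array<double, 4>, int>> keys;
    for (size_t i = 0; i < alns.size(); ++i) {
      List a = alns[i];
      int m = as<int>(a["matches"]);
      int mm = as<int>(a["mismatches"]);
      int qg = as<int>(a["query_gap_bases"]);
      int tg = as<int>(a["target_gap_bases"]);
      int cols = m + mm;
      double denom = m + mm + qg + tg;
      double ident = denom > 0 ? m / denom : 0.0;
      if (cols < min_align_length) continue;
      if (ident < min_identity) continue;
      keys.push_back({{-as<double>(a["score"]), (double)-m,
                       (double)as<int>(a["tid"]), (double)as<int>(a["tstart"])},
                      (int)i});
    }
    std::sort(keys.begin(), keys.end());
    List res(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) res[i] = alns[keys[i].second];
    out[qi] = res;
  }
  return out;
}
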