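#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Local alignment machinery shared by the segment caller and the seeded V
// annotator. Scores: match > 0, mismatch/gap < 0. Bands are expressed on the
// diagonal d = i - j (query index - ref index). Alignments are trimmed so
// that both ends terminate in END_RUN consecutive matches: segment ends are
// biological boundaries (exonuclease trimming, junction), and untrimmed
// local alignments would extend past them on chance matches.

namespace {

constexpr int END_RUN = 6;

struct LocalAln {
  int score = 0;
  int qs = 0, qe = 0, rs = 0, re = 0;   // 1-based inclusive, 0 = empty
  int nsub = 0, nins = 0, ndel = 0;     // ins/del relative to the query
  int nmatch = 0;
  std::string muts;                     // "refpos:base;..." substitutions
};

struct Workspace {
  std::vector<int> prev, cur;
  std::vector<int> Mp, Xp, Yp, Mc, Xc, Yc;
  std::vector<uint8_t> dir;
  std::vector<uint8_t> ops;             // traceback path (1 diag, 2 up, 3 left)
};

Workspace& ws() {
  static Workspace w;
  return w;
}

// Banded local alignment of query q vs reference r, diagonals in [dlo, dhi].
LocalAln sw_banded(const char* q, int n, const char* r, int m,
                   int dlo, int dhi, int match, int mismatch, int gap) {
  LocalAln out;
  if (n <= 0 || m <= 0) return out;
  dlo = std::max(dlo, 1 - m);
  dhi = std::min(dhi, n - 1);
  if (dlo > dhi) return out;
  const int W = dhi - dlo + 1;
  Workspace& w = ws();
  if ((int)w.prev.size() < W + 2) { w.prev.resize(W + 2); w.cur.resize(W + 2); }
  if ((int)w.dir.size() < (m + 1) * W) w.dir.resize((size_t)(m + 1) * W);
  int* prev = w.prev.data() + 1;        // index -1..W
  int* cur = w.cur.data() + 1;
  std::fill(w.prev.begin(), w.prev.begin() + W + 2, 0);
  std::fill(w.cur.begin(), w.cur.begin() + W + 2, 0);
  uint8_t* dirbase = w.dir.data();
  int best = 0, bj = 0, bc = 0;
  for (int j = 1; j <= m; ++j) {
    const char rb = r[j - 1];
    const int ilo = std::max(1, j + dlo), ihi = std::min(n, j + dhi);
    if (ilo > ihi) { std::swap(prev, cur); continue; }
    const int clo = ilo - j - dlo, chi = ihi - j - dlo;
    uint8_t* dj = dirbase + (size_t)j * W;
    cur[clo - 1] = 0;                   // out-of-band left neighbour
    const char* qp = q + ilo - 1;
    for (int c = clo; c <= chi; ++c, ++qp) {
      const char qb = *qp;
      int s = prev[c] + ((qb == rb && qb != 'n') ? match : mismatch);
      uint8_t d = 1;
      int v = prev[c + 1] + gap;        // up: ref consumed alone (deletion)
      if (v > s) { s = v; d = 2; }
      v = cur[c - 1] + gap;             // left: query consumed alone (insertion)
      if (v > s) { s = v; d = 3; }
      if (s <= 0) { s = 0; d = 0; }
      cur[c] = s;
      dj[c] = d;
      if (s > best) { best = s; bj = j; bc = c; }
    }
    cur[clo - 1] = 0;
    if (chi + 1 <= W) cur[chi + 1] = 0; // stale cells from older rows
    // boundary dirs must be 0: the dir matrix is reused across alignments
    if (clo - 1 >= 0) dj[clo - 1] = 0;
    if (chi + 1 < W) dj[chi + 1] = 0;
    std::swap(prev, cur);
  }
  if (best <= 0) return out;
  // traceback: collect the path, then trim ends to runs of END_RUN matches
  std::vector<uint8_t>& ops = w.ops;
  ops.clear();
  std::vector<char> qchar;              // query base per op (diag/left)
  qchar.clear();
  int j = bj, c = bc;
  int i = c + j + dlo;
  const int qe0 = i, re0 = j;
  while (j >= 1) {
    uint8_t d = dirbase[(size_t)j * W + c];
    if (d == 0) break;
    ops.push_back(d);
    if (d == 1) { qchar.push_back(q[i - 1]); --i; --j; }
    else if (d == 2) { qchar.push_back(0); --j; ++c; }
    else { qchar.push_back(q[i - 1]); --i; --c; }
  }
  // ops/qchar run from alignment end backwards; alignment start = (i+1, j+1)
  const int qs0 = i + 1, rs0 = j + 1;
  const int len = ops.size();
  // match mask along the path, in forward order
  std::vector<char> fwd_ops(len);
  std::vector<char> fwd_q(len);
  for (int t = 0; t < len; ++t) {
    fwd_ops[t] = ops[len - 1 - t];
    fwd_q[t] = qchar[len - 1 - t];
  }
  std::vector<char> is_match(len, 0);
  {
    int ri = rs0;
    for (int t = 0; t < len; ++t) {
      if (fwd_ops[t] == 1) {
        is_match[t] = (fwd_q[t] == r[ri - 1] && fwd_q[t] != 'n');
        ++ri;
      } else if (fwd_ops[t] == 2) ++ri;
    }
  }
  auto run_starts_at = [&](int t) {
    if (t + END_RUN > len) return false;
    for (int z = 0; z < END_RUN; ++z) if (!is_match[t + z]) return false;
    return true;
  };
  int tstart = 0;
  while (tstart < len && !run_starts_at(tstart)) ++tstart;
  if (tstart >= len) return out;        // no anchored segment
  int tend = len - 1;
  auto run_ends_at = [&](int t) {
    if (t - END_RUN + 1 < 0) return false;
    for (int z = 0; z < END_RUN; ++z) if (!is_match[t - z]) return false;
    return true;
  };
  while (tend >= tstart && !run_ends_at(tend)) --tend;
  if (tend < tstart) return out;
  // recompute coordinates and stats over the trimmed window [tstart, tend]
  int qi2 = qs0, ri2 = rs0, score = 0;
  std::string ms;
  for (int t = 0; t < len && t <= tend; ++t) {
    if (t == tstart) { out.qs = qi2; out.rs = ri2; }
    if (fwd_ops[t] == 1) {
      if (t >= tstart) {
        if (is_match[t]) { out.nmatch++; score += match; }
        else {
          out.nsub++; score += mismatch;
          if (!ms.empty()) ms += ";";
          ms += std::to_string(ri2) + ":" + fwd_q[t];
        }
      }
      ++qi2; ++ri2;
    } else if (fwd_ops[t] == 2) {
      if (t >= tstart) { out.ndel++; score += gap; }
      ++ri2;
    } else {
      if (t >= tstart) { out.nins++; score += gap; }
      ++qi2;
    }
  }
  out.qe = qi2 - 1; out.re = ri2 - 1;
  out.score = score;
  out.muts = ms;
  return out;
}

List aln_fields(int nq) {
  return List::create(
    _["call_idx"] = CharacterVector(nq),
    _["score"] = IntegerVector(nq), _["q_start"] = IntegerVector(nq),
    _["q_end"] = IntegerVector(nq), _["r_start"] = IntegerVector(nq),
    _["r_end"] = IntegerVector(nq), _["nsub"] = IntegerVector(nq),
    _["nins"] = IntegerVector(nq), _["ndel"] = IntegerVector(nq),
    _["span"] = IntegerVector(nq), _["muts"] = CharacterVector(nq));
}

void store_aln(List& res, int qi, const std::string& calls, const LocalAln& a) {
  CharacterVector call_idx = res["call_idx"], muts = res["muts"];
  IntegerVector score = res["score"], q_start = res["q_start"],
    q_end = res["q_end"], r_start = res["r_start"], r_end = res["r_end"],
    nsub = res["nsub"], nins = res["nins"], ndel = res["ndel"],
    span = res["span"];
  call_idx[qi] = calls;
  score[qi] = a.score;
  q_start[qi] = a.qs; q_end[qi] = a.qe;
  r_start[qi] = a.rs; r_end[qi] = a.re;
  nsub[qi] = a.nsub; nins[qi] = a.nins; ndel[qi] = a.ndel;
  span[qi] = (a.re >= a.rs && a.re > 0) ? a.re - a.rs + 1 : 0;
  muts[qi] = a.muts;
}

inline int enc(char b) {
  switch (b) { case 'a': case 'A': return 0; case 'c': case 'C': return 1;
               case 'g': case 'G': return 2; case 't': case 'T': return 3; }
  return -1;
}

}  // namespace

// Exhaustive banded local alignment of every query against every reference.
// Calls = all references tying on the best score with ref span >= min_overlap.
// dlo/dhi bound the query-minus-reference diagonal (pass wide bounds for a
// full scan).
// [[Rcpp::export]]
List cpp_align_exhaustive(CharacterVector queries, CharacterVector refs,
                          int min_overlap, int match, int mismatch, int gap,
                          int dlo = -100000, int dhi = 100000) {
  const int nq = queries.size(), nr = refs.size();
  List res = aln_fields(nq);
  std::vector<std::string> rs(nr);
  for (int k = 0; k < nr; ++k) rs[k] = as<std::string>(refs[k]);
  for (int qi = 0; qi < nq; ++qi) {
    std::string qs = as<std::string>(queries[qi]);
    LocalAln best; int bestscore = -1; std::string calls;
    for (int k = 0; k < nr; ++k) {
      LocalAln a = sw_banded(qs.c_str(), qs.size(), rs[k].c_str(),
                             rs[k].size(), dlo, dhi, match, mismatch, gap);
      if (a.re - a.rs + 1 < min_overlap || a.re == 0) continue;
      if (a.score > bestscore) {
        bestscore = a.score; best = a; calls = std::to_string(k + 1);
      } else if (a.score == bestscore) {
        calls += "," + std::to_string(k + 1);
      }
    }
    if (bestscore >= 0) store_aln(res, qi, calls, best);
  }
  return res;
}

// Seeded, banded V-segment annotator. A k-mer index over the references
// proposes (reference, diagonal) candidates per read; only candidates are
// aligned, banded around their voted diagonal. Identical references receive
// identical votes and scores and are all reported.
// [[Rcpp::export]]
List cpp_annotate_v(CharacterVector reads, CharacterVector refs,
                    int k, int step, int max_cand, int band, int min_votes,
                    int min_overlap, int match, int mismatch, int gap,
                    int max_read_scan) {
  const int nq = reads.size(), nr = refs.size();
  List res = aln_fields(nq);
  std::vector<std::string> rs(nr);
  for (int t = 0; t < nr; ++t) rs[t] = as<std::string>(refs[t]);
  // k-mer index: key -> packed (ref << 11 | pos)
  std::unordered_map<uint32_t, std::vector<uint32_t>> idx;
  idx.reserve(1 << 17);
  const uint32_t mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  for (int t = 0; t < nr; ++t) {
    const std::string& s = rs[t];
    uint32_t key = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int e = enc(s[p]);
      if (e < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | e) & mask;
      if (++run >= k) idx[key].push_back(((uint32_t)t << 11) | (uint32_t)(p - k + 1));
    }
  }
  std::unordered_map<uint64_t, int> votes;
  std::vector<int> tot(nr), bestd(nr), bestc(nr);
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(reads[qi]);
    const int n = q.size(), scan = std::min(n, max_read_scan);
    votes.clear();
    std::fill(tot.begin(), tot.end(), 0);
    std::fill(bestc.begin(), bestc.end(), 0);
    uint32_t key = 0; int run = 0;
    for (int p = 0; p < scan; ++p) {
      int e = enc(q[p]);
      if (e < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | e) & mask;
      ++run;
      int start = p - k + 1;
      if (run < k || (start % step) != 0) continue;
      auto it = idx.find(key);
      if (it == idx.end()) continue;
      for (uint32_t pk : it->second) {
        int t = pk >> 11, rp = pk & 0x7FF;
        int d = start - rp;
        uint64_t vk = ((uint64_t)t << 32) | (uint32_t)(d + 100000);
        int c = ++votes[vk];
        tot[t]++;
        if (c > bestc[t]) { bestc[t] = c; bestd[t] = d; }
      }
    }
    // candidate selection
    std::vector<std::pair<int, int>> cand;  // (-votes, ref)
    int top = 0;
    for (int t = 0; t < nr; ++t) if (tot[t] > top) top = tot[t];
    if (top < min_votes) continue;          // no call
    const int thresh = std::max(min_votes, top / 2);
    for (int t = 0; t < nr; ++t)
      if (tot[t] >= thresh) cand.push_back({-tot[t], t});
    std::sort(cand.begin(), cand.end());
    if ((int)cand.size() > max_cand) {
      int cut = -cand[max_cand - 1].first;  // keep equal-vote overflow
      int end = max_cand;
      while (end < (int)cand.size() && -cand[end].first == cut) ++end;
      cand.resize(end);
    }
    LocalAln best; int bestscore = -1;
    std::vector<int> tied;
    for (auto& cv : cand) {
      int t = cv.second;
      LocalAln a = sw_banded(q.c_str(), n, rs[t].c_str(), rs[t].size(),
                             bestd[t] - band, bestd[t] + band,
                             match, mismatch, gap);
      if (a.re - a.rs + 1 < min_overlap || a.re == 0) continue;
      if (a.score > bestscore) { bestscore = a.score; best = a; tied.assign(1, t + 1); }
      else if (a.score == bestscore) tied.push_back(t + 1);
    }
    if (bestscore < 0) continue;
    std::sort(tied.begin(), tied.end());
    std::string calls;
    for (size_t z = 0; z < tied.size(); ++z) {
      if (z) calls += ",";
      calls += std::to_string(tied[z]);
    }
    store_aln(res, qi, calls, best);
  }
  return res;
}

// Banded global alignment (affine gaps, cost-minimising) of each read's
// constant segment against a reference exon scaffold, with free tail gaps on
// either sequence. Read insertions are removed; read deletions are filled
// with the reference base and flagged low-confidence.
// [[Rcpp::export]]
List cpp_correct_c(CharacterVector reads, std::string ref, int band,
                   int mismatch, int gap_open, int gap_ext) {
  const int nq = reads.size(), m = ref.size();
  const int INF = 1 << 27;
  const int W = 2 * band + 1;
  CharacterVector corrected(nq), conf(nq);
  NumericVector identity(nq);
  IntegerVector nsub(nq), nins(nq), ndel(nq), reflen(nq);
  Workspace& w = ws();
  if ((int)w.Mp.size() < W + 2) {
    w.Mp.resize(W + 2); w.Xp.resize(W + 2); w.Yp.resize(W + 2);
    w.Mc.resize(W + 2); w.Xc.resize(W + 2); w.Yc.resize(W + 2);
  }
  if ((int)w.dir.size() < (m + 1) * W) w.dir.resize((size_t)(m + 1) * W);
  int *Mp = w.Mp.data() + 1, *Xp = w.Xp.data() + 1, *Yp = w.Yp.data() + 1;
  int *Mc = w.Mc.data() + 1, *Xc = w.Xc.data() + 1, *Yc = w.Yc.data() + 1;
  uint8_t* dirbase = w.dir.data();
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(reads[qi]);
    const int n = q.size();
    if (n == 0) { corrected[qi] = ""; conf[qi] = ""; identity[qi] = 0.0; continue; }
    for (int c = -1; c <= W; ++c) { Mp[c] = Xp[c] = Yp[c] = INF; }
    Mp[band] = 0;                       // (i=0, j=0)
    for (int c = band + 1; c < W; ++c) {  // row 0: pure insertions
      int i = c - band;
      if (i > n) break;
      Yp[c] = gap_open + gap_ext * (i - 1);
    }
    int bend = INF, bj = -1, bc = -1, bmat = -1;
    for (int j = 1; j <= m; ++j) {
      const char rb = ref[j - 1];
      uint8_t* dj = dirbase + (size_t)j * W;
      const int ilo = std::max(0, j - band), ihi = std::min(n, j + band);
      const int clo = ilo - j + band, chi = ihi - j + band;
      Mc[clo - 1] = Xc[clo - 1] = Yc[clo - 1] = INF;
      const bool lastrow = (j == m);
      for (int c = clo; c <= chi; ++c) {
        const int i = c + j - band;
        // X: ref consumed alone, from (i, j-1) => prev row, c+1
        int xm = Mp[c + 1] + gap_open, xx = Xp[c + 1] + gap_ext;
        uint8_t d = 0;
        int X;
        if (xm <= xx) X = xm; else { X = xx; d |= 4; }
        Xc[c] = X;
        // Y: read consumed alone, from (i-1, j) => same row, c-1
        int ym = Mc[c - 1] + gap_open, yy = Yc[c - 1] + gap_ext;
        int Y;
        if (ym <= yy) Y = ym; else { Y = yy; d |= 8; }
        Yc[c] = Y;
        // M: consume pair, from (i-1, j-1) => prev row, same c
        int M = INF;
        if (i >= 1) {
          int base = Mp[c];             // src bits 0-1: 0=M, 1=X, 2=Y
          uint8_t src = 0;
          if (Xp[c] < base) { base = Xp[c]; src = 1; }
          if (Yp[c] < base) { base = Yp[c]; src = 2; }
          if (base < INF) {
            M = base + ((q[i - 1] == rb && q[i - 1] != 'n') ? 0 : mismatch);
            d |= src;
          }
        }
        Mc[c] = M;
        dj[c] = d;
        if (lastrow || i == n) {
          int v = std::min(M, std::min(X, Y));
          if (v < bend) {
            bend = v; bj = j; bc = c;
            bmat = (v == M) ? 0 : (v == X ? 1 : 2);
          }
        }
      }
      Mc[clo - 1] = Xc[clo - 1] = Yc[clo - 1] = INF;
      if (chi + 1 <= W) { Mc[chi + 1] = Xc[chi + 1] = Yc[chi + 1] = INF; }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    if (bj < 0) { corrected[qi] = ""; conf[qi] = ""; identity[qi] = 0.0; continue; }
    // traceback from (bj, bc, bmat) to (0, 0)
    std::string cor, cf;
    cor.reserve(bj); cf.reserve(bj);
    int j = bj, c = bc, mat = bmat;
    int i = c + j - band;
    int sub = 0, insn = 0, del = 0, matches = 0;
    while (j > 0 || i > 0) {
      uint8_t d = dirbase[(size_t)j * W + c];
      if (mat == 0) {
        if (i <= 0 || j <= 0) break;
        bool okm = (q[i - 1] == ref[j - 1]) && q[i - 1] != 'n';
        cor.push_back(q[i - 1]); cf.push_back('0');
        if (okm) matches++; else sub++;
        mat = d & 3; --i; --j;
      } else if (mat == 1) {
        if (j <= 0) break;
        cor.push_back(ref[j - 1]); cf.push_back('1');
        del++;
        mat = (d & 4) ? 1 : 0; --j; ++c;
      } else {
        if (i <= 0) break;
        insn++;
        mat = (d & 8) ? 2 : 0; --i; --c;
      }
    }
    std::reverse(cor.begin(), cor.end());
    std::reverse(cf.begin(), cf.end());
    corrected[qi] = cor; conf[qi] = cf;
    reflen[qi] = bj;
    identity[qi] = bj > 0 ? (double)matches / (double)bj : 0.0;
    nsub[qi] = sub; nins[qi] = insn; ndel[qi] = del;
  }
  return List::create(_["corrected"] = corrected, _["conf"] = conf,
                      _["identity"] = identity, _["nsub"] = nsub,
                      _["nins"] = nins, _["ndel"] = ndel,
                      _["ref_cov"] = reflen);
}

// D-segment call: longest ungapped exact run between each junction window and
// each D reference; calls require run >= min_run, ties reported together.
// [[Rcpp::export]]
List cpp_call_d(CharacterVector windows, CharacterVector drefs, int min_run) {
  const int nq = windows.size(), nr = drefs.size();
  CharacterVector call_idx(nq);
  IntegerVector runlen(nq);
  std::vector<std::string> rs(nr);
  for (int t = 0; t < nr; ++t) rs[t] = as<std::string>(drefs[t]);
  for (int qi = 0; qi < nq; ++qi) {
    std::string wd = as<std::string>(windows[qi]);
    const int n = wd.size();
    if (n == 0) continue;
    int best = 0; std::vector<int> tied;
    for (int t = 0; t < nr; ++t) {
      const std::string& r = rs[t];
      const int m = r.size();
      int loc = 0;
      for (int off = -(m - 1); off <= n - 1; ++off) {
        int run = 0;
        for (int j = std::max(0, -off); j < m && off + j < n; ++j) {
          if (r[j] == wd[off + j] && r[j] != 'n') { if (++run > loc) loc = run; }
          else run = 0;
        }
      }
      if (loc > best) { best = loc; tied.assign(1, t + 1); }
      else if (loc == best && loc > 0) tied.push_back(t + 1);
    }
    if (best >= min_run) {
      std::string calls;
      for (size_t z = 0; z < tied.size(); ++z) {
        if (z) calls += ",";
        calls += std::to_string(tied[z]);
      }
      call_idx[qi] = calls; runlen[qi] = best;
    }
  }
  return List::create(_["call_idx"] = call_idx, _["run"] = runlen);
}

// PacBio-like error model: per-base substitutions plus single-base
// insertions/deletions at homopolymer runs (length >= 2) of the input.
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
List cpp_seq_errors(CharacterVector seqs, double sub_rate, double hp_rate) {
  const int nq = seqs.size();
  CharacterVector out(nq), sub_pos(nq);
  IntegerVector nsub(nq), nins(nq), ndel(nq);
  const char bases[4] = {'a', 'c', 'g', 't'};
  for (int qi = 0; qi < nq; ++qi) {
    std::string s = as<std::string>(seqs[qi]);
    const int n = s.size();
    std::string sp;
    int ns = 0;
    if (sub_rate > 0) {
      for (int p = 0; p < n; ++p) {
        if (unif_rand() < sub_rate) {
          char orig = s[p], nb = orig;
          while (nb == orig) nb = bases[(int)(unif_rand() * 4) & 3];
          s[p] = nb; ns++;
          if (!sp.empty()) sp += ";";
          sp += std::to_string(p + 1);
        }
      }
    }
    int ni = 0, nd = 0;
    if (hp_rate > 0) {
      std::string r;
      r.reserve(n + 4);
      int p = 0;
      while (p < n) {
        int e = p;
        while (e + 1 < n && s[e + 1] == s[p]) ++e;
        int len = e - p + 1;
        int emit = len;
        if (len >= 2 && unif_rand() < hp_rate) {
          if (unif_rand() < 0.5) { emit = len + 1; ni++; }
          else { emit = len - 1; nd++; }
        }
        r.append(emit, s[p]);
        p = e + 1;
      }
      s = r;
    }
    out[qi] = s; sub_pos[qi] = sp;
    nsub[qi] = ns; nins[qi] = ni; ndel[qi] = nd;
  }
  return List::create(_["seq"] = out, _["sub_pos"] = sub_pos,
                      _["nsub"] = nsub, _["nins"] = nins, _["ndel"] = ndel);
}
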