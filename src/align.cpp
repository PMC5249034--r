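// Seed-and-extend local alignment core and read-pileup consensus.
//
// The aligner finds maximal exact word matches between query and subject,
// chains them into diagonal clusters, and runs a banded affine-gap local
// Smith-Waterman (with traceback) over the rectangle each cluster spans.
// Scores: match/mismatch per base, a gap of length L costs open + L*ext.
// All coordinates are 0-based half-open; strand handling lives in R.

#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

namespace {

const int NEG = -1000000000;

struct Scoring {
  int match;     // > 0
  int mismatch;  // < 0
  int gap_open;  // > 0 penalty, charged once per gap
  int gap_ext;   // > 0 penalty, charged per gap position
};

inline int b2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

struct Run { int q0, s0, len; };

// Maximal exact-match runs of word hits, merged along diagonals.
void seed_runs(const std::string& q, const std::string& s, int w,
               int max_occ, std::vector<Run>& runs) {
  const int qn = (int)q.size(), sn = (int)s.size();
  if (qn < w || sn < w) return;
  const uint64_t mask = (1ULL << (2 * w)) - 1;

  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve((size_t)sn);
  uint64_t h = 0; int valid = 0;
  for (int i = 0; i < sn; ++i) {
    int c = b2(s[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask; ++valid;
    if (valid >= w) idx[h].push_back(i - w + 1);
  }

  std::vector<std::pair<int64_t, int>> hits;  // (diagonal, query pos)
  h = 0; valid = 0;
  for (int i = 0; i < qn; ++i) {
    int c = b2(q[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask; ++valid;
    if (valid >= w) {
      auto it = idx.find(h);
      if (it == idx.end()) continue;
      if ((int)it->second.size() > max_occ) continue;
      int qp = i - w + 1;
      for (int sp : it->second) hits.push_back({(int64_t)sp - qp, qp});
    }
  }
  std::sort(hits.begin(), hits.end());

  size_t k = 0;
  while (k < hits.size()) {
    int64_t d = hits[k].first;
    int q0 = hits[k].second, qe = q0 + w;
    size_t j = k + 1;
    // overlapping/adjacent word hits on one diagonal form one exact run
    while (j < hits.size() && hits[j].first == d && hits[j].second <= qe) {
      qe = std::max(qe, hits[j].second + w);
      ++j;
    }
    runs.push_back({q0, (int)(q0 + d), qe - q0});
    k = j;
  }
}

struct Cluster {
  int qlo, qhi, slo, shi;
  int64_t dmin, dmax;
  long total;
};

std::vector<Cluster> cluster_runs(std::vector<Run>& runs,
                                  int diag_tol, int chain_gap) {
  std::vector<Cluster> cl;
  std::sort(runs.begin(), runs.end(), [](const Run& a, const Run& b) {
    if (a.s0 != b.s0) return a.s0 < b.s0;
    return a.q0 < b.q0;
  });
  for (const Run& r : runs) {
    int64_t d = (int64_t)r.s0 - r.q0;
    bool placed = false;
    int lo = std::max(0, (int)cl.size() - 512);  // bounded back-scan
    for (int ci = (int)cl.size() - 1; ci >= lo; --ci) {
      Cluster& c = cl[ci];
      if (r.s0 - c.shi > chain_gap) continue;
      if (d >= c.dmin - diag_tol && d <= c.dmax + diag_tol &&
          r.q0 >= c.qlo - diag_tol && r.q0 - c.qhi <= chain_gap) {
        c.qlo = std::min(c.qlo, r.q0);
        c.qhi = std::max(c.qhi, r.q0 + r.len);
        c.slo = std::min(c.slo, r.s0);
        c.shi = std::max(c.shi, r.s0 + r.len);
        c.dmin = std::min(c.dmin, d);
        c.dmax = std::max(c.dmax, d);
        c.total += r.len;
        placed = true;
        break;
      }
    }
    if (!placed)
      cl.push_back({r.q0, r.q0 + r.len, r.s0, r.s0 + r.len, d, d, (long)r.len});
  }
  return cl;
}

struct Aln {
  int score = 0, q_start = 0, q_end = 0, s_start = 0, s_end = 0;
  int matches = 0, length = 0;
};

// Banded local affine SW over rows [qlo,qhi) x cols [slo,shi), restricted to
// diagonals j - i in [dmin, dmax]. Returns best local alignment in the band.
bool band_sw(const std::string& q, const std::string& s, const Scoring& sc,
             int qlo, int qhi, int slo, int shi, int64_t dmin, int64_t dmax,
             Aln& out) {
  const int band = (int)(dmax - dmin) + 1;
  const int nrow = qhi - qlo;
  if (band <= 0 || nrow <= 0 || slo >= shi) return false;
  if ((double)band * nrow > 6e8) return false;  // refuse absurd bands

  std::vector<int> Hp(band, 0), Hc(band, 0), Fp(band, NEG), Fc(band, NEG);
  std::vector<int> Ec(band, NEG);
  std::vector<uint8_t> tb((size_t)nrow * band, 0);

  int best = 0, bi = -1, bo = -1;
  for (int r = 0; r < nrow; ++r) {
    const int i = qlo + r;
    const int qb = b2(q[i]);
    for (int o = 0; o < band; ++o) {
      int64_t j64 = (int64_t)i + dmin + o;
      if (j64 < slo || j64 >= shi) {
        Hc[o] = 0; Ec[o] = NEG; Fc[o] = NEG;
        tb[(size_t)r * band + o] = 0;
        continue;
      }
      const int j = (int)j64;

      int e = NEG; uint8_t eb = 0;  // gap consuming subject (left cell)
      if (o > 0) {
        int eo = Hc[o - 1] - sc.gap_open - sc.gap_ext;
        int ee = Ec[o - 1] - sc.gap_ext;
        if (ee > eo) { e = ee; eb = 1; } else e = eo;
      }
      int f = NEG; uint8_t fb = 0;  // gap consuming query (upper cell)
      if (r > 0 && o + 1 < band) {
        int fo = Hp[o + 1] - sc.gap_open - sc.gap_ext;
        int fe = Fp[o + 1] - sc.gap_ext;
        if (fe > fo) { f = fe; fb = 1; } else f = fo;
      }
      int hprev = (r > 0) ? Hp[o] : 0;  // virtual 0 = fresh local start
      int sb = b2(s[j]);
      int dg = hprev + ((qb >= 0 && qb == sb) ? sc.match : sc.mismatch);

      int hv = 0; uint8_t hb = 0;
      if (dg >= e && dg >= f && dg > 0) { hv = dg; hb = 1; }
      else if (e >= f && e > 0)         { hv = e;  hb = 2; }
      else if (f > 0)                   { hv = f;  hb = 3; }

      Hc[o] = hv; Ec[o] = e; Fc[o] = f;
      tb[(size_t)r * band + o] = (uint8_t)(hb | (eb << 2) | (fb << 3));
      if (hv > best) { best = hv; bi = r; bo = o; }
    }
    std::swap(Hp, Hc);
    std::swap(Fp, Fc);
  }
  if (best <= 0) return false;

  // traceback
  int r = bi, o = bo, state = 0;  // 0=H, 1=E, 2=F
  const int i_end = qlo + bi;
  const int j_end = (int)((int64_t)i_end + dmin + bo);
  int qs = i_end, ss = j_end, matches = 0, length = 0;
  while (r >= 0 && o >= 0 && o < band) {
    const uint8_t t = tb[(size_t)r * band + o];
    const int i = qlo + r;
    const int j = (int)((int64_t)i + dmin + o);
    if (state == 0) {
      const uint8_t hb = t & 3;
      if (hb == 0) break;  // fresh-start cell: alignment begins after it
      if (hb == 1) {
        ++length;
        if (b2(q[i]) >= 0 && b2(q[i]) == b2(s[j])) ++matches;
        qs = i; ss = j;
        --r;               // diagonal predecessor keeps the same offset
        if (r < 0) break;
      } else if (hb == 2) state = 1;
      else                state = 2;
    } else if (state == 1) {
      ++length; ss = j;    // subject base aligned to a gap
      state = ((t >> 2) & 1) ? 1 : 0;
      --o;
    } else {
      ++length; qs = i;    // query base aligned to a gap
      state = ((t >> 3) & 1) ? 2 : 0;
      --r; ++o;
    }
  }

  out.score = best;
  out.q_start = qs; out.q_end = i_end + 1;
  out.s_start = ss; out.s_end = j_end + 1;
  out.matches = matches; out.length = length;
  return true;
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string query, std::string subject,
                          int word_size, int match, int mismatch,
                          int gap_open, int gap_ext,
                          int diag_tol, int chain_gap, int pad, int band_pad,
                          int max_occ, int max_clusters) {
  Scoring sc{match, mismatch, gap_open, gap_ext};
  std::vector<Run> runs;
  seed_runs(query, subject, word_size, max_occ, runs);
  std::vector<Cluster> cls = cluster_runs(runs, diag_tol, chain_gap);
  std::sort(cls.begin(), cls.end(), [](const Cluster& a, const Cluster& b) {
    if (a.total != b.total) return a.total > b.total;
    if (a.slo != b.slo) return a.slo < b.slo;
    return a.qlo < b.qlo;
  });
  if ((int)cls.size() > max_clusters) cls.resize(max_clusters);

  std::vector<int> qsv, qev, ssv, sev, scv, mv, lv;
  const int qn = (int)query.size(), sn = (int)subject.size();
  for (const Cluster& c : cls) {
    int qlo = std::max(0, c.qlo - pad), qhi = std::min(qn, c.qhi + pad);
    int slo = std::max(0, c.slo - pad), shi = std::min(sn, c.shi + pad);
    Aln a;
    if (!band_sw(query, subject, sc, qlo, qhi, slo, shi,
                 c.dmin - band_pad - pad, c.dmax + band_pad + pad, a))
      continue;
    qsv.push_back(a.q_start); qev.push_back(a.q_end);
    ssv.push_back(a.s_start); sev.push_back(a.s_end);
    scv.push_back(a.score);   mv.push_back(a.matches);
    lv.push_back(a.length);
  }
  return DataFrame::create(
      _["q_start"] = qsv, _["q_end"] = qev,
      _["s_start"] = ssv, _["s_end"] = sev,
      _["score"] = scv, _["matches"] = mv, _["aln_length"] = lv);
}

namespace {

std::string revcomp_str(const std::string& x) {
  std::string r(x.rbegin(), x.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default:  c = 'N';
    }
  }
  return r;
}

// Full (unbanded) local SW of a read against a small template window,
// recording per-column pileup contributions via traceback.
struct ReadAln {
  int score = 0, t_start = 0, t_end = 0, r_start = 0, r_end = 0;
  int matches = 0, length = 0;
  // per aligned template column: read base (or '-'), plus insertions keyed
  // by the template position they precede
  std::vector<std::pair<int, char>> cols;          // (template pos, base/'-')
  std::vector<std::pair<int, std::string>> inss;   // (template pos, inserted seq)
};

bool sw_read(const std::string& rd, const std::string& tmpl, int wlo, int whi,
             const Scoring& sc, ReadAln& out) {
  const int m = (int)rd.size(), n = whi - wlo;
  if (m <= 0 || n <= 0) return false;
  std::vector<int> Hp(n + 1, 0), Hc(n + 1, 0), Fp(n + 1, NEG), Fc(n + 1, NEG);
  std::vector<uint8_t> tb((size_t)m * (n + 1), 0);
  int best = 0, bi = -1, bj = -1;
  for (int i = 0; i < m; ++i) {
    const int rb = b2(rd[i]);
    int e = NEG; uint8_t prev_eb = 0; (void)prev_eb;
    Hc[0] = 0; Fc[0] = NEG;
    int erow = NEG;
    for (int j = 1; j <= n; ++j) {
      int eo = Hc[j - 1] - sc.gap_open - sc.gap_ext;
      int ee = erow - sc.gap_ext;
      uint8_t eb = 0;
      if (ee > eo) { e = ee; eb = 1; } else e = eo;
      erow = e;
      int fo = Hp[j] - sc.gap_open - sc.gap_ext;
      int fe = Fp[j] - sc.gap_ext;
      uint8_t fb = 0; int f;
      if (fe > fo) { f = fe; fb = 1; } else f = fo;
      int tbase = b2(tmpl[wlo + j - 1]);
      int dg = Hp[j - 1] + ((rb >= 0 && rb == tbase) ? sc.match : sc.mismatch);
      int hv = 0; uint8_t hb = 0;
      if (dg >= e && dg >= f && dg > 0) { hv = dg; hb = 1; }
      else if (e >= f && e > 0)         { hv = e;  hb = 2; }
      else if (f > 0)                   { hv = f;  hb = 3; }
      Hc[j] = hv; Fc[j] = f;
      tb[(size_t)i * (n + 1) + j] = (uint8_t)(hb | (eb << 2) | (fb << 3));
      if (hv > best) { best = hv; bi = i; bj = j; }
    }
    std::swap(Hp, Hc);
    std::swap(Fp, Fc);
  }
  if (best <= 0) return false;

  int i = bi, j = bj, state = 0;
  out.score = best;
  out.t_end = wlo + bj; out.r_end = bi + 1;
  std::string pend_ins;
  // walk backwards collecting columns; cols/inss produced in reverse order
  while (i >= 0 && j >= 0) {
    const uint8_t t = tb[(size_t)i * ((size_t)(whi - wlo) + 1) + j];
    if (state == 0) {
      const uint8_t hb = t & 3;
      if (hb == 0) break;
      if (hb == 1) {
        if (!pend_ins.empty()) {
          out.inss.push_back({wlo + j, std::string(pend_ins.rbegin(), pend_ins.rend())});
          pend_ins.clear();
        }
        ++out.length;
        if (b2(rd[i]) >= 0 && b2(rd[i]) == b2(tmpl[wlo + j - 1])) ++out.matches;
        out.cols.push_back({wlo + j - 1, rd[i]});
        out.t_start = wlo + j - 1; out.r_start = i;
        --i; --j;
      } else if (hb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // gap in read: template base deleted
      if (!pend_ins.empty()) {
        out.inss.push_back({wlo + j, std::string(pend_ins.rbegin(), pend_ins.rend())});
        pend_ins.clear();
      }
      ++out.length;
      out.cols.push_back({wlo + j - 1, '-'});
      out.t_start = wlo + j - 1;
      state = ((t >> 2) & 1) ? 1 : 0;
      --j;
    } else {  // gap in template: read base inserted before template pos (wlo+j)
      ++out.length;
      pend_ins.push_back(rd[i]);
      out.r_start = i;
      state = ((t >> 3) & 1) ? 2 : 0;
      --i;
    }
  }
  // insertions dangling at the very start of the alignment are dropped
  std::reverse(out.cols.begin(), out.cols.end());
  std::reverse(out.inss.begin(), out.inss.end());
  return true;
}

}  // namespace

// Map reads to a template by seed voting + local alignment; build a
// majority-rule pileup consensus with an explicit template column map.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, std::string tmpl,
                   int seed_len, double min_identity, double min_cov_frac,
                   int match, int mismatch, int gap_open, int gap_ext,
                   int window_pad) {
  Scoring sc{match, mismatch, gap_open, gap_ext};
  const int L = (int)tmpl.size();
  if (L == 0) stop("empty template");

  // template seed index
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1;
  std::unordered_map<uint64_t, std::vector<int>> idx;
  {
    uint64_t h = 0; int valid = 0;
    for (int i = 0; i < L; ++i) {
      int c = b2(tmpl[i]);
      if (c < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask; ++valid;
      if (valid >= seed_len) idx[h].push_back(i - seed_len + 1);
    }
  }

  std::vector<std::array<int, 5>> counts((size_t)L, {0, 0, 0, 0, 0});
  std::vector<int> cov(L, 0);
  std::vector<int> junc_cov(L + 1, 0);  // diff array over junctions
  std::unordered_map<int, std::unordered_map<std::string, int>> ins_counts;
  std::unordered_map<int, int> ins_totals;
  int n_mapped = 0;

  const int nr = reads.size();
  for (int ri = 0; ri < nr; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    if ((int)fwd.size() < seed_len) continue;
    std::string rev = revcomp_str(fwd);
    int best_votes = 0, best_diag = 0, best_strand = 0;
    for (int st = 0; st < 2; ++st) {
      const std::string& rd = (st == 0) ? fwd : rev;
      std::unordered_map<int, int> votes;  // diag bucket -> count
      uint64_t h = 0; int valid = 0;
      for (int i = 0; i < (int)rd.size(); ++i) {
        int c = b2(rd[i]);
        if (c < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask; ++valid;
        if (valid < seed_len) continue;
        auto it = idx.find(h);
        if (it == idx.end()) continue;
        if (it->second.size() > 64) continue;
        int rp = i - seed_len + 1;
        for (int tp : it->second) ++votes[(tp - rp) >> 4];
      }
      for (auto& kv : votes) {
        int v = kv.second;
        auto nb = votes.find(kv.first + 1);
        if (nb != votes.end()) v += nb->second;
        if (v > best_votes) { best_votes = v; best_diag = kv.first << 4; best_strand = st; }
      }
    }
    if (best_votes < 1) continue;

    const std::string& rd = (best_strand == 0) ? fwd : rev;
    int wlo = std::max(0, best_diag - window_pad);
    int whi = std::min(L, best_diag + (int)rd.size() + 16 + window_pad);
    ReadAln a;
    if (!sw_read(rd, tmpl, wlo, whi, sc, a)) continue;
    if (a.length <= 0) continue;
    double ident = (double)a.matches / a.length;
    int span = a.r_end - a.r_start;
    int max_span = std::min((int)rd.size(), whi - wlo);
    if (ident < min_identity || span < min_cov_frac * max_span) continue;

    ++n_mapped;
    for (auto& pc : a.cols) {
      int tp = pc.first;
      if (tp < 0 || tp >= L) continue;
      int c;
      switch (pc.second) {
        case 'A': c = 0; break; case 'C': c = 1; break;
        case 'G': c = 2; break; case 'T': c = 3; break;
        case '-': c = 4; break; default: c = -1;
      }
      if (c < 0) continue;  // N read base: no vote
      ++counts[tp][c];
      ++cov[tp];
    }
    if (a.t_start + 1 <= a.t_end - 1 && a.t_end <= L) {
      ++junc_cov[a.t_start + 1];
      --junc_cov[a.t_end];
    }
    for (auto& pi : a.inss) {
      if (pi.first <= a.t_start || pi.first >= a.t_end) continue;
      ++ins_counts[pi.first][pi.second];
      ++ins_totals[pi.first];
    }
  }

  // prefix-sum the junction coverage
  std::vector<int> jc(L + 1, 0);
  {
    int acc = 0;
    for (int j = 0; j <= L; ++j) { acc += junc_cov[j]; jc[j] = acc; }
  }

  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::string cons;
  std::vector<int> depth, colmap;
  cons.reserve(L); depth.reserve(L); colmap.reserve(L);
  for (int j = 0; j < L; ++j) {
    // majority-supported insertion before column j
    auto ti = ins_totals.find(j);
    if (j > 0 && ti != ins_totals.end() && jc[j] > 0 && 2 * ti->second > jc[j]) {
      const auto& m = ins_counts[j];
      std::string bests; int bestc = -1;
      for (auto& kv : m)
        if (kv.second > bestc || (kv.second == bestc && kv.first < bests)) {
          bests = kv.first; bestc = kv.second;
        }
      for (char c : bests) {
        cons.push_back(c);
        depth.push_back(bestc);
        colmap.push_back(-1);
      }
    }
    const auto& ct = counts[j];
    const int dp = cov[j];
    if (dp == 0) {
      cons.push_back(tmpl[j]);
      depth.push_back(0);
      colmap.push_back(j);
      continue;
    }
    int tbase = b2(tmpl[j]);
    int bestc = -1, besti = -1;
    for (int c = 0; c < 5; ++c) {
      if (ct[c] > bestc) { bestc = ct[c]; besti = c; }
      else if (ct[c] == bestc && c == tbase) besti = c;  // tie -> template base
    }
    if (besti == 4) continue;  // majority deletion: column dropped
    cons.push_back(BASES[besti]);
    depth.push_back(dp);
    colmap.push_back(j);
  }

  return List::create(
      _["consensus"] = cons,
      _["depth"] = wrap(depth),
      _["col_map"] = wrap(colmap),
      _["n_mapped"] = n_mapped);
}
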