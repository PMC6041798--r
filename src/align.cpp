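// Seed-and-verify read alignment against a (small) set of per-haplotype
// transcript sequences.
//
// Exact k-mer seeds locate candidate diagonals; each candidate is verified by
// banded semi-global edit-distance DP (free reference ends, read fully
// aligned).  NM is the DP edit distance (substitutions + insertions +
// deletions), CIGAR is reported in transcript space with M/I/D ops.  All hits
// tied at the per-read best NM within a haplotype are returned so the caller
// can collapse transcript-space duplicates that project to the same genomic
// locus and decide mapping quality.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': case 'a': c = 'T'; break;
      case 'C': case 'c': c = 'G'; break;
      case 'G': case 'g': c = 'C'; break;
      case 'T': case 't': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

struct Hit {
  int tid;       // 0-based transcript index within the haplotype
  int pos;       // 0-based start in transcript
  int strand;    // 0 = forward, 1 = reverse-complement
  int nm;
  std::string cigar;
};

struct Workspace {
  std::vector<int> prev, cur;
  std::vector<uint8_t> tb;
  std::string ops;
};

// Banded semi-global alignment of read[0..m) against win[0..n): the read is
// fully aligned, reference ends are free.  Band half-width b: column j is
// explored for j in [i, i + 2b].  Returns the edit distance, fills the
// start/end offsets in the window and the CIGAR; returns -1 when no
// alignment within max_nm fits in the band.
static int band_align(const char *read, int m, const char *win, int n, int b,
                      int max_nm, int &w_start, int &w_end,
                      std::string &cigar, Workspace &ws) {
  const int W = 2 * b + 1;
  const int INF = 1 << 28;
  ws.prev.assign(W, 0);
  ws.cur.assign(W, 0);
  ws.tb.resize((size_t)(m + 1) * W);
  int *prev = ws.prev.data();
  int *cur = ws.cur.data();
  uint8_t *tb = ws.tb.data();  // 0 diag, 1 up (I), 2 left (D)

  for (int i = 1; i <= m; ++i) {
    int row_min = INF;
    const char ri = read[i - 1];
    uint8_t *tbrow = tb + (size_t)i * W;
    for (int jj = 0; jj < W; ++jj) {
      int j = i + jj;  // window prefix length
      int best = INF; uint8_t dir = 0;
      if (j <= n) {
        int v = prev[jj] + (ri == win[j - 1] ? 0 : 1);
        if (v < best) { best = v; dir = 0; }
        if (jj + 1 < W) {
          int v2 = prev[jj + 1] + 1;
          if (v2 < best) { best = v2; dir = 1; }
        }
        if (jj >= 1 && cur[jj - 1] < INF) {
          int v3 = cur[jj - 1] + 1;
          if (v3 < best) { best = v3; dir = 2; }
        }
      }
      cur[jj] = best;
      tbrow[jj] = dir;
      if (best < row_min) row_min = best;
    }
    if (row_min > max_nm) return -1;  // cannot recover within the ceiling
    std::swap(prev, cur);
  }
  int best = INF, best_jj = -1;
  for (int jj = 0; jj < W; ++jj) {
    if (m + jj > n) continue;
    if (prev[jj] < best) { best = prev[jj]; best_jj = jj; }
  }
  if (best_jj < 0 || best > max_nm) return -1;

  std::string &ops = ws.ops;
  ops.clear();
  int i = m, jj = best_jj;
  w_end = m + best_jj;
  while (i > 0) {
    uint8_t dir = tb[(size_t)i * W + jj];
    if (dir == 0) { ops.push_back('M'); --i; }
    else if (dir == 1) { ops.push_back('I'); --i; ++jj; }
    else { ops.push_back('D'); --jj; }
  }
  w_start = jj;
  std::reverse(ops.begin(), ops.end());
  cigar.clear();
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cigar += std::to_string(q - p);
    cigar.push_back(ops[p]);
    p = q;
  }
  return best;
}

// [[Rcpp::export(name = ".align_reads_cpp")]]
List align_reads_cpp(CharacterVector reads, List tx_by_hap, int k = 15,
                     int band = 5, int max_nm = 2) {
  const int nr = reads.size();
  const int nh = tx_by_hap.size();
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // pre-convert reads and their reverse complements once
  std::vector<std::string> fwd(nr), rc(nr);
  for (int r = 0; r < nr; ++r) {
    fwd[r] = as<std::string>(reads[r]);
    rc[r] = revcomp(fwd[r]);
  }

  std::vector<int> out_read, out_hap, out_tid, out_pos, out_strand, out_nm;
  std::vector<std::string> out_cigar;
  out_read.reserve((size_t)nr * nh);

  Workspace ws;
  std::vector<std::pair<int32_t, int32_t>> cand, uniq;
  std::vector<Hit> hits;
  std::string cg;
  const int MAX_CAND = 48;

  for (int hidx = 0; hidx < nh; ++hidx) {
    CharacterVector transcripts = tx_by_hap[hidx];
    const int nt = transcripts.size();
    std::vector<std::string> tx(nt);
    for (int t = 0; t < nt; ++t) tx[t] = as<std::string>(transcripts[t]);

    // k-mer index over this haplotype's transcripts
    std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> index;
    index.reserve(1 << 16);
    for (int t = 0; t < nt; ++t) {
      const std::string &s = tx[t];
      if ((int)s.size() < k) continue;
      uint64_t h = 0; int valid = 0;
      for (int i = 0; i < (int)s.size(); ++i) {
        int c = base_code(s[i]);
        if (c < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & mask;
        if (++valid >= k) index[h].push_back({(int32_t)t, (int32_t)(i - k + 1)});
      }
    }

    for (int r = 0; r < nr; ++r) {
      const int m = (int)fwd[r].size();
      if (m < k) continue;
      hits.clear();
      int best_nm = max_nm + 1;
      for (int strand = 0; strand < 2; ++strand) {
        const std::string &rd = (strand == 0) ? fwd[r] : rc[r];
        cand.clear();
        // seeds at stride k plus the tail
        for (int p = 0; ; p += k) {
          if (p + k > m) p = m - k;
          uint64_t h = 0; bool ok = true;
          for (int i = 0; i < k; ++i) {
            int c = base_code(rd[(size_t)p + i]);
            if (c < 0) { ok = false; break; }
            h = ((h << 2) | (uint64_t)c) & mask;
          }
          if (ok) {
            auto it = index.find(h);
            if (it != index.end())
              for (auto &tp : it->second)
                cand.push_back({tp.first, tp.second - (int32_t)p});
          }
          if (p == m - k) break;
        }
        if (cand.empty()) continue;
        std::sort(cand.begin(), cand.end());
        uniq.clear();
        for (auto &c : cand) {
          if (!uniq.empty() && uniq.back().first == c.first &&
              c.second - uniq.back().second <= band)
            continue;
          uniq.push_back(c);
          if ((int)uniq.size() >= MAX_CAND) break;
        }
        for (auto &c : uniq) {
          int tid = c.first, diag = c.second;
          const std::string &ts = tx[tid];
          int w0 = diag - band;
          int w1 = diag + m + band;  // exclusive
          if (w0 < 0) w0 = 0;
          if (w1 > (int)ts.size()) w1 = (int)ts.size();
          if (w1 - w0 < m) continue;
          int ws_ = 0, we_ = 0;
          int nm = band_align(rd.c_str(), m, ts.c_str() + w0, w1 - w0, band,
                              max_nm, ws_, we_, cg, ws);
          if (nm < 0) continue;
          hits.push_back(Hit{tid, w0 + ws_, strand, nm, cg});
          if (nm < best_nm) best_nm = nm;
        }
      }
      if (best_nm > max_nm) continue;
      std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
        if (a.tid != b.tid) return a.tid < b.tid;
        if (a.pos != b.pos) return a.pos < b.pos;
        return a.strand < b.strand;
      });
      for (size_t i = 0; i < hits.size(); ++i) {
        if (hits[i].nm != best_nm) continue;
        if (i > 0 && hits[i].tid == hits[i - 1].tid &&
            hits[i].pos == hits[i - 1].pos &&
            hits[i].strand == hits[i - 1].strand &&
            hits[i - 1].nm == best_nm)
          continue;
        out_read.push_back(r + 1);
        out_hap.push_back(hidx + 1);
        out_tid.push_back(hits[i].tid + 1);
        out_pos.push_back(hits[i].pos);
        out_strand.push_back(hits[i].strand);
        out_nm.push_back(hits[i].nm);
        out_cigar.push_back(hits[i].cigar);
      }
    }
  }

  return List::create(_["read"] = wrap(out_read), _["hap"] = wrap(out_hap),
                      _["tid"] = wrap(out_tid), _["pos"] = wrap(out_pos),
                      _["strand"] = wrap(out_strand), _["nm"] = wrap(out_nm),
                      _["cigar"] = wrap(out_cigar));
}

// Project transcript-space alignments to genomic coordinates with spliced
// (N-gapped) CIGARs.  Exon starts/lengths are genomic, ascending; `minus`
// marks transcripts on the minus strand (whose sequence is the reverse
// complement of the spliced exons), for which the alignment is mirrored
// before projection.
// [[Rcpp::export(name = ".project_alignments_cpp")]]
List project_alignments_cpp(IntegerVector tpos, CharacterVector cigar,
                            IntegerVector tid, LogicalVector minus,
                            List exon_starts, List exon_lens) {
  const int n = tpos.size();
  IntegerVector gpos(n), gend(n);
  CharacterVector gcig(n);
  for (int r = 0; r < n; ++r) {
    std::string cg = as<std::string>(cigar[r]);
    std::vector<std::pair<long, char>> ops;
    long num = 0, refspan = 0;
    for (char c : cg) {
      if (c >= '0' && c <= '9') { num = num * 10 + (c - '0'); }
      else { ops.push_back({num, c}); if (c == 'M' || c == 'D') refspan += num; num = 0; }
    }
    IntegerVector es = exon_starts[tid[r] - 1];
    IntegerVector el = exon_lens[tid[r] - 1];
    long tlen = 0;
    for (int i = 0; i < el.size(); ++i) tlen += el[i];
    long p = tpos[r];
    if (minus[r]) {
      p = tlen - tpos[r] - refspan;
      std::reverse(ops.begin(), ops.end());
    }
    int e = 0; long cum = 0;
    while (e < (int)es.size() - 1 && cum + el[e] <= p) { cum += el[e]; ++e; }
    long off = p - cum;
    long gstart = (long)es[e] + off;
    std::string out;
    long last_len = 0; char last_op = 0; long gref = 0;
    auto emit = [&](long len, char op) {
      if (len == 0) return;
      if (op == last_op) { last_len += len; return; }
      if (last_op) { out += std::to_string(last_len); out.push_back(last_op); }
      last_op = op; last_len = len;
    };
    int cur_e = e; long cur_off = off;
    for (auto &o : ops) {
      if (o.second == 'I') { emit(o.first, 'I'); continue; }
      long rem = o.first;
      while (rem > 0) {
        long exrem = (long)el[cur_e] - cur_off;
        long take = rem < exrem ? rem : exrem;
        emit(take, o.second); gref += take;
        cur_off += take; rem -= take;
        if (cur_off == (long)el[cur_e] && rem > 0) {
          long gap = (long)es[cur_e + 1] - ((long)es[cur_e] + (long)el[cur_e]);
          if (gap > 0) { emit(gap, 'N'); gref += gap; }
          ++cur_e; cur_off = 0;
        }
      }
    }
    if (last_op) { out += std::to_string(last_len); out.push_back(last_op); }
    gpos[r] = (int)gstart;
    gend[r] = (int)(gstart + gref);
    gcig[r] = out;
  }
  return List::create(_["pos"] = gpos, _["end"] = gend, _["cigar"] = gcig);
}
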