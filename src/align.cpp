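// Seed-and-extend local alignment for nucleotide genome pairs and
// Smith-Waterman with affine gaps for protein pairs.
//
// The nucleotide engine follows the classic BLAST architecture: exact
// word seeds on both strands, ungapped x-drop extension, then gapped
// x-drop extension with an adaptive band.  N is encoded as 4 and never
// matches anything (including another N).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int enc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<uint8_t> encode_dna(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t) enc_base(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = c < 4 ? (uint8_t)(3 - c) : (uint8_t)4;
  }
  return r;
}

struct UExt { int len; int score; int ident; };

// Ungapped x-drop extension.  Starts comparing q[q0], s[s0] and walks in
// direction dir (+1/-1).  Returns consumed length, score and identity
// count at the score maximum.
static UExt ungapped_ext(const std::vector<uint8_t> &q, const std::vector<uint8_t> &s,
                         long q0, long s0, int dir,
                         int match, int mismatch, int xdrop) {
  UExt best = {0, 0, 0};
  int score = 0, ident = 0, len = 0;
  long i = q0, j = s0;
  long nq = (long) q.size(), ns = (long) s.size();
  while (i >= 0 && i < nq && j >= 0 && j < ns) {
    bool hit = (q[i] == s[j] && q[i] < 4);
    score += hit ? match : -mismatch;
    ident += hit ? 1 : 0;
    ++len;
    if (score > best.score) { best.score = score; best.len = len; best.ident = ident; }
    if (score <= best.score - xdrop) break;
    i += dir; j += dir;
  }
  return best;
}

struct GExt { int di; int dj; int score; int ident; int alen; };

// Gapped x-drop extension with affine gaps (gap of length L costs
// gopen + gext*L) and adaptive band.  q0/s0 are the first positions to
// consume in direction dir; nq/ns are how many positions are available.
static GExt gapped_ext(const std::vector<uint8_t> &q, long q0, long nq,
                       const std::vector<uint8_t> &s, long s0, long ns,
                       int dir, int match, int mismatch,
                       int gopen, int gext, int xdrop) {
  GExt res = {0, 0, 0, 0, 0};
  if (nq <= 0 || ns <= 0) return res;
  long maxn = nq, maxm = ns;

  // persistent DP rows, grown as needed and never re-initialized: every
  // read is guarded by the live-window bounds, so stale values are
  // never consulted
  static std::vector<int> pM, pIx, pIy, cM, cIx, cIy;
  if ((long) pM.size() < maxm + 1) {
    size_t nsz = (size_t)(maxm + 1);
    pM.resize(nsz); pIx.resize(nsz); pIy.resize(nsz);
    cM.resize(nsz); cIx.resize(nsz); cIy.resize(nsz);
  }
  // traceback rows: byte = Msrc(2 bits) | Ixsrc<<2 | Iysrc<<3
  std::vector<long> row_lo;
  std::vector< std::vector<uint8_t> > rows;

  int best = 0; long bi = 0, bj = 0;
  long plo = 0, phi = 0;

  // row 0
  {
    std::vector<uint8_t> tb;
    pM[0] = 0; pIx[0] = NEG; pIy[0] = NEG;
    tb.push_back(0);
    long j = 1;
    while (j <= maxm) {
      int open = pM[j - 1] - gopen - gext;
      int ext = pIy[j - 1] > NEG ? pIy[j - 1] - gext : NEG;
      int v = std::max(open, ext);
      if (v <= best - xdrop) break;
      pM[j] = NEG; pIx[j] = NEG; pIy[j] = v;
      tb.push_back((uint8_t)((ext > open ? 1 : 0) << 3));
      ++j;
    }
    phi = j - 1;
    row_lo.push_back(0);
    rows.push_back(tb);
  }

  for (long i = 1; i <= maxn; ++i) {
    long lo = plo, j = lo;
    long first_live = -1, last_live = -1;
    std::vector<uint8_t> tb;
    bool prev_cell_live = false;
    while (j <= maxm) {
      if (j > phi + 1 && !prev_cell_live) break;
      int dM = NEG, dIx = NEG, dIy = NEG;  // prev row, col j-1 (diag)
      if (j - 1 >= plo && j - 1 <= phi) { dM = pM[j - 1]; dIx = pIx[j - 1]; dIy = pIy[j - 1]; }
      int uM = NEG, uIx = NEG;             // prev row, col j (up)
      if (j >= plo && j <= phi) { uM = pM[j]; uIx = pIx[j]; }
      int lM = NEG, lIy = NEG;             // current row, col j-1 (left)
      if (j - 1 >= lo && (long)tb.size() >= j - lo) { lM = cM[j - 1]; lIy = cIy[j - 1]; }

      int m_v = NEG; uint8_t msrc = 0;
      if (j >= 1) {
        int pre = dM; msrc = 1;
        if (dIx > pre) { pre = dIx; msrc = 2; }
        if (dIy > pre) { pre = dIy; msrc = 3; }
        if (pre > NEG) {
          bool hit = (q[q0 + dir * (i - 1)] == s[s0 + dir * (j - 1)] && q[q0 + dir * (i - 1)] < 4);
          m_v = pre + (hit ? match : -mismatch);
        }
      }
      int ix_open = uM > NEG ? uM - gopen - gext : NEG;
      int ix_ext = uIx > NEG ? uIx - gext : NEG;
      int ix_v = std::max(ix_open, ix_ext);
      int iy_open = lM > NEG ? lM - gopen - gext : NEG;
      int iy_ext = lIy > NEG ? lIy - gext : NEG;
      int iy_v = std::max(iy_open, iy_ext);

      int v = std::max(m_v, std::max(ix_v, iy_v));
      bool live = v > best - xdrop;
      if (!live) { m_v = NEG; ix_v = NEG; iy_v = NEG; }

      if ((long)tb.size() == 0 && !live && first_live < 0) {
        // still searching for the first live cell of the row
        lo = j + 1;
        cM[j] = NEG; cIx[j] = NEG; cIy[j] = NEG;
        prev_cell_live = false;
        ++j;
        continue;
      }
      cM[j] = m_v; cIx[j] = ix_v; cIy[j] = iy_v;
      uint8_t b = 0;
      if (m_v > NEG) b |= msrc;
      if (ix_v > NEG && ix_ext > ix_open) b |= (1 << 2);
      if (iy_v > NEG && iy_ext > iy_open) b |= (1 << 3);
      tb.push_back(b);
      if (live) {
        if (first_live < 0) first_live = j;
        last_live = j;
        if (m_v > best) { best = m_v; bi = i; bj = j; }
      }
      prev_cell_live = live;
      ++j;
    }
    if (first_live < 0) break;
    // trim the row to the live range
    long keep_lo = first_live;
    if (keep_lo > lo) {
      tb.erase(tb.begin(), tb.begin() + (keep_lo - lo));
      lo = keep_lo;
    }
    if (last_live < lo + (long)tb.size() - 1)
      tb.resize(last_live - lo + 1);
    row_lo.push_back(lo);
    rows.push_back(tb);
    std::swap(pM, cM); std::swap(pIx, cIx); std::swap(pIy, cIy);
    plo = lo; phi = last_live;
    if ((double)rows.size() * 64.0 > 5e8) break;  // hard safety cap
  }

  if (best <= 0) return res;
  // traceback from (bi, bj) in M
  long i = bi, j = bj;
  int state = 1;  // 1=M, 2=Ix, 3=Iy
  int ident = 0, alen = 0;
  while (!(i == 0 && j == 0)) {
    const std::vector<uint8_t> &tb = rows[i];
    long lo = row_lo[i];
    uint8_t b = tb[j - lo];
    if (state == 1) {
      bool hit = (q[q0 + dir * (i - 1)] == s[s0 + dir * (j - 1)] && q[q0 + dir * (i - 1)] < 4);
      ident += hit ? 1 : 0;
      ++alen;
      state = b & 3;
      --i; --j;
      if (state == 0) break;  // came from the origin
    } else if (state == 2) {
      ++alen;
      state = (b & (1 << 2)) ? 2 : 1;
      --i;
    } else {
      ++alen;
      state = (b & (1 << 3)) ? 3 : 1;
      --j;
    }
  }
  res.di = (int) bi; res.dj = (int) bj;
  res.score = best; res.ident = ident; res.alen = alen;
  return res;
}

struct Hsp {
  long qs, qe, ss, se;
  int len, ident, score;
  bool minus;
};

static void find_hsps_one(const std::vector<uint8_t> &q, const std::vector<uint8_t> &s,
                          int w, int match, int mismatch, int gopen, int gext,
                          int xdrop, int min_score, bool minus,
                          std::vector<Hsp> &out) {
  long nq = (long) q.size(), ns = (long) s.size();
  if (nq < w || ns < w) return;
  long tab = 1L << (2 * w);

  // CSR index of subject words (persistent buffer, cleared per call)
  static std::vector<int> cnt;
  if ((long) cnt.size() < tab + 1) cnt.resize((size_t) tab + 1);
  std::fill(cnt.begin(), cnt.begin() + tab + 1, 0);
  {
    uint32_t code = 0; int run = 0;
    for (long j = 0; j < ns; ++j) {
      if (s[j] > 3) { run = 0; code = 0; continue; }
      code = ((code << 2) | s[j]) & (uint32_t)(tab - 1);
      if (++run >= w) cnt[code + 1]++;
    }
  }
  for (long k = 0; k < tab; ++k) cnt[k + 1] += cnt[k];
  std::vector<int> pos(cnt[tab]);
  {
    std::vector<int> fill(cnt.begin(), cnt.end() - 1);
    uint32_t code = 0; int run = 0;
    for (long j = 0; j < ns; ++j) {
      if (s[j] > 3) { run = 0; code = 0; continue; }
      code = ((code << 2) | s[j]) & (uint32_t)(tab - 1);
      if (++run >= w) pos[fill[code]++] = (int)(j - w + 1);
    }
  }

  std::vector<long> hwm(nq + ns + 1, -1);  // per-diagonal extent already covered
  std::vector<Hsp> gapped;

  uint32_t code = 0; int run = 0;
  for (long i = 0; i < nq; ++i) {
    if (q[i] > 3) { run = 0; code = 0; continue; }
    code = ((code << 2) | q[i]) & (uint32_t)(tab - 1);
    if (++run < w) continue;
    long qpos = i - w + 1;
    for (int k = cnt[code]; k < cnt[code + 1]; ++k) {
      long j = pos[k];
      long d = qpos - j + ns;
      if (qpos <= hwm[d]) continue;
      UExt r = ungapped_ext(q, s, qpos + w, j + w, +1, match, mismatch, xdrop);
      UExt l = ungapped_ext(q, s, qpos - 1, j - 1, -1, match, mismatch, xdrop);
      long qs = qpos - l.len, qe = qpos + w - 1 + r.len;
      long ss = j - l.len, se = j + w - 1 + r.len;
      int score0 = w * match + r.score + l.score;
      int ident0 = w + r.ident + l.ident;
      hwm[d] = qe;
      bool contained = false;
      for (size_t g = 0; g < gapped.size(); ++g) {
        if (qs >= gapped[g].qs && qe <= gapped[g].qe &&
            ss >= gapped[g].ss && se <= gapped[g].se) { contained = true; break; }
      }
      if (contained) continue;
      GExt gr = gapped_ext(q, qe + 1, nq - qe - 1, s, se + 1, ns - se - 1,
                           +1, match, mismatch, gopen, gext, xdrop);
      GExt gl = gapped_ext(q, qs - 1, qs, s, ss - 1, ss,
                           -1, match, mismatch, gopen, gext, xdrop);
      Hsp h;
      h.qs = qs - gl.di; h.qe = qe + gr.di;
      h.ss = ss - gl.dj; h.se = se + gr.dj;
      h.score = score0 + gr.score + gl.score;
      h.ident = ident0 + gr.ident + gl.ident;
      h.len = (int)(qe - qs + 1) + gr.alen + gl.alen;
      h.minus = minus;
      if (h.score >= min_score) {
        out.push_back(h);
        if (gr.alen > 0 || gl.alen > 0 || h.score >= 2 * min_score)
          gapped.push_back(h);
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_find_hsps(std::string query, std::string subject,
                        int word_size, int match, int mismatch,
                        int gap_open, int gap_extend,
                        int x_drop, int min_hsp_score) {
  if (word_size < 4 || word_size > 13)
    stop("word_size must be between 4 and 13");
  std::vector<uint8_t> q = encode_dna(query);
  std::vector<uint8_t> s = encode_dna(subject);
  std::vector<uint8_t> src = revcomp_codes(s);
  std::vector<Hsp> hsps;
  find_hsps_one(q, s, word_size, match, mismatch, gap_open, gap_extend,
                x_drop, min_hsp_score, false, hsps);
  find_hsps_one(q, src, word_size, match, mismatch, gap_open, gap_extend,
                x_drop, min_hsp_score, true, hsps);

  long ns = (long) s.size();
  // map minus-strand subject coordinates back to forward coordinates
  for (size_t k = 0; k < hsps.size(); ++k) {
    if (hsps[k].minus) {
      long a = ns - 1 - hsps[k].se, b = ns - 1 - hsps[k].ss;
      hsps[k].ss = a; hsps[k].se = b;
    }
  }
  std::sort(hsps.begin(), hsps.end(), [](const Hsp &a, const Hsp &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.qs != b.qs) return a.qs < b.qs;
    return a.ss < b.ss;
  });
  // drop exact duplicates (same coordinates and strand)
  std::vector<Hsp> uniq;
  for (size_t k = 0; k < hsps.size(); ++k) {
    bool dup = false;
    for (size_t g = 0; g < uniq.size(); ++g) {
      if (uniq[g].qs == hsps[k].qs && uniq[g].qe == hsps[k].qe &&
          uniq[g].ss == hsps[k].ss && uniq[g].se == hsps[k].se &&
          uniq[g].minus == hsps[k].minus) { dup = true; break; }
    }
    if (!dup) uniq.push_back(hsps[k]);
  }

  int n = (int) uniq.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), len(n), ident(n), score(n);
  CharacterVector strand(n);
  for (int k = 0; k < n; ++k) {
    qs[k] = (int)(uniq[k].qs + 1); qe[k] = (int)(uniq[k].qe + 1);
    ss[k] = (int)(uniq[k].ss + 1); se[k] = (int)(uniq[k].se + 1);
    len[k] = uniq[k].len; ident[k] = uniq[k].ident; score[k] = uniq[k].score;
    strand[k] = uniq[k].minus ? "-" : "+";
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe,
    _["s_start"] = ss, _["s_end"] = se,
    _["strand"] = strand, _["length"] = len,
    _["identities"] = ident, _["score"] = score,
    _["stringsAsFactors"] = false);
}

// Smith-Waterman local alignment with affine gaps for proteins.
// a, b: 0-based integer codes into the substitution matrix.
// [[Rcpp::export]]
List cpp_sw_protein(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                    int gap_open, int gap_extend) {
  long n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double) n * (double) m > 6e7) stop("protein pair too large");
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG), F((n + 1) * (m + 1), NEG);
  std::vector<uint8_t> tb((n + 1) * (m + 1), 0);
  // tb bits: 0-1 H source (0 stop, 1 diag, 2 E, 3 F); 2 E ext; 3 F ext
  int best = 0; long bi = 0, bj = 0;
  for (long i = 1; i <= n; ++i) {
    for (long j = 1; j <= m; ++j) {
      long c = i * (m + 1) + j, up = (i - 1) * (m + 1) + j, lf = c - 1, dg = up - 1;
      int e_open = H[up] - gap_open - gap_extend;
      int e_ext = E[up] > NEG ? E[up] - gap_extend : NEG;
      int e = std::max(e_open, e_ext);
      int f_open = H[lf] - gap_open - gap_extend;
      int f_ext = F[lf] > NEG ? F[lf] - gap_extend : NEG;
      int f = std::max(f_open, f_ext);
      int dsc = H[dg] + sub(a[i - 1], b[j - 1]);
      int h = 0; uint8_t src = 0;
      if (dsc > h) { h = dsc; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      H[c] = h; E[c] = e; F[c] = f;
      uint8_t bbyte = src;
      if (e_ext > e_open) bbyte |= (1 << 2);
      if (f_ext > f_open) bbyte |= (1 << 3);
      tb[c] = bbyte;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  long i = bi, j = bj;
  int state = 1, ident = 0, alen = 0, posi = 0;
  long ae = bi, be = bj;
  while (i > 0 && j > 0) {
    long c = i * (m + 1) + j;
    uint8_t b8 = tb[c];
    if (state == 1) {
      uint8_t src = b8 & 3;
      if (src == 0 || H[c] == 0) break;
      if (src == 1) {
        ident += (a[i - 1] == b[j - 1]) ? 1 : 0;
        posi += (sub(a[i - 1], b[j - 1]) > 0) ? 1 : 0;
        ++alen; --i; --j;
      } else {
        state = src;  // switch matrix, no move yet
      }
    } else if (state == 2) {
      ++alen;
      state = (b8 & (1 << 2)) ? 2 : 1;
      --i;
    } else {
      ++alen;
      state = (b8 & (1 << 3)) ? 3 : 1;
      --j;
    }
  }
  return List::create(
    _["score"] = best, _["length"] = alen, _["identities"] = ident,
    _["positives"] = posi,
    _["a_start"] = (int)(i + 1), _["a_end"] = (int) ae,
    _["b_start"] = (int)(j + 1), _["b_end"] = (int) be);
}
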