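#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <cctype>
#include <algorithm>
using namespace Rcpp;

// Residues outside the alphabet collapse onto 'X'.
static void build_charmap(const std::string &alpha, int *map) {
  int xi = 0;
  for (size_t i = 0; i < alpha.size(); ++i) if (alpha[i] == 'X') xi = (int)i;
  for (int i = 0; i < 256; ++i) map[i] = xi;
  for (size_t i = 0; i < alpha.size(); ++i) {
    map[(unsigned char)alpha[i]] = (int)i;
    map[(unsigned char)std::tolower(alpha[i])] = (int)i;
  }
}

static std::vector<int> encode(const char *s, const int *map) {
  size_t n = std::strlen(s);
  std::vector<int> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = map[(unsigned char)s[i]];
  return v;
}

struct AlnRes {
  int score, qs, qe, ss, se, len, nident, gaps, mism;
};

// Local affine-gap alignment (Smith-Waterman) with full traceback.
// Gap of length L costs gap_open + L * gap_ext.
static bool sw_affine(const std::vector<int> &q, const std::vector<int> &s,
                      const IntegerMatrix &S, int go, int ge, AlnRes &out) {
  const int m = (int)q.size(), n = (int)s.size();
  if (m == 0 || n == 0) return false;
  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Ecur(n + 1, NEG), Fprev(n + 1, NEG), Fcur(n + 1, NEG);
  // traceback matrices: tbH 0=stop 1=diag 2=fromE 3=fromF; tbE/tbF bit 1 = opened here
  std::vector<unsigned char> tbH((size_t)(m + 1) * (n + 1), 0),
      tbE((size_t)(m + 1) * (n + 1), 0), tbF((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG;
    int qi = q[i - 1];
    size_t row = (size_t)i * (n + 1);
    for (int j = 1; j <= n; ++j) {
      int eo = Hcur[j - 1] - go - ge, ee = Ecur[j - 1] - ge;
      int E = eo >= ee ? eo : ee;
      tbE[row + j] = eo >= ee ? 1 : 0;
      Ecur[j] = E;
      int fo = Hprev[j] - go - ge, fe = Fprev[j] - ge;
      int F = fo >= fe ? fo : fe;
      tbF[row + j] = fo >= fe ? 1 : 0;
      Fcur[j] = F;
      int diag = Hprev[j - 1] + S(qi, s[j - 1]);
      int h = 0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E > h) { h = E; tb = 2; }
      if (F > h) { h = F; tb = 3; }
      Hcur[j] = h; tbH[row + j] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  if (best <= 0) return false;
  // traceback
  int i = bi, j = bj, state = 0; // 0 = in H
  int nident = 0, mism = 0, gaps = 0, len = 0;
  int qe = bi, se = bj;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) {
        ++len;
        if (q[i - 1] == s[j - 1]) ++nident; else ++mism;
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // gap consuming subject
      ++len; ++gaps;
      unsigned char opened = tbE[idx];
      --j;
      if (opened) state = 0;
    } else { // gap consuming query
      ++len; ++gaps;
      unsigned char opened = tbF[idx];
      --i;
      if (opened) state = 0;
    }
  }
  out.score = best;
  out.qs = i; out.qe = qe; out.ss = j; out.se = se; // 0-based half-open: [qs, qe)
  out.len = len; out.nident = nident; out.gaps = gaps; out.mism = mism;
  return true;
}

// X-drop ungapped extension of a 3-mer seed; returns score, sets right extent.
static int ungapped_extend(const std::vector<int> &q, const std::vector<int> &s,
                           int qpos, int spos, const IntegerMatrix &S, int xdrop,
                           int *right_end) {
  int base = 0;
  for (int k = 0; k < 3; ++k) base += S(q[qpos + k], s[spos + k]);
  int run = 0, bestR = 0, i = qpos + 3, j = spos + 3, re = qpos + 2;
  const int m = (int)q.size(), n = (int)s.size();
  while (i < m && j < n) {
    run += S(q[i], s[j]);
    if (run > bestR) { bestR = run; re = i; }
    if (bestR - run > xdrop) break;
    ++i; ++j;
  }
  run = 0; int bestL = 0;
  i = qpos - 1; j = spos - 1;
  while (i >= 0 && j >= 0) {
    run += S(q[i], s[j]);
    if (run > bestL) bestL = run;
    if (bestL - run > xdrop) break;
    --i; --j;
  }
  *right_end = re;
  return base + bestL + bestR;
}

// Seeded protein-protein local search: 3-mer neighbourhood seeds (score >= word_T
// under the supplied matrix), two-hit diagonal trigger, ungapped X-drop filter,
// then full affine Smith-Waterman on shortlisted query/subject pairs.
// Coordinates in the result are 0-based half-open.
// [[Rcpp::export]]
DataFrame cpp_protein_search(CharacterVector queries, CharacterVector subjects,
                             IntegerMatrix smat, std::string alphabet,
                             int word_T, int two_hit_window, int xdrop,
                             int ungapped_trigger, int gap_open, int gap_ext,
                             int min_report) {
  int map[256];
  build_charmap(alphabet, map);
  const int A = (int)alphabet.size(), A2 = A * A, A3 = A2 * A;
  const int nsub = subjects.size(), nq = queries.size();

  std::vector<std::vector<int>> sub(nsub);
  int maxq = 0;
  for (int i = 0; i < nq; ++i) {
    int L = (int)std::strlen(CHAR(STRING_ELT(queries, i)));
    if (L > maxq) maxq = L;
  }
  // postings (CSR) over db words
  std::vector<int> wcount(A3, 0);
  long total_words = 0;
  for (int sIdx = 0; sIdx < nsub; ++sIdx) {
    sub[sIdx] = encode(CHAR(STRING_ELT(subjects, sIdx)), map);
    int L = (int)sub[sIdx].size();
    for (int p = 0; p + 2 < L; ++p) {
      int id = sub[sIdx][p] * A2 + sub[sIdx][p + 1] * A + sub[sIdx][p + 2];
      ++wcount[id]; ++total_words;
    }
  }
  std::vector<long> off(A3 + 1, 0);
  for (int w = 0; w < A3; ++w) off[w + 1] = off[w] + wcount[w];
  std::vector<int> post_sid(total_words), post_pos(total_words);
  {
    std::vector<long> cur(off.begin(), off.end() - 1);
    for (int sIdx = 0; sIdx < nsub; ++sIdx) {
      int L = (int)sub[sIdx].size();
      for (int p = 0; p + 2 < L; ++p) {
        int id = sub[sIdx][p] * A2 + sub[sIdx][p + 1] * A + sub[sIdx][p + 2];
        post_sid[cur[id]] = sIdx;
        post_pos[cur[id]] = p;
        ++cur[id];
      }
    }
  }
  // neighbourhood: query word -> distinct db words scoring >= word_T
  std::vector<int> colmax(A, -1000);
  for (int b = 0; b < A; ++b)
    for (int a = 0; a < A; ++a)
      if (smat(a, b) > colmax[b]) colmax[b] = smat(a, b);
  std::vector<std::vector<int>> neigh(A3);
  for (int dw = 0; dw < A3; ++dw) {
    if (wcount[dw] == 0) continue;
    int a2 = dw / A2, b2 = (dw / A) % A, c2 = dw % A;
    int bc = colmax[b2] + colmax[c2];
    for (int qa = 0; qa < A; ++qa) {
      int s1 = smat(qa, a2);
      if (s1 + bc < word_T) continue;
      int base1 = qa * A2;
      for (int qb = 0; qb < A; ++qb) {
        int s2 = s1 + smat(qb, b2);
        if (s2 + colmax[c2] < word_T) continue;
        int base2 = base1 + qb * A;
        for (int qc = 0; qc < A; ++qc) {
          if (s2 + smat(qc, c2) >= word_T) neigh[base2 + qc].push_back(dw);
        }
      }
    }
  }
  // per-subject diagonal bookkeeping (stamped, reset-free)
  std::vector<std::vector<int>> dstamp(nsub), dlast(nsub), dext(nsub);
  for (int sIdx = 0; sIdx < nsub; ++sIdx) {
    int sz = (int)sub[sIdx].size() + maxq + 3;
    dstamp[sIdx].assign(sz, -1);
    dlast[sIdx].assign(sz, 0);
    dext[sIdx].assign(sz, -1);
  }
  std::vector<int> subj_seen(nsub, -1);

  std::vector<int> r_q, r_s, r_score, r_qs, r_qe, r_ss, r_se, r_len, r_nid, r_gap, r_mm;
  std::vector<int> cands;

  for (int qi = 0; qi < nq; ++qi) {
    std::vector<int> q = encode(CHAR(STRING_ELT(queries, qi)), map);
    int qlen = (int)q.size();
    if (qlen < 3) continue;
    cands.clear();
    for (int qpos = 0; qpos + 2 < qlen; ++qpos) {
      int wid = q[qpos] * A2 + q[qpos + 1] * A + q[qpos + 2];
      const std::vector<int> &nb = neigh[wid];
      for (size_t u = 0; u < nb.size(); ++u) {
        int dw = nb[u];
        for (long k = off[dw]; k < off[dw + 1]; ++k) {
          int sid = post_sid[k], spos = post_pos[k];
          int d = qpos - spos + (int)sub[sid].size();
          if (dstamp[sid][d] != qi) {
            dstamp[sid][d] = qi;
            dlast[sid][d] = qpos;
            dext[sid][d] = -1;
            continue;
          }
          if (dext[sid][d] >= qpos) continue;
          int lastq = dlast[sid][d];
          if (qpos - lastq < 3) continue;  // overlapping word hit
          dlast[sid][d] = qpos;
          if (qpos - lastq <= two_hit_window) {
            int re;
            int usc = ungapped_extend(q, sub[sid], qpos, spos, smat, xdrop, &re);
            dext[sid][d] = re;
            if (usc >= ungapped_trigger && subj_seen[sid] != qi) {
              subj_seen[sid] = qi;
              cands.push_back(sid);
            }
          }
        }
      }
    }
    for (size_t c = 0; c < cands.size(); ++c) {
      AlnRes res;
      if (!sw_affine(q, sub[cands[c]], smat, gap_open, gap_ext, res)) continue;
      if (res.score < min_report) continue;
      r_q.push_back(qi + 1); r_s.push_back(cands[c] + 1);
      r_score.push_back(res.score);
      r_qs.push_back(res.qs); r_qe.push_back(res.qe);
      r_ss.push_back(res.ss); r_se.push_back(res.se);
      r_len.push_back(res.len); r_nid.push_back(res.nident);
      r_gap.push_back(res.gaps); r_mm.push_back(res.mism);
    }
  }
  return DataFrame::create(
      _["query"] = r_q, _["subject"] = r_s, _["raw_score"] = r_score,
      _["qstart"] = r_qs, _["qend"] = r_qe, _["sstart"] = r_ss, _["send"] = r_se,
      _["length"] = r_len, _["nident"] = r_nid, _["gaps"] = r_gap,
      _["mismatches"] = r_mm);
}

// Direct affine local alignment of one query/subject pair (no seeding).
// [[Rcpp::export]]
List cpp_pair_align(std::string query, std::string subject, IntegerMatrix smat,
                    std::string alphabet, int gap_open, int gap_ext) {
  int map[256];
  build_charmap(alphabet, map);
  std::vector<int> q = encode(query.c_str(), map), s = encode(subject.c_str(), map);
  AlnRes res;
  if (!sw_affine(q, s, smat, gap_open, gap_ext, res))
    return List::create(_["raw_score"] = 0);
  return List::create(_["raw_score"] = res.score, _["qstart"] = res.qs,
                      _["qend"] = res.qe, _["sstart"] = res.ss, _["send"] = res.se,
                      _["length"] = res.len, _["nident"] = res.nident,
                      _["gaps"] = res.gaps, _["mismatches"] = res.mism);
}

// BWA-style quality tail trimming: remove the 3' suffix maximising
// sum(threshold - q_i); returns the retained length per read.
// [[Rcpp::export]]
IntegerVector cpp_quality_trim(List quals, int threshold) {
  int n = quals.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    IntegerVector q = quals[r];
    int len = q.size(), best = 0, run = 0, cut = len;
    for (int i = len - 1; i >= 0; --i) {
      run += threshold - q[i];
      if (run > best) { best = run; cut = i; }
    }
    out[r] = best > 0 ? cut : len;
  }
  return out;
}

// Best ungapped local adapter match per read over all offsets (Kadane per
// offset, +match/-mismatch scoring). Returns score, 1-based read span, adapter.
// [[Rcpp::export]]
IntegerMatrix cpp_adapter_scan(CharacterVector reads, CharacterVector adapters,
                               int match, int mismatch) {
  int n = reads.size(), na = adapters.size();
  IntegerMatrix out(n, 4);
  std::vector<std::string> ad(na);
  for (int a = 0; a < na; ++a) {
    ad[a] = CHAR(STRING_ELT(adapters, a));
    for (size_t k = 0; k < ad[a].size(); ++k) ad[a][k] = std::toupper(ad[a][k]);
  }
  for (int r = 0; r < n; ++r) {
    std::string rd = CHAR(STRING_ELT(reads, r));
    for (size_t k = 0; k < rd.size(); ++k) rd[k] = std::toupper(rd[k]);
    int lr = (int)rd.size();
    int best = 0, bs = 0, be = -1, ba = 0;
    for (int a = 0; a < na; ++a) {
      int la = (int)ad[a].size();
      for (int o = -(la - 1); o <= lr - 1; ++o) {
        int t0 = o > 0 ? o : 0;
        int t1 = (o + la) < lr ? (o + la) : lr;
        int run = 0, rstart = t0;
        for (int t = t0; t < t1; ++t) {
          int v = (rd[t] == ad[a][t - o] && rd[t] != 'N') ? match : mismatch;
          if (run <= 0) { run = v; rstart = t; }
          else run += v;
          if (run > best) { best = run; bs = rstart; be = t; ba = a; }
        }
      }
    }
    out(r, 0) = best;
    out(r, 1) = bs + 1;
    out(r, 2) = be + 1;
    out(r, 3) = ba + 1;
  }
  return out;
}

// Global affine alignment over a precomputed column-score matrix (profile vs
// profile). All gaps, including terminal ones, cost gap_open + L * gap_ext.
// Adjacent opposite gaps are disallowed (gaps open only from the match state).
// Returns aligned column indices (1-based, 0 = gap) for both profiles.
// [[Rcpp::export]]
List cpp_affine_path(NumericMatrix S, double gap_open, double gap_ext) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -1e18;
  std::vector<std::vector<double>> M(m + 1, std::vector<double>(n + 1, NEG)),
      E(m + 1, std::vector<double>(n + 1, NEG)),
      F(m + 1, std::vector<double>(n + 1, NEG));
  std::vector<std::vector<unsigned char>> tbM(m + 1, std::vector<unsigned char>(n + 1, 1)),
      tbE(m + 1, std::vector<unsigned char>(n + 1, 0)),
      tbF(m + 1, std::vector<unsigned char>(n + 1, 0));
  M[0][0] = 0;
  for (int j = 1; j <= n; ++j) E[0][j] = -gap_open - gap_ext * j;
  for (int i = 1; i <= m; ++i) F[i][0] = -gap_open - gap_ext * i;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double eo = M[i][j - 1] - gap_open - gap_ext;
      double ee = E[i][j - 1] - gap_ext;
      if (eo >= ee) { E[i][j] = eo; tbE[i][j] = 1; } else { E[i][j] = ee; tbE[i][j] = 0; }
      double fo = M[i - 1][j] - gap_open - gap_ext;
      double fe = F[i - 1][j] - gap_ext;
      if (fo >= fe) { F[i][j] = fo; tbF[i][j] = 1; } else { F[i][j] = fe; tbF[i][j] = 0; }
      double pM = M[i - 1][j - 1], pE = E[i - 1][j - 1], pF = F[i - 1][j - 1];
      double prev = std::max(pM, std::max(pE, pF));
      M[i][j] = prev + S(i - 1, j - 1);
      tbM[i][j] = (pM >= pE && pM >= pF) ? 1 : (pE >= pF ? 2 : 3);
    }
  }
  double sM = M[m][n], sE = E[m][n], sF = F[m][n];
  int state = (sM >= sE && sM >= sF) ? 1 : (sE >= sF ? 2 : 3);
  double score = std::max(sM, std::max(sE, sF));
  std::vector<int> p1, p2;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (i == 0) { p1.push_back(0); p2.push_back(j); --j; continue; }
    if (j == 0) { p1.push_back(i); p2.push_back(0); --i; continue; }
    if (state == 1) {
      p1.push_back(i); p2.push_back(j);
      state = tbM[i][j];
      --i; --j;
    } else if (state == 2) {
      p1.push_back(0); p2.push_back(j);
      bool opened = tbE[i][j];
      --j;
      if (opened) state = 1;
    } else {
      p1.push_back(i); p2.push_back(0);
      bool opened = tbF[i][j];
      --i;
      if (opened) state = 1;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["path1"] = wrap(p1), _["path2"] = wrap(p2),
                      _["score"] = score);
}
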