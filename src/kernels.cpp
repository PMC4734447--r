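// Alignment kernels: affine-gap local/global DP with traceback, a
// seed-and-extend nucleotide search against an indexed subject, a
// profile-profile global path DP, and a first-order Markov sequence
// sampler. Gap convention throughout: a gap of length L costs
// gap_open + L * gap_extend (matches Biostrings::pairwiseAlignment).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const float NEG_INF = -1e30f;

struct SubMat {
  std::vector<float> s;   // n x n
  int n;
  int lut[256];
  float minval;
  float score(unsigned char a, unsigned char b) const {
    int ia = lut[a], ib = lut[b];
    if (ia < 0 || ib < 0) return minval;
    return s[ia * n + ib];
  }
};

static SubMat make_submat(const NumericMatrix& m) {
  SubMat sm;
  sm.n = m.nrow();
  if (m.ncol() != sm.n) stop("substitution matrix must be square");
  List dn = m.attr("dimnames");
  if (dn.size() < 1 || Rf_isNull(dn[0])) stop("substitution matrix needs dimnames");
  CharacterVector rn = dn[0];
  sm.s.resize(sm.n * sm.n);
  sm.minval = 1e30f;
  for (int i = 0; i < sm.n; ++i)
    for (int j = 0; j < sm.n; ++j) {
      sm.s[i * sm.n + j] = (float)m(i, j);
      sm.minval = std::min(sm.minval, sm.s[i * sm.n + j]);
    }
  for (int i = 0; i < 256; ++i) sm.lut[i] = -1;
  for (int i = 0; i < sm.n; ++i) {
    std::string nm = as<std::string>(rn[i]);
    if (nm.size() != 1) stop("substitution matrix dimnames must be single characters");
    sm.lut[(unsigned char)nm[0]] = i;
  }
  return sm;
}

static inline bool is_acgt(unsigned char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct AlnOut {
  float score;
  int qstart, qend, sstart, send;  // 0-based half-open
  int n_id, aln_len;
  std::string aq, as;
  bool found;
  int seed_count;
};

// Local Smith-Waterman with affine gaps and traceback.
// nt_mode: identity requires both chars in {A,C,G,T}.
static AlnOut sw_affine(const std::string& a, const std::string& b,
                        const SubMat& sm, float go, float ge,
                        bool nt_mode, bool want_aln) {
  AlnOut out; out.found = false; out.score = 0;
  size_t m = a.size(), n = b.size();
  if ((double)(m + 1) * (n + 1) > 6.5e7) stop("alignment problem too large");
  std::vector<float> H((m + 1) * (n + 1), 0.0f);
  std::vector<float> E((m + 1) * (n + 1), NEG_INF);
  std::vector<float> F((m + 1) * (n + 1), NEG_INF);
  size_t W = n + 1;
  std::vector<int> ea(m), eb(n);
  for (size_t i = 0; i < m; ++i) ea[i] = sm.lut[(unsigned char)a[i]];
  for (size_t j = 0; j < n; ++j) eb[j] = sm.lut[(unsigned char)b[j]];
  const float goe = go + ge;
  float best = 0.0f; size_t bi = 0, bj = 0;
  for (size_t i = 1; i <= m; ++i) {
    float* Hi = &H[i * W];
    float* Ei = &E[i * W];
    float* Fi = &F[i * W];
    const float* Hp = &H[(i - 1) * W];
    const float* Fp = &F[(i - 1) * W];
    const int ca = ea[i - 1];
    const float* srow = (ca >= 0) ? &sm.s[ca * sm.n] : NULL;
    for (size_t j = 1; j <= n; ++j) {
      float e = std::max(Hi[j - 1] - goe, Ei[j - 1] - ge);
      float f = std::max(Hp[j] - goe, Fp[j] - ge);
      int cb = eb[j - 1];
      float s = (srow && cb >= 0) ? srow[cb] : sm.minval;
      float d = Hp[j - 1] + s;
      float h = std::max(0.0f, std::max(d, std::max(e, f)));
      Ei[j] = e; Fi[j] = f; Hi[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0f) return out;
  out.found = true;
  out.score = best;
  // traceback from (bi, bj), state H
  size_t i = bi, j = bj;
  int n_id = 0, len = 0;
  std::string aq, as;
  int state = 0;  // 0 = H, 1 = F (gap in b), 2 = E (gap in a)
  while (true) {
    if (state == 0) {
      float h = H[i * W + j];
      if (h <= 0.0f || i == 0 || j == 0) break;
      float d = H[(i - 1) * W + j - 1] + sm.score(a[i - 1], b[j - 1]);
      if (h == d) {
        unsigned char ca = a[i - 1], cb = b[j - 1];
        bool id = (ca == cb) && (!nt_mode || is_acgt(ca));
        if (id) ++n_id;
        ++len;
        if (want_aln) { aq.push_back(ca); as.push_back(cb); }
        --i; --j;
      } else if (h == F[i * W + j]) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++len;
      if (want_aln) { aq.push_back(a[i - 1]); as.push_back('-'); }
      if (F[i * W + j] == H[(i - 1) * W + j] - go - ge) state = 0;
      --i;
    } else {
      ++len;
      if (want_aln) { aq.push_back('-'); as.push_back(b[j - 1]); }
      if (E[i * W + j] == H[i * W + j - 1] - go - ge) state = 0;
      --j;
    }
  }
  out.qstart = (int)i; out.qend = (int)bi;
  out.sstart = (int)j; out.send = (int)bj;
  out.n_id = n_id; out.aln_len = len;
  if (want_aln) {
    std::reverse(aq.begin(), aq.end());
    std::reverse(as.begin(), as.end());
    out.aq = aq; out.as = as;
  }
  return out;
}

// Global Needleman-Wunsch with affine gaps (end gaps penalized).
static AlnOut nw_affine(const std::string& a, const std::string& b,
                        const SubMat& sm, float go, float ge, bool nt_mode) {
  AlnOut out;
  size_t m = a.size(), n = b.size();
  if ((double)(m + 1) * (n + 1) > 6.5e7) stop("alignment problem too large");
  size_t W = n + 1;
  std::vector<float> H((m + 1) * (n + 1), NEG_INF);
  std::vector<float> E((m + 1) * (n + 1), NEG_INF);
  std::vector<float> F((m + 1) * (n + 1), NEG_INF);
  H[0] = 0.0f;
  for (size_t j = 1; j <= n; ++j) {
    E[j] = -go - (float)j * ge;
    H[j] = E[j];
  }
  for (size_t i = 1; i <= m; ++i) {
    F[i * W] = -go - (float)i * ge;
    H[i * W] = F[i * W];
  }
  for (size_t i = 1; i <= m; ++i) {
    for (size_t j = 1; j <= n; ++j) {
      float e = std::max(H[i * W + j - 1] - go - ge, E[i * W + j - 1] - ge);
      float f = std::max(H[(i - 1) * W + j] - go - ge, F[(i - 1) * W + j] - ge);
      float d = H[(i - 1) * W + j - 1] + sm.score(a[i - 1], b[j - 1]);
      E[i * W + j] = e; F[i * W + j] = f;
      H[i * W + j] = std::max(d, std::max(e, f));
    }
  }
  out.found = true;
  out.score = H[m * W + n];
  size_t i = m, j = n;
  int n_id = 0, len = 0;
  std::string aq, as;
  int state = 0;
  // resolve final state
  if (i > 0 && j > 0) {
    float h = H[i * W + j];
    if (h == F[i * W + j]) state = 1;
    else if (h == E[i * W + j]) state = 2;
    float d = H[(i - 1) * W + j - 1] + sm.score(a[i - 1], b[j - 1]);
    if (h == d) state = 0;
  } else if (i > 0) state = 1;
  else if (j > 0) state = 2;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      float h = H[i * W + j];
      float d = H[(i - 1) * W + j - 1] + sm.score(a[i - 1], b[j - 1]);
      if (h == d) {
        unsigned char ca = a[i - 1], cb = b[j - 1];
        bool id = (ca == cb) && (!nt_mode || is_acgt(ca));
        if (id) ++n_id;
        ++len;
        aq.push_back(ca); as.push_back(cb);
        --i; --j;
        if (i > 0 && j > 0) {
          float h2 = H[i * W + j];
          float d2 = H[(i - 1) * W + j - 1] + sm.score(a[i - 1], b[j - 1]);
          if (h2 == d2) state = 0;
          else if (h2 == F[i * W + j]) state = 1;
          else state = 2;
        }
      } else if (h == F[i * W + j]) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++len;
      aq.push_back(a[i - 1]); as.push_back('-');
      if (F[i * W + j] == H[(i - 1) * W + j] - go - ge) {
        --i;
        if (i > 0 && j > 0) {
          float h2 = H[i * W + j];
          float d2 = H[(i - 1) * W + j - 1] + sm.score(a[i - 1], b[j - 1]);
          if (h2 == d2) state = 0;
          else if (h2 == F[i * W + j]) state = 1;
          else state = 2;
        } else state = 0;
      } else --i;
    } else {
      ++len;
      aq.push_back('-'); as.push_back(b[j - 1]);
      if (E[i * W + j] == H[i * W + j - 1] - go - ge) {
        --j;
        if (i > 0 && j > 0) {
          float h2 = H[i * W + j];
          float d2 = H[(i - 1) * W + j - 1] + sm.score(a[i - 1], b[j - 1]);
          if (h2 == d2) state = 0;
          else if (h2 == F[i * W + j]) state = 1;
          else state = 2;
        } else state = 0;
      } else --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(as.begin(), as.end());
  out.aq = aq; out.as = as;
  out.qstart = 0; out.qend = (int)m;
  out.sstart = 0; out.send = (int)n;
  out.n_id = n_id; out.aln_len = len;
  return out;
}

static List aln_to_list(const AlnOut& o, bool want_aln) {
  List L = List::create(
    _["score"] = (double)o.score,
    _["qstart"] = o.qstart, _["qend"] = o.qend,
    _["sstart"] = o.sstart, _["send"] = o.send,
    _["n_id"] = o.n_id, _["aln_len"] = o.aln_len);
  if (want_aln) {
    L["aligned_query"] = o.aq;
    L["aligned_subject"] = o.as;
  }
  return L;
}

// [[Rcpp::export]]
SEXP cpp_sw_align(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_extend, bool nt_mode,
                  bool want_aln) {
  SubMat sm = make_submat(submat);
  AlnOut o = sw_affine(a, b, sm, (float)gap_open, (float)gap_extend,
                       nt_mode, want_aln);
  if (!o.found) return R_NilValue;
  return aln_to_list(o, want_aln);
}

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_extend, bool nt_mode) {
  SubMat sm = make_submat(submat);
  AlnOut o = nw_affine(a, b, sm, (float)gap_open, (float)gap_extend, nt_mode);
  return aln_to_list(o, true);
}

// ---- seed-and-extend nucleotide search ------------------------------------

typedef std::unordered_map<uint32_t, std::vector<int> > KmerIndex;

static KmerIndex build_index(const std::string& s, int k) {
  KmerIndex idx;
  int n = (int)s.size();
  uint32_t code = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c;
    switch (s[i]) {
      case 'A': c = 0; break; case 'C': c = 1; break;
      case 'G': c = 2; break; case 'T': c = 3; break;
      default: c = -1;
    }
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run >= k) idx[code].push_back(i - k + 1);
  }
  return idx;
}

struct Cluster { int dmin, dmax, count; };

// Collect seed diagonals of query against an indexed subject and propose
// alignment windows. Returns best local alignment over the windows.
// min_count: evaluate only diagonal clusters holding at least this
// many seeds (used to cheapen the opposite-strand search when the
// primary strand already holds a well-seeded hit; sparsely seeded
// clusters are chance matches that cannot beat it).
static AlnOut seed_extend_core(const std::string& q, const std::string& s,
                               const KmerIndex& idx, int k,
                               const SubMat& sm, float go, float ge,
                               int band, int max_windows, bool want_aln,
                               int min_count = 1) {
  AlnOut best; best.found = false; best.score = 0; best.seed_count = 0;
  int nq = (int)q.size(), ns = (int)s.size();
  if (nq < k) return best;
  std::vector<int> diags;
  uint32_t code = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < nq; ++i) {
    int c;
    switch (q[i]) {
      case 'A': c = 0; break; case 'C': c = 1; break;
      case 'G': c = 2; break; case 'T': c = 3; break;
      default: c = -1;
    }
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run >= k) {
      int qpos = i - k + 1;
      KmerIndex::const_iterator it = idx.find(code);
      if (it != idx.end())
        for (size_t t = 0; t < it->second.size(); ++t)
          diags.push_back(it->second[t] - qpos);
    }
  }
  if (diags.empty()) return best;
  std::vector<std::pair<int, int> > windows;  // [start, end) on subject
  std::vector<int> wcount;
  bool small_subject = ((double)ns <= std::max(2000.0, 4.0 * nq)) &&
                       ((double)(nq + 1) * (ns + 1) <= 3.0e7);
  if (small_subject) {
    if ((int)diags.size() < min_count) return best;
    windows.push_back(std::make_pair(0, ns));
    wcount.push_back((int)diags.size());
  } else {
    std::sort(diags.begin(), diags.end());
    std::vector<Cluster> cl;
    Cluster cur; cur.dmin = cur.dmax = diags[0]; cur.count = 1;
    for (size_t t = 1; t < diags.size(); ++t) {
      if (diags[t] - cur.dmax <= band) { cur.dmax = diags[t]; ++cur.count; }
      else { cl.push_back(cur); cur.dmin = cur.dmax = diags[t]; cur.count = 1; }
    }
    cl.push_back(cur);
    std::stable_sort(cl.begin(), cl.end(),
                     [](const Cluster& x, const Cluster& y) {
                       if (x.count != y.count) return x.count > y.count;
                       return x.dmin < y.dmin;
                     });
    // prefer well-seeded regions: when any cluster has >= 2 seeds,
    // clusters far below the best seed count are almost surely chance
    // matches and are dropped
    if (cl[0].count >= 2) {
      int thr = std::max(2, cl[0].count / 8);
      size_t keep = 0;
      while (keep < cl.size() && cl[keep].count >= thr) ++keep;
      cl.resize(keep);
    }
    if (cl[0].count < min_count) return best;
    int take = std::min((int)cl.size(), max_windows);
    for (int t = 0; t < take; ++t) {
      int ws = std::max(0, cl[t].dmin - band);
      int we = std::min(ns, cl[t].dmax + nq + band);
      if (we > ws) {
        windows.push_back(std::make_pair(ws, we));
        wcount.push_back(cl[t].count);
      }
    }
  }
  for (size_t w = 0; w < windows.size(); ++w) {
    std::string sub = s.substr(windows[w].first,
                               windows[w].second - windows[w].first);
    AlnOut o = sw_affine(q, sub, sm, go, ge, true, want_aln);
    if (!o.found) continue;
    o.sstart += windows[w].first;
    o.send += windows[w].first;
    if (!best.found || o.score > best.score ||
        (o.score == best.score && o.sstart < best.sstart)) {
      best = o;
      best.seed_count = wcount[w];
    }
  }
  return best;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break; case 'T': r[i] = 'A'; break;
      case 'C': r[i] = 'G'; break; case 'G': r[i] = 'C'; break;
      case 'R': r[i] = 'Y'; break; case 'Y': r[i] = 'R'; break;
      case 'K': r[i] = 'M'; break; case 'M': r[i] = 'K'; break;
      case 'B': r[i] = 'V'; break; case 'V': r[i] = 'B'; break;
      case 'D': r[i] = 'H'; break; case 'H': r[i] = 'D'; break;
      default: break;  // N, S, W are self-complementary
    }
  }
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }

// Best local alignment of query against subject, both strands.
// Minus-strand hits are reported with query coordinates on the original
// query and strand "-" (subject coordinates always forward).
// [[Rcpp::export]]
SEXP cpp_seed_extend(std::string query, std::string subject,
                     NumericMatrix submat, double gap_open,
                     double gap_extend, int k, int band, int max_windows,
                     bool want_aln) {
  SubMat sm = make_submat(submat);
  KmerIndex idx = build_index(subject, k);
  float maxdiag = 0.0f;
  for (int i = 0; i < sm.n; ++i) maxdiag = std::max(maxdiag, sm.s[i * sm.n + i]);
  AlnOut fw = seed_extend_core(query, subject, idx, k, sm,
                               (float)gap_open, (float)gap_extend,
                               band, max_windows, want_aln);
  bool strong_fw = fw.found && fw.score >= 0.25f * maxdiag * query.size();
  bool perfect_fw = fw.found && fw.score >= maxdiag * query.size();
  int rc_floor = strong_fw ? std::max(3, fw.seed_count / 8) : 1;
  AlnOut rc;
  rc.found = false;
  if (!perfect_fw) {
    std::string qrc = revcomp_str(query);
    rc = seed_extend_core(qrc, subject, idx, k, sm,
                          (float)gap_open, (float)gap_extend,
                          band, max_windows, want_aln, rc_floor);
  }
  bool use_rc = rc.found && (!fw.found || rc.score > fw.score);
  if (!fw.found && !rc.found) return R_NilValue;
  AlnOut o = use_rc ? rc : fw;
  int nq = (int)query.size();
  List L = aln_to_list(o, want_aln);
  if (use_rc) {
    // map query span back to original (plus-strand) query coordinates
    int qs = nq - o.qend, qe = nq - o.qstart;
    L["qstart"] = qs; L["qend"] = qe;
    L["strand"] = "-";
  } else {
    L["strand"] = "+";
  }
  return L;
}

// Map many fragments onto one subject (index built once), both strands.
// [[Rcpp::export]]
DataFrame cpp_frag_map(CharacterVector frags, std::string subject,
                       NumericMatrix submat, double gap_open,
                       double gap_extend, int k, int band,
                       int max_windows) {
  SubMat sm = make_submat(submat);
  KmerIndex idx = build_index(subject, k);
  int nf = frags.size();
  NumericVector score(nf, NA_REAL);
  IntegerVector n_id(nf, NA_INTEGER), aln_len(nf, NA_INTEGER),
      qstart(nf, NA_INTEGER), qend(nf, NA_INTEGER),
      sstart(nf, NA_INTEGER), send(nf, NA_INTEGER);
  CharacterVector strand(nf, NA_STRING);
  float maxdiag = 0.0f;
  for (int t = 0; t < sm.n; ++t) maxdiag = std::max(maxdiag, sm.s[t * sm.n + t]);
  for (int i = 0; i < nf; ++i) {
    Rcpp::checkUserInterrupt();
    std::string q = as<std::string>(frags[i]);
    AlnOut fw = seed_extend_core(q, subject, idx, k, sm,
                                 (float)gap_open, (float)gap_extend,
                                 band, max_windows, false);
    bool strong_fw = fw.found && fw.score >= 0.25f * maxdiag * q.size();
    bool perfect_fw = fw.found && fw.score >= maxdiag * q.size();
    int rc_floor = strong_fw ? std::max(3, fw.seed_count / 8) : 1;
    AlnOut rc;
    rc.found = false;
    if (!perfect_fw) {
      std::string qrc = revcomp_str(q);
      rc = seed_extend_core(qrc, subject, idx, k, sm,
                            (float)gap_open, (float)gap_extend,
                            band, max_windows, false, rc_floor);
    }
    bool use_rc = rc.found && (!fw.found || rc.score > fw.score);
    if (!fw.found && !rc.found) continue;
    AlnOut o = use_rc ? rc : fw;
    score[i] = o.score;
    n_id[i] = o.n_id; aln_len[i] = o.aln_len;
    int nq = (int)q.size();
    if (use_rc) {
      qstart[i] = nq - o.qend; qend[i] = nq - o.qstart;
      strand[i] = "-";
    } else {
      qstart[i] = o.qstart; qend[i] = o.qend;
      strand[i] = "+";
    }
    sstart[i] = o.sstart; send[i] = o.send;
  }
  return DataFrame::create(
    _["score"] = score, _["n_id"] = n_id, _["aln_len"] = aln_len,
    _["qstart"] = qstart, _["qend"] = qend,
    _["sstart"] = sstart, _["send"] = send, _["strand"] = strand,
    _["stringsAsFactors"] = false);
}

// All-vs-all protein Smith-Waterman. Returns score, identities and
// alignment-column matrices (rows = a, cols = b).
// [[Rcpp::export]]
List cpp_aa_allvsall(CharacterVector seqs_a, CharacterVector seqs_b,
                     NumericMatrix submat, double gap_open,
                     double gap_extend) {
  SubMat sm = make_submat(submat);
  int na = seqs_a.size(), nb = seqs_b.size();
  NumericMatrix score(na, nb);
  IntegerMatrix n_id(na, nb), aln_len(na, nb);
  std::vector<std::string> sa(na), sb(nb);
  for (int i = 0; i < na; ++i) sa[i] = as<std::string>(seqs_a[i]);
  for (int j = 0; j < nb; ++j) sb[j] = as<std::string>(seqs_b[j]);
  for (int i = 0; i < na; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < nb; ++j) {
      AlnOut o = sw_affine(sa[i], sb[j], sm, (float)gap_open,
                           (float)gap_extend, false, false);
      if (o.found) {
        score(i, j) = o.score;
        n_id(i, j) = o.n_id;
        aln_len(i, j) = o.aln_len;
      } else {
        score(i, j) = 0; n_id(i, j) = 0; aln_len(i, j) = 0;
      }
    }
  }
  return List::create(_["score"] = score, _["n_id"] = n_id,
                      _["aln_len"] = aln_len);
}

// Global affine-gap path over a precomputed column-score matrix
// (profile-profile alignment). Returns 1-based column indices with 0 = gap.
// [[Rcpp::export]]
List cpp_nw_path(NumericMatrix colscore, double gap_open,
                 double gap_extend) {
  size_t m = colscore.nrow(), n = colscore.ncol();
  if ((double)(m + 1) * (n + 1) > 6.5e7) stop("profile alignment too large");
  float go = (float)gap_open, ge = (float)gap_extend;
  size_t W = n + 1;
  std::vector<float> H((m + 1) * (n + 1), NEG_INF);
  std::vector<float> E((m + 1) * (n + 1), NEG_INF);
  std::vector<float> F((m + 1) * (n + 1), NEG_INF);
  H[0] = 0.0f;
  for (size_t j = 1; j <= n; ++j) { E[j] = -go - (float)j * ge; H[j] = E[j]; }
  for (size_t i = 1; i <= m; ++i) {
    F[i * W] = -go - (float)i * ge; H[i * W] = F[i * W];
  }
  for (size_t i = 1; i <= m; ++i)
    for (size_t j = 1; j <= n; ++j) {
      float e = std::max(H[i * W + j - 1] - go - ge, E[i * W + j - 1] - ge);
      float f = std::max(H[(i - 1) * W + j] - go - ge, F[(i - 1) * W + j] - ge);
      float d = H[(i - 1) * W + j - 1] + (float)colscore(i - 1, j - 1);
      E[i * W + j] = e; F[i * W + j] = f;
      H[i * W + j] = std::max(d, std::max(e, f));
    }
  std::vector<int> ai, bi;
  size_t i = m, j = n;
  int state = 0;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    else {
      float h = H[i * W + j];
      float d = H[(i - 1) * W + j - 1] + (float)colscore(i - 1, j - 1);
      if (state == 0) {
        if (h == d) state = 0;
        else if (h == F[i * W + j]) state = 1;
        else state = 2;
      }
    }
    if (state == 0) {
      ai.push_back((int)i); bi.push_back((int)j);
      --i; --j;
    } else if (state == 1) {
      ai.push_back((int)i); bi.push_back(0);
      if (F[i * W + j] == H[(i - 1) * W + j] - go - ge) state = 0;
      --i;
    } else {
      ai.push_back(0); bi.push_back((int)j);
      if (E[i * W + j] == H[i * W + j - 1] - go - ge) state = 0;
      --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = (double)H[m * W + n],
                      _["ai"] = wrap(ai), _["bi"] = wrap(bi));
}

// First-order Markov chain sampler over A,C,G,T using R's RNG.
// P is the 4x4 row-stochastic transition matrix; init the start
// distribution.
// [[Rcpp::export]]
std::string cpp_markov_seq(NumericMatrix P, NumericVector init, int n) {
  if (P.nrow() != 4 || P.ncol() != 4 || init.size() != 4)
    stop("need 4x4 transition matrix and length-4 init");
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  std::string out(n, 'A');
  double cum[4][4];
  for (int i = 0; i < 4; ++i) {
    double c = 0;
    for (int j = 0; j < 4; ++j) { c += P(i, j); cum[i][j] = c; }
    for (int j = 0; j < 4; ++j) cum[i][j] /= c;
  }
  double ci[4]; double c = 0;
  for (int j = 0; j < 4; ++j) { c += init[j]; ci[j] = c; }
  for (int j = 0; j < 4; ++j) ci[j] /= c;
  double u = unif_rand();
  int cur = 0;
  while (cur < 3 && u > ci[cur]) ++cur;
  out[0] = bases[cur];
  for (int t = 1; t < n; ++t) {
    u = unif_rand();
    int nx = 0;
    while (nx < 3 && u > cum[cur][nx]) ++nx;
    out[t] = bases[nx];
    cur = nx;
  }
  return out;
}
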