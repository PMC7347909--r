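#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

// Local (Smith-Waterman-style) Viterbi over a linear profile of M match
// states with insert/delete states. Emission log-odds (log2 emission /
// background) are in emis_lo (nrow = alphabet size, ncol = M); insert
// emissions score 0 (background). trans_lo holds log2 transition
// probabilities: mm, mi, md, im, ii, dm, dd. Alignment may start at any
// match state at no cost and end at any match state; the score is the best
// local path score in bits.

static inline int aa_idx(const std::string& alphabet, char c) {
  size_t p = alphabet.find(c);
  return p == std::string::npos ? -1 : (int) p;
}

// [[Rcpp::export]]
NumericVector profile_viterbi_scores(NumericMatrix emis_lo, NumericVector trans_lo,
                                     CharacterVector prots, std::string alphabet) {
  int M = emis_lo.ncol();
  int A = emis_lo.nrow();
  double tmm = trans_lo[0], tmi = trans_lo[1], tmd = trans_lo[2];
  double tim = trans_lo[3], tii = trans_lo[4], tdm = trans_lo[5], tdd = trans_lo[6];
  const double NEG = -1e30;
  R_xlen_t n = prots.size();
  NumericVector out(n);
  // flat emission table: row ai holds the M state log-odds contiguously,
  // plus an all-zero row for unknown residues
  std::vector<double> E((A + 1) * M);
  for (int ai = 0; ai < A; ++ai)
    for (int j = 0; j < M; ++j) E[(size_t) ai * M + j] = emis_lo(ai, j);
  for (int j = 0; j < M; ++j) E[(size_t) A * M + j] = 0.0;
  std::vector<double> Mp(M + 1), Ip(M + 1), Dp(M + 1), Mc(M + 1), Ic(M + 1), Dc(M + 1);
  int idx_cache[256];
  for (int c = 0; c < 256; ++c) idx_cache[c] = A; // unknown -> zero row
  for (int j = 0; j < (int) alphabet.size(); ++j) idx_cache[(unsigned char) alphabet[j]] = j;

  for (R_xlen_t p = 0; p < n; ++p) {
    const char* q = CHAR(STRING_ELT(prots, p));
    int L = (int) std::strlen(q);
    double best = 0.0; // empty local alignment scores 0
    for (int j = 0; j <= M; ++j) { Mp[j] = NEG; Ip[j] = NEG; Dp[j] = NEG; }
    double *mp = Mp.data(), *ip = Ip.data(), *dp = Dp.data();
    double *mc = Mc.data(), *ic = Ic.data(), *dc = Dc.data();
    for (int i = 1; i <= L; ++i) {
      const double* erow = &E[(size_t) idx_cache[(unsigned char) q[i - 1]] * M];
      mc[0] = NEG; ic[0] = NEG; dc[0] = NEG;
      for (int j = 1; j <= M; ++j) {
        double m = 0.0; // free local entry
        double a = mp[j - 1] + tmm;
        double b = ip[j - 1] + tim;
        double d = dp[j - 1] + tdm;
        if (a > m) m = a;
        if (b > m) m = b;
        if (d > m) m = d;
        double vm = erow[j - 1] + m;
        mc[j] = vm;
        if (vm > best) best = vm;
        double vi = mp[j] + tmi;
        double vi2 = ip[j] + tii;
        ic[j] = vi2 > vi ? vi2 : vi;
        double vd = mc[j - 1] + tmd;
        double vd2 = dc[j - 1] + tdd;
        dc[j] = vd2 > vd ? vd2 : vd;
      }
      std::swap(mp, mc); std::swap(ip, ic); std::swap(dp, dc);
    }
    out[p] = best;
  }
  return out;
}

// Full Viterbi with traceback for a single query: returns the score, the
// query span of the best local path, and the match-state index aligned to
// each query position (0 = not a match state).
// [[Rcpp::export]]
List profile_viterbi_align(NumericMatrix emis_lo, NumericVector trans_lo,
                           std::string q, std::string alphabet) {
  int M = emis_lo.ncol();
  int A = emis_lo.nrow();
  int L = q.size();
  double tmm = trans_lo[0], tmi = trans_lo[1], tmd = trans_lo[2];
  double tim = trans_lo[3], tii = trans_lo[4], tdm = trans_lo[5], tdd = trans_lo[6];
  const double NEG = -1e30;
  // state matrices (L+1) x (M+1); pointers: 0 none/start, 1 M, 2 I, 3 D
  std::vector<std::vector<double> > VM(L + 1, std::vector<double>(M + 1, NEG));
  std::vector<std::vector<double> > VI(L + 1, std::vector<double>(M + 1, NEG));
  std::vector<std::vector<double> > VD(L + 1, std::vector<double>(M + 1, NEG));
  std::vector<std::vector<signed char> > PM(L + 1, std::vector<signed char>(M + 1, 0));
  std::vector<std::vector<signed char> > PI(L + 1, std::vector<signed char>(M + 1, 0));
  std::vector<std::vector<signed char> > PD(L + 1, std::vector<signed char>(M + 1, 0));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    int ai = aa_idx(alphabet, q[i - 1]);
    for (int j = 1; j <= M; ++j) {
      double e = (ai >= 0 && ai < A) ? emis_lo(ai, j - 1) : 0.0;
      double m = 0.0; signed char ptr = 0;
      if (VM[i - 1][j - 1] + tmm > m) { m = VM[i - 1][j - 1] + tmm; ptr = 1; }
      if (VI[i - 1][j - 1] + tim > m) { m = VI[i - 1][j - 1] + tim; ptr = 2; }
      if (VD[i - 1][j - 1] + tdm > m) { m = VD[i - 1][j - 1] + tdm; ptr = 3; }
      VM[i][j] = e + m; PM[i][j] = ptr;
      if (VM[i][j] > best) { best = VM[i][j]; bi = i; bj = j; }
      double vi_ = VM[i - 1][j] + tmi; signed char pi_ = 1;
      if (VI[i - 1][j] + tii > vi_) { vi_ = VI[i - 1][j] + tii; pi_ = 2; }
      VI[i][j] = vi_; PI[i][j] = pi_;
      double vd_ = VM[i][j - 1] + tmd; signed char pd_ = 1;
      if (VD[i][j - 1] + tdd > vd_) { vd_ = VD[i][j - 1] + tdd; pd_ = 3; }
      VD[i][j] = vd_; PD[i][j] = pd_;
    }
  }
  IntegerVector path(L, 0);
  int qstart = 0, qend = 0;
  if (bi > 0) {
    qend = bi;
    int i = bi, j = bj, state = 1;
    while (i > 0 && j > 0) {
      if (state == 1) {
        path[i - 1] = j;
        qstart = i;
        signed char ptr = PM[i][j];
        --i; --j;
        if (ptr == 0) break;
        state = ptr;
      } else if (state == 2) {
        signed char ptr = PI[i][j];
        --i;
        state = ptr;
      } else {
        signed char ptr = PD[i][j];
        --j;
        state = ptr;
      }
    }
  }
  return List::create(_["score"] = best, _["qstart"] = qstart, _["qend"] = qend,
                      _["state_path"] = path);
}

// k-mer prescreen: TRUE if the protein shares at least one length-k word
// with the profile consensus. Used as an optional accelerator before exact
// Viterbi scoring of large ORF sets.
// [[Rcpp::export]]
LogicalVector kmer_prescreen_cpp(CharacterVector prots, std::string consensus, int k) {
  std::unordered_set<uint64_t> words;
  int Lc = consensus.size();
  for (int i = 0; i + k <= Lc; ++i) {
    uint64_t h = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      char c = consensus[i + j];
      if (c < 'A' || c > 'Z') { ok = false; break; }
      h = h * 26u + (uint64_t)(c - 'A');
    }
    if (ok) words.insert(h);
  }
  R_xlen_t n = prots.size();
  LogicalVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    std::string q = as<std::string>(prots[p]);
    int L = q.size();
    bool hit = false;
    for (int i = 0; i + k <= L && !hit; ++i) {
      uint64_t h = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        char c = q[i + j];
        if (c < 'A' || c > 'Z') { ok = false; break; }
        h = h * 26u + (uint64_t)(c - 'A');
      }
      if (ok && words.count(h)) hit = true;
    }
    out[p] = hit;
  }
  return out;
}
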