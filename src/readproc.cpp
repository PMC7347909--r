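#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <string>
using namespace Rcpp;

std::string revcomp_str(const std::string& s);

// Remove the longest 3' suffix of each read that matches a prefix of the
// adapter with <= max_mm_frac mismatches, requiring >= min_match bases.
// Qualities are trimmed in lockstep. No match leaves the read unchanged.
// [[Rcpp::export]]
List trim_adapter_cpp(CharacterVector seqs, CharacterVector quals,
                      std::string adapter, double max_mm_frac, int min_match) {
  R_xlen_t n = seqs.size();
  CharacterVector out_s(n), out_q(n);
  IntegerVector n_removed(n);
  int alen = adapter.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    int L = s.size();
    int kmax = std::min(L, alen);
    int found = 0;
    for (int k = kmax; k >= min_match; --k) {
      int cap = (int) std::floor(max_mm_frac * k);
      int mm = 0;
      bool ok = true;
      const char* suf = s.c_str() + (L - k);
      for (int j = 0; j < k; ++j) {
        if (suf[j] != adapter[j]) {
          if (++mm > cap) { ok = false; break; }
        }
      }
      if (ok) { found = k; break; }
    }
    if (found > 0) {
      out_s[i] = s.substr(0, L - found);
      out_q[i] = q.substr(0, L - found);
    } else {
      out_s[i] = s; out_q[i] = q;
    }
    n_removed[i] = found;
  }
  return List::create(_["seq"] = out_s, _["qual"] = out_q,
                      _["n_removed"] = n_removed);
}

// Overlap-consensus merging of a read pair. All offsets of revcomp(mate 2)
// against mate 1 are evaluated; the admissible offset (overlap >= min_overlap,
// mismatch fraction <= max_mm_frac) maximizing matches - mismatches wins,
// ties broken by larger overlap then smaller offset. Consensus takes the
// higher-quality base (quality = max Q on agreement, |Q1-Q2| on conflict;
// equal-quality conflicts emit 'N' at quality 0, which keeps merging
// symmetric under mate swap).
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector s1v, CharacterVector q1v,
                     CharacterVector s2v, CharacterVector q2v,
                     int min_overlap, double max_mm_frac) {
  R_xlen_t n = s1v.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector ovlen(n);
  LogicalVector merged(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(s1v[i]);
    std::string q1 = as<std::string>(q1v[i]);
    std::string s2 = as<std::string>(s2v[i]);
    std::string q2 = as<std::string>(q2v[i]);
    std::string r2 = revcomp_str(s2);
    std::string qr2(q2.rbegin(), q2.rend());
    int L1 = s1.size(), L2 = r2.size();
    int best_score = INT_MIN, best_d = 0, best_ov = 0;
    bool found = false;
    if (L1 >= min_overlap && L2 >= min_overlap) {
      // visit offsets in order of decreasing overlap so that, once a good
      // offset is found, offsets whose full overlap cannot beat its score
      // (score <= ov) are pruned; every admissible offset is still
      // considered
      std::vector<int> ds;
      ds.reserve(L1 + L2);
      for (int d = -(L2 - min_overlap); d <= L1 - min_overlap; ++d) ds.push_back(d);
      std::stable_sort(ds.begin(), ds.end(), [&](int x, int y) {
        int ovx = std::min(L1, x + L2) - std::max(0, x);
        int ovy = std::min(L1, y + L2) - std::max(0, y);
        if (ovx != ovy) return ovx > ovy;
        return x < y;
      });
      for (int d : ds) {
        int a = std::max(0, d);              // overlap start in s1 coords
        int b = std::min(L1, d + L2);        // overlap end in s1 coords
        int ov = b - a;
        if (ov < min_overlap) continue;
        if (found && ov <= best_score) break; // no remaining offset can win
        int cap = (int) std::floor(max_mm_frac * ov);
        int mm = 0;
        bool ok = true;
        const char* p1 = s1.c_str() + a;
        const char* p2 = r2.c_str() + (a - d);
        for (int j = 0; j < ov; ++j) {
          if (p1[j] != p2[j]) {
            if (++mm > cap) { ok = false; break; }
          }
        }
        if (!ok) continue;
        int score = (ov - mm) - mm;
        if (score > best_score ||
            (score == best_score && (ov > best_ov ||
             (ov == best_ov && d < best_d)))) {
          best_score = score; best_d = d; best_ov = ov; found = true;
        }
      }
    }
    if (!found) {
      mseq[i] = ""; mqual[i] = ""; ovlen[i] = 0; merged[i] = false;
      continue;
    }
    int d = best_d;
    int a = std::max(0, d), b = std::min(L1, d + L2);
    std::string cons, consq;
    cons.reserve(L1 + L2 - best_ov);
    consq.reserve(L1 + L2 - best_ov);
    if (d > 0) { cons += s1.substr(0, d); consq += q1.substr(0, d); }
    else if (d < 0) { cons += r2.substr(0, -d); consq += qr2.substr(0, -d); }
    for (int j = a; j < b; ++j) {
      char c1 = s1[j], c2 = r2[j - d];
      int Q1 = q1[j] - 33, Q2 = qr2[j - d] - 33;
      if (c1 == c2) {
        cons.push_back(c1);
        consq.push_back((char) (33 + std::max(Q1, Q2)));
      } else if (Q1 > Q2) {
        cons.push_back(c1); consq.push_back((char) (33 + (Q1 - Q2)));
      } else if (Q2 > Q1) {
        cons.push_back(c2); consq.push_back((char) (33 + (Q2 - Q1)));
      } else {
        cons.push_back('N'); consq.push_back('!');
      }
    }
    if (d + L2 > L1) { cons += r2.substr(L1 - d); consq += qr2.substr(L1 - d); }
    else if (d + L2 < L1) { cons += s1.substr(d + L2); consq += q1.substr(d + L2); }
    mseq[i] = cons; mqual[i] = consq; ovlen[i] = best_ov; merged[i] = true;
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual,
                      _["overlap_len"] = ovlen, _["merged"] = merged);
}

// Mean Phred score of each quality string (ASCII offset 33).
// [[Rcpp::export]]
NumericVector mean_phred_cpp(CharacterVector quals) {
  R_xlen_t n = quals.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    size_t L = std::strlen(q);
    if (L == 0) { out[i] = NA_REAL; continue; }
    long s = 0;
    for (size_t j = 0; j < L; ++j) s += q[j] - 33;
    out[i] = (double) s / (double) L;
  }
  return out;
}
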