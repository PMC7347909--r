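#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

std::string revcomp_str(const std::string& s);

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Six-frame maximal ORF caller: an ORF runs from a start codon to the next
// stop codon (coordinates include the stop); an open frame at the sequence
// end is emitted without a stop (truncated gene). The start codon is
// translated as Met, the rest under the supplied genetic code (table 11
// passed from R). Coordinates are 1-based inclusive on the forward strand.
// [[Rcpp::export]]
DataFrame predict_orfs_cpp(std::vector<std::string> seqs, int min_len_aa,
                           std::vector<std::string> start_codons,
                           std::vector<std::string> codon_names,
                           std::string codon_aas, bool both_strands) {
  char table[64];
  bool is_stop[64], is_start[64];
  for (int i = 0; i < 64; ++i) { table[i] = 'X'; is_stop[i] = false; is_start[i] = false; }
  for (size_t i = 0; i < codon_names.size(); ++i) {
    const std::string& cd = codon_names[i];
    int a = base_idx(cd[0]), b = base_idx(cd[1]), c = base_idx(cd[2]);
    if (a < 0 || b < 0 || c < 0) continue;
    int idx = 16 * a + 4 * b + c;
    table[idx] = codon_aas[i];
    if (codon_aas[i] == '*') is_stop[idx] = true;
  }
  for (const std::string& sc : start_codons) {
    int a = base_idx(sc[0]), b = base_idx(sc[1]), c = base_idx(sc[2]);
    if (a < 0 || b < 0 || c < 0) continue;
    is_start[16 * a + 4 * b + c] = true;
  }

  std::vector<int> o_seq, o_start, o_end;
  std::vector<std::string> o_strand, o_prot;

  std::vector<signed char> bi;
  for (size_t si = 0; si < seqs.size(); ++si) {
    int L = seqs[si].size();
    int nstr = both_strands ? 2 : 1;
    for (int st = 0; st < nstr; ++st) {
      std::string s = (st == 0) ? seqs[si] : revcomp_str(seqs[si]);
      bi.assign(L, -1);
      for (int p = 0; p < L; ++p) bi[p] = (signed char) base_idx(s[p]);
      for (int frame = 0; frame < 3; ++frame) {
        int ncod = (L - frame) / 3;
        int cur = -1; // codon index of current ORF start
        for (int ci = 0; ci <= ncod; ++ci) {
          bool at_end = (ci == ncod);
          int idx = -1;
          bool stop = false;
          if (!at_end) {
            int p = frame + 3 * ci;
            int a = bi[p], b = bi[p + 1], c = bi[p + 2];
            if (a >= 0 && b >= 0 && c >= 0) {
              idx = 16 * a + 4 * b + c;
              stop = is_stop[idx];
            }
          }
          if (at_end || stop) {
            if (cur >= 0) {
              int len_aa = ci - cur;
              if (len_aa >= min_len_aa) {
                std::string prot;
                prot.reserve(len_aa);
                for (int k = cur; k < ci; ++k) {
                  if (k == cur) { prot.push_back('M'); continue; }
                  int p = frame + 3 * k;
                  int a = bi[p], b = bi[p + 1], c = bi[p + 2];
                  prot.push_back((a >= 0 && b >= 0 && c >= 0) ? table[16 * a + 4 * b + c] : 'X');
                }
                int lstart = frame + 3 * cur + 1;               // 1-based local
                int lend = frame + 3 * ci + (stop ? 3 : 0);     // include stop
                if (at_end) lend = frame + 3 * ci;
                int fstart, fend;
                if (st == 0) { fstart = lstart; fend = lend; }
                else { fstart = L - lend + 1; fend = L - lstart + 1; }
                o_seq.push_back((int) si + 1);
                o_start.push_back(fstart);
                o_end.push_back(fend);
                o_strand.push_back(st == 0 ? "+" : "-");
                o_prot.push_back(prot);
              }
            }
            cur = -1;
          } else if (cur < 0 && idx >= 0 && is_start[idx]) {
            cur = ci;
          }
        }
      }
    }
  }
  return DataFrame::create(_["seq_idx"] = o_seq, _["start"] = o_start,
                           _["end"] = o_end, _["strand"] = o_strand,
                           _["protein"] = o_prot,
                           _["stringsAsFactors"] = false);
}
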