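#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[i] = comp_base(s[s.size() - 1 - i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  return out;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Paired-end shotgun simulator. Fragment lengths are truncated-normal on
// [min_frag, genome length]; fragments are drawn from genomes with the
// probabilities in `cdf` (precomputed in R, proportional to relative
// abundance x genome length) and a uniform start; orientation is random.
// When the fragment is shorter than the read, the adapter (then random
// bases) is read through. Substitution errors and two-state (high/low)
// per-base qualities are applied independently. Uses R's RNG, so results
// are reproducible under set.seed().
// [[Rcpp::export]]
List simulate_pairs_cpp(std::vector<std::string> genomes, NumericVector cdf,
                        int n_pairs, int read_len, double insert_mean,
                        double insert_sd, int min_frag, double per_base_error,
                        std::string adapter, double p_low, int q_low, int q_high) {
  int ng = genomes.size();
  IntegerVector genome_idx(n_pairs), frag_start(n_pairs), frag_len(n_pairs);
  LogicalVector flipped(n_pairs);
  CharacterVector s1(n_pairs), q1(n_pairs), s2(n_pairs), q2(n_pairs);

  for (int p = 0; p < n_pairs; ++p) {
    double u = R::runif(0.0, 1.0);
    int g = 0;
    while (g < ng - 1 && u > cdf[g]) ++g;
    int glen = genomes[g].size();
    int lo = std::min(min_frag, glen);
    int flen;
    if (insert_sd <= 0.0) {
      flen = (int) std::round(insert_mean);
      if (flen < lo) flen = lo;
      if (flen > glen) flen = glen;
    } else {
      int tries = 0;
      do {
        flen = (int) std::round(R::rnorm(insert_mean, insert_sd));
        ++tries;
      } while ((flen < lo || flen > glen) && tries < 1000);
      if (flen < lo) flen = lo;
      if (flen > glen) flen = glen;
    }
    int start = (int) std::floor(R::runif(0.0, (double) (glen - flen + 1)));
    if (start > glen - flen) start = glen - flen;
    std::string frag = genomes[g].substr(start, flen);
    bool flip = R::runif(0.0, 1.0) < 0.5;
    if (flip) frag = revcomp_str(frag);

    int rl = std::min(read_len, flen);
    std::string r1 = frag.substr(0, rl);
    std::string fr = revcomp_str(frag);
    std::string r2 = fr.substr(0, rl);
    if (flen < read_len) { // adapter read-through; reads end at the adapter
      int need = std::min(read_len - flen, (int) adapter.size());
      r1 += adapter.substr(0, need);
      r2 += adapter.substr(0, need);
    }

    // substitution errors
    if (per_base_error > 0) {
      for (std::string* r : {&r1, &r2}) {
        for (size_t i = 0; i < r->size(); ++i) {
          if (R::runif(0.0, 1.0) < per_base_error) {
            char cur = (*r)[i];
            char nb;
            do { nb = BASES[(int) std::floor(R::runif(0.0, 4.0))]; } while (nb == cur);
            (*r)[i] = nb;
          }
        }
      }
    }

    // two-state qualities
    std::string qs1(r1.size(), '!'), qs2(r2.size(), '!');
    for (size_t i = 0; i < r1.size(); ++i)
      qs1[i] = (char) (33 + ((R::runif(0.0, 1.0) < p_low) ? q_low : q_high));
    for (size_t i = 0; i < r2.size(); ++i)
      qs2[i] = (char) (33 + ((R::runif(0.0, 1.0) < p_low) ? q_low : q_high));

    genome_idx[p] = g + 1;
    frag_start[p] = start + 1;
    frag_len[p] = flen;
    flipped[p] = flip;
    s1[p] = r1; q1[p] = qs1; s2[p] = r2; q2[p] = qs2;
  }
  return List::create(_["genome_idx"] = genome_idx, _["frag_start"] = frag_start,
                      _["frag_len"] = frag_len, _["flipped"] = flipped,
                      _["seq1"] = s1, _["qual1"] = q1,
                      _["seq2"] = s2, _["qual2"] = q2);
}
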