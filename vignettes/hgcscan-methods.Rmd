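---
title: "Detecting mercury-methylation marker genes in shotgun metagenomes"
author: "hgcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mercury-methylation marker genes in shotgun metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microbial methylation of inorganic mercury to neurotoxic methylmercury
(MeHg) is carried out by organisms bearing the paired genes *hgcA* (a
corrinoid methyltransferase-like protein with a catalytically required
cysteine in its "cap helix") and *hgcB* (a small ferredoxin with duplicated
`CX2CX2CX3C` metal-binding motifs). In seawater surveys, the abundance of
these markers in shotgun metagenomes — normalized to the essential
single-copy gene *recA* — is compared against total mercury (THg) and MeHg
depth profiles to ask where in the water column methylators plausibly live.

`hgcscan` implements that analysis as a tested pipeline:

1. **Read processing** — adapter trimming, overlap merging of 2 × 250 bp
   mates from ~350 bp inserts, and a quality/length filter (mean Phred ≥ 20,
   length ≥ 300 bp).
2. **Marker search** — six-frame ORF prediction under NCBI translation
   table 11; profile models built from reference alignments; local Viterbi
   scoring with Gumbel-calibrated E-values at a 1e-5 cutoff.
3. **Validation** — hgcA hits must align a cysteine to reference column 93
   within a cap-helix window; hgcB hits need two non-overlapping ferredoxin
   motifs; contig-scale sequences additionally face 175/50 aa length and
   50% gap rules.
4. **Quantification** — per-fragment counting, *recA* normalization, and
   recovery diagnostics against synthetic ground truth.
5. **Pathway context** — KEGG-style module completion ratios (MCR) and
   ribosomal-protein-normalized module abundances from KO tables.
6. **Statistics** — Hg unit conversions, censoring of below-detection
   values to zero, and Spearman correlation of marker abundance with
   THg/MeHg profiles.

Every stage runs against synthetic data with known ground truth, so the
package needs no sequence download to be exercised end to end.

## The profile model and its E-values

Profiles are linear position-specific models with one match state per
alignment column whose gap fraction is at most 0.5. Match emissions are
pseudocounted frequencies, `(count + w·bg) / (n_nongap + w)` with `w = 1`
by default; the background `bg` is pooled over the whole alignment with
add-one smoothing so log-odds stay finite. Global match/insert/delete
transition probabilities are estimated from the alignment's gap structure
with add-one pseudocounts. Scoring is a local (Smith–Waterman-style)
Viterbi pass in log2 odds: alignment may enter and leave at any match
state at no cost, so the empty alignment scores 0 and appending residues
to a query can never lower its score. Viterbi rather than forward scoring
keeps the statistic deterministic and exactly checkable; at the E ≤ 1e-5
operating point the difference is immaterial.

E-values use a Gumbel law fitted by maximum likelihood to the scores of
`n_null = 1000` seeded random sequences drawn from the profile background
(length = median reference length): `E = N_targets · exp(−(S − μ)/β)`.
The suite checks both parameter recovery on synthetic Gumbel draws and
the uniformity of null E-values at the 0.1 tail. For large ORF sets the
search first requires a shared consensus 5-mer (an accelerator in the
spirit of the fast filters of production HMM search tools); the exact
scorer is always available via `method = "exact"`, and all contract tests
use it.

## Validation rules

The cap-helix pattern for HgcA is configurable; the default window
`N[VI]WCA[AG]GK` anchors the conserved cysteine at reference column 93,
following the hgcA literature — only the cysteine itself is universally
agreed, so the pattern is a user-level parameter, not a constant. A hit
whose alignment does not cover the motif window fails validation with the
logged reason `"motif region not covered"` rather than erroring: on
~350 bp fragments partial coverage is the normal case, and the read-level
counting rule (no motif, no count) is what the quantification applies. For
HgcB, two non-overlapping `CX2CX2CX3C` occurrences are required, counted
left to right — the strictest reading of "two strictly conserved motifs".
Length/gap rules (175 aa for hgcA, 50 aa for hgcB, ≤ 50% aligned gaps) are
exposed separately (`apply_length_rules()`) because they belong to the
contig/phylogeny path, not to read-level counting.

## What the synthetic data emulates — and what it does not

`family_spec()`/`make_reference_family()` generate aligned families by
seeded per-site substitution around a random ancestor, with motif columns
frozen; defaults mirror the curated reference sets for these genes
(145 hgcA-like members of 349 aa, 128 hgcB-like members of 99 aa, and a
50-member recA-like family of 353 aa, 5% per-site divergence). Communities
place back-translated members (uniform synonymous codons, trailing TAA) at
known coordinates in random genome backbones; the abundance-weighted copy
ratio is therefore known exactly. Reads follow the survey library design this emulates:
2 × 250 bp pairs from truncated-normal ~350 ± 30 bp fragments, adapter
read-through for short fragments, independent substitution errors
(0.1%/base by default), and two-state per-base qualities (Phred 38/11,
5% low) so the Q < 20 filter has real work. Sequencing depth per sample is
a free parameter; the recovery analyses
below use 50 000 pairs per sample.

Deliberately not modeled: instrument-specific error profiles, quality
decay along the read, chimeras, GC bias, and real phylogenetic structure
within families. Passing tests therefore demonstrate the correctness of
the pipeline's logic and its statistical calibration on idealized
libraries, not robustness to every real-data artifact.

## Recovery of spiked copy ratios

The read pipeline does not estimate the raw copy ratio: detection is
length- and motif-weighted. A fragment counts for *recA* when it yields an
in-frame ORF long enough to clear the score threshold anywhere on the
gene; it counts for *hgcA* only when its ORF also covers the full
cap-helix window. `expected_detected_ratio()` computes the resulting
expectation independently of the search code, by Monte Carlo over the
fragment geometry on the actual placed gene sequences: truncated-normal
fragment lengths (conditioned on the ≥ 300 bp filter), uniform positions,
first in-frame start codon, minimum aligned length derived from the
profile's calibration (`min_alignment_length()`), motif-window coverage,
and an analytic `(1 − e)^span` attrition for sequencing errors across the
motif. Known approximations, each small and documented here: ORFs starting
in the flanking sequence upstream of a gene are ignored; consensus error
correction in the mate overlap makes the motif attrition slightly
conservative; fragments at genome edges are not special-cased. The
acceptance suite simulates hgcA:recA ∈ {0.1, 0.5, 1.0}% at 50 000 pairs ×
10 seeds and requires agreement with this expectation within 3 binomial
standard errors per ratio and a precision-weighted relative bias below 10%
across the grid; a separate depth ladder (4 000/12 000/50 000 pairs at 20/
14/10 seeds) checks that RMSE falls monotonically with depth. The seed
counts on the ladder were chosen a priori so that sampling noise in the
RMSE estimates is small relative to the expected √depth spacing.

## Merging and its tie rule

Merging evaluates every overlap offset between mate 1 and the reverse
complement of mate 2, keeping the admissible offset (overlap ≥ 10 bp,
mismatch fraction ≤ 10%) that maximizes matches − mismatches; ties prefer
the larger overlap, then the smaller offset. Offsets are visited in
decreasing-overlap order purely as a pruning device — the selected offset
is identical to the exhaustive scan. Consensus bases take the
higher-quality mate (quality `|Q1 − Q2|` at conflicts, `max(Q1, Q2)` at
agreements); an equal-quality conflict emits `N` at quality 0, which is
what makes merging exactly symmetric under swapping mates. The
observed-vs-expected alignment statistic of dedicated merge tools is not
reproduced: merging is preprocessing here, and the contract that matters —
exact fragment reconstruction on clean data, checked against simulator
coordinates — is tested directly. "Q-value < 20" is read as mean read
quality (the `min_qual_mean` convention); a per-base reading would be a
different, stricter filter, and the choice is configurable.

## Statistics conventions

Hg mass–molar conversions divide by the atomic mass of mercury
(200.59 g/mol) for both analytes; this is the basis under which the
reference-material pairs (1900 pg/L = 9.5 pM; 1.4 pg/L = 0.007 pM) round-trip,
whereas the molecular mass of CH3Hg+ would not reproduce them. Values
below a detection limit are set to zero for statistics — the standard
substitution rule in this survey literature — while undefined relative abundances (recA = 0) are dropped,
never zero-filled, since a zero there would fabricate signal. Spearman's
rho uses mid-ranks; for n < 10 the two-sided p-value is computed by
exhaustive enumeration of all n! orderings (exact under ties), and by the
t-approximation for n ≥ 10. The exact/approximate crossover at 10 keeps
every in-study sample size (n = 11, 19) on the approximate path while the
test suite verifies the enumerator against an independent oracle and
against `cor.test()` where both are exact.

The MCR of a module is `100 · satisfied / total` components (a component
is satisfied when any of its alternative KOs has a nonzero count), rounded
half-up to integer percent. The packaged worked example encodes the
reductive acetyl-CoA (Wood–Ljungdahl) module as ten single-KO components
in table row order; this reconstruction reproduces the packaged table's MCR row for
all 19 samples, which is the strongest empirical check available since
automated annotators do not export their Boolean module definitions. Module abundances
are normalized to a configurable ribosomal-protein KO list and
standardized per module with the population standard deviation for
heatmap display.

## Worked example

```{r, eval = FALSE}
library(hgcscan)

fams <- default_families()
profiles <- lapply(fams, build_profile)
profiles <- Map(calibrate, profiles, seed = 1:3)

comm <- make_spiked_community(0.5, fams, n_recA = 500, seed = 1)
pairs <- simulate_reads(comm, sim_config(n_pairs = 20000, seed = 2))
rec <- quantify_sample(pairs, profiles, sample_id = "St0_800m",
                       station = "St0", depth_m = 800)
rec$rel_hgcA_pct

# pathway context and chemistry
mcr(acetyl_coa_module(), acetyl_coa_ko_table())
hg <- make_hg_table(hg_table_spec(seed = 3))
```

## Numerical choices and degenerate inputs

Seeds are explicit everywhere randomness exists (families, communities,
reads, calibration, Monte Carlo expectations); functions restore the
caller's RNG state. The Gumbel fit solves the one-dimensional ML
fixed-point for β by bisection on `[0.02·sd, 10·sd]`, centered at the
sample minimum for overflow safety, and refuses degenerate
(zero-variance) null scores. Profile search of an empty protein set
returns an empty hit table; a constant vector yields `rho = NA` with a
warning rather than an error; correlation cells with fewer than three
joined samples are flagged `"insufficient"`. Coordinates are 1-based
inclusive in all outputs (0-based half-open only inside the C++ kernels).
ORFs at fragment ends without a stop codon are emitted as truncated genes;
a start codon is still required, which costs some detection efficiency on
gene-interior fragments and is accounted for by the detectability
emulator.

## Limitations

Detection counts are fragment-level; unmerged pairs are dropped rather
than analyzed single-end, matching the merged-read analysis unit. Absolute
gene abundances (per litre) are out of reach without spike-ins and are not
modeled. The lineage assigner is a nearest-reference classifier by global
percent identity — a deliberate stand-in for maximum-likelihood
phylogenetics, adequate for synthetic families but not a tree. Reproducing a real survey's correlation table requires that survey's own
abundance/chemistry values as input; the package provides the full
computation path and verifies its qualitative behavior on synthetic
surveys.
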