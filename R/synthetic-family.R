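# Synthetic reference protein families with embedded conserved motifs.

#' Specify a synthetic reference protein family
#'
#' Describes an aligned protein family generated by mutating a random
#' ancestor: `n_members` sequences of aligned length `length_aa`, with each
#' non-conserved position substituted independently with probability
#' `substitution_rate`. Motifs listed in `motif_rules` are embedded at the
#' columns in `motif_at` and those columns (plus `conserved_positions`) are
#' never mutated, so every member carries every embedded motif.
#'
#' @param family_id Family label (e.g. `"hgcA"`).
#' @param n_members Number of member sequences.
#' @param length_aa Aligned length in residues.
#' @param substitution_rate Per-site substitution probability in \[0, 1\].
#' @param motif_rules List of [motif_rule()] objects to embed.
#' @param motif_at Integer vector of 1-based start columns, one per rule.
#' @param conserved_positions Additional columns never mutated.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(family_id, n_members, length_aa, substitution_rate,
                        motif_rules = list(), motif_at = integer(),
                        conserved_positions = integer(), seed = NULL) {
  stopifnot(n_members >= 1, length_aa >= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            length(motif_rules) == length(motif_at))
  for (k in seq_along(motif_rules)) {
    r <- motif_rules[[k]]
    stopifnot(inherits(r, "motif_rule"))
    if (motif_at[k] < 1 || motif_at[k] + r$span - 1L > length_aa) {
      stop("motif '", r$rule_id, "' (span ", r$span, ") at column ", motif_at[k],
           " does not fit in an alignment of length ", length_aa, call. = FALSE)
    }
  }
  structure(list(family_id = family_id, n_members = as.integer(n_members),
                 length_aa = as.integer(length_aa),
                 substitution_rate = substitution_rate,
                 motif_rules = motif_rules, motif_at = as.integer(motif_at),
                 conserved_positions = as.integer(conserved_positions),
                 seed = seed),
            class = "family_spec")
}

#' Generate an aligned synthetic reference family
#'
#' Draws a random ancestor from the background residue distribution, embeds
#' the specified motifs, and derives members by independent per-site
#' substitution outside the conserved columns. All members have equal
#' aligned length and identical residues at motif columns. Deterministic for
#' a fixed seed.
#'
#' @param spec A [family_spec()].
#' @return An object of class `ref_family` with elements `family_id`,
#'   `members` (named character vector of aligned sequences), `ancestor`,
#'   `motif_rules`, `motif_at` and `conserved` (all frozen columns).
#' @export
#' @examples
#' fam <- make_reference_family(family_spec("toy", 5, 40, 0, seed = 1))
#' length(unique(fam$members))
make_reference_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    bg <- aa_background()
    letters20 <- aa_letters()
    anc <- sample(letters20, spec$length_aa, replace = TRUE, prob = bg)
    conserved <- spec$conserved_positions
    for (k in seq_along(spec$motif_rules)) {
      r <- spec$motif_rules[[k]]
      at <- spec$motif_at[k]
      inst <- sample_motif_instance(r)
      idx <- at:(at + r$span - 1L)
      anc[idx] <- inst
      conserved <- c(conserved, idx)
    }
    conserved <- sort(unique(conserved))
    conserved <- conserved[conserved >= 1 & conserved <= spec$length_aa]
    free <- setdiff(seq_len(spec$length_aa), conserved)
    members <- character(spec$n_members)
    for (m in seq_len(spec$n_members)) {
      s <- anc
      if (spec$substitution_rate > 0 && length(free) > 0) {
        hit <- free[runif(length(free)) < spec$substitution_rate]
        if (length(hit)) {
          # background-distributed replacements, resampling any draw that
          # equals the current residue
          repl <- sample(letters20, length(hit), replace = TRUE, prob = bg)
          same <- which(repl == s[hit])
          while (length(same)) {
            repl[same] <- sample(letters20, length(same), replace = TRUE,
                                 prob = bg)
            same <- same[repl[same] == s[hit][same]]
          }
          s[hit] <- repl
        }
      }
      members[m] <- paste(s, collapse = "")
    }
    names(members) <- sprintf("%s_%03d", spec$family_id, seq_len(spec$n_members))
    structure(list(family_id = spec$family_id, members = members,
                   ancestor = paste(anc, collapse = ""),
                   motif_rules = spec$motif_rules, motif_at = spec$motif_at,
                   conserved = conserved, spec = spec),
              class = "ref_family")
  })
}

#' @export
print.ref_family <- function(x, ...) {
  cat("<ref_family> ", x$family_id, ": ", length(x$members),
      " aligned members of length ", nchar(x$members[[1]]), " aa\n", sep = "")
  if (length(x$motif_rules)) {
    for (k in seq_along(x$motif_rules)) {
      cat("  motif ", x$motif_rules[[k]]$rule_id, " at column ",
          x$motif_at[k], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write an aligned family as FASTA
#' @param fam A `ref_family` (or any named character vector of sequences).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(fam, path) {
  seqs <- if (inherits(fam, "ref_family")) fam$members else fam
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read an aligned protein family from FASTA
#' @param path Aligned FASTA file (`-` for gaps).
#' @return Named character vector of aligned sequences.
#' @export
read_family_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

# default study families -----------------------------------------------------

#' Default synthetic study families
#'
#' The reference sets used throughout the synthetic study conditions:
#' an hgcA-like family (145 members, 349 aa, cap-helix motif with the
#' conserved Cys at column 93), an hgcB-like family (128 members, 99 aa, two
#' ferredoxin CX2CX2CX3C motifs), and a recA-like single-copy family
#' (50 members, 353 aa, no motif). All start with a conserved Met so that
#' back-translated genes begin with a genuine start codon. Member counts for
#' hgcA/hgcB mirror the sizes of curated reference sets for these genes.
#'
#' @param substitution_rate Per-site divergence of members from the ancestor.
#' @param seed Base seed; each family uses a fixed offset from it.
#' @return Named list of `ref_family` objects (`hgcA`, `hgcB`, `recA`).
#' @export
default_families <- function(substitution_rate = 0.05, seed = 20180313L) {
  capr <- cap_helix_rule()
  hgcA <- make_reference_family(family_spec(
    "hgcA", n_members = 145, length_aa = 349,
    substitution_rate = substitution_rate,
    motif_rules = list(capr), motif_at = capr$anchor_column - capr$anchor_offset + 1L,
    conserved_positions = 1L, seed = seed + 1L))
  ferr <- ferredoxin_rule()
  hgcB <- make_reference_family(family_spec(
    "hgcB", n_members = 128, length_aa = 99,
    substitution_rate = substitution_rate,
    motif_rules = list(ferr, ferr), motif_at = c(20L, 60L),
    conserved_positions = 1L, seed = seed + 2L))
  recA <- make_reference_family(family_spec(
    "recA", n_members = 50, length_aa = 353,
    substitution_rate = substitution_rate,
    conserved_positions = 1L, seed = seed + 3L))
  # ensure the conserved first residue is Met (real genes start with one)
  for (nm in c("hgcA", "hgcB", "recA")) {
    fam <- get(nm)
    substr(fam$ancestor, 1, 1) <- "M"
    fam$members <- vapply(fam$members, function(s) { substr(s, 1, 1) <- "M"; s },
                          character(1))
    assign(nm, fam)
  }
  list(hgcA = hgcA, hgcB = hgcB, recA = recA)
}
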