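# Validation of profile hits: conserved motifs, length/gap rules, and
# nearest-reference lineage assignment.

#' Validate an hgcA-like hit by its cap-helix cysteine
#'
#' Checks that the query residue aligned to the match state mapped from the
#' rule's anchor column (reference position 93 by default) is a cysteine and
#' that the query window aligned across the full motif span matches the
#' cap-helix pattern. A hit whose alignment does not cover the motif window
#' fails validation (reason `"motif region not covered"`) rather than
#' erroring.
#'
#' @param hit One row of an `hgc_hits` data frame (with `state_path`).
#' @param protein The query protein sequence.
#' @param profile The `hgc_profile` the hit came from.
#' @param rule A [cap_helix_rule()] (or compatible [motif_rule()]).
#' @return Logical; on failure the `reason` attribute explains why.
#' @export
validate_hgcA <- function(hit, protein, profile, rule = cap_helix_rule()) {
  path <- if (is.data.frame(hit)) hit$state_path[[1]] else hit$state_path
  if (is.null(path)) stop("hit carries no state path", call. = FALSE)
  anchor_state <- match(rule$anchor_column, profile$column_map)
  if (is.na(anchor_state)) {
    return(structure(FALSE, reason = "anchor column is not a match state"))
  }
  first_col <- rule$anchor_column - rule$anchor_offset + 1L
  needed_cols <- first_col:(first_col + rule$span - 1L)
  needed_states <- match(needed_cols, profile$column_map)
  if (anyNA(needed_states)) {
    return(structure(FALSE, reason = "motif columns are not all match states"))
  }
  qpos <- match(needed_states, path)
  if (anyNA(qpos)) {
    return(structure(FALSE, reason = "motif region not covered"))
  }
  res <- strsplit(toupper(protein), "")[[1]][qpos]
  anchor_res <- res[rule$anchor_offset]
  if (is.na(anchor_res) || anchor_res != "C") {
    return(structure(FALSE, reason = "anchor residue is not Cys"))
  }
  window <- paste(res, collapse = "")
  ok <- grepl(paste0("^", rule$pattern, "$"), window)
  if (!ok) {
    return(structure(FALSE, reason = "cap-helix window does not match pattern"))
  }
  structure(TRUE, reason = NA_character_)
}

#' Validate an hgcB-like sequence by its ferredoxin motifs
#'
#' TRUE iff the protein contains at least `min_occurrences` (default two)
#' non-overlapping `CX2CX2CX3C` motifs, scanned left to right.
#'
#' @param protein Protein sequence.
#' @param rule A [ferredoxin_rule()] (or compatible [motif_rule()]).
#' @return Logical.
#' @export
validate_hgcB <- function(protein, rule = ferredoxin_rule()) {
  count_motif(toupper(protein), rule) >= rule$min_occurrences
}

#' Define a minimum-length / gap-content rule
#' @param family_id Family label.
#' @param min_len_aa Minimum ungapped length in residues.
#' @param max_gap_frac Maximum aligned gap fraction.
#' @return An object of class `length_rule`.
#' @export
length_rule <- function(family_id, min_len_aa, max_gap_frac = 0.5) {
  stopifnot(min_len_aa > 0, max_gap_frac >= 0, max_gap_frac <= 1)
  structure(list(family_id = family_id, min_len_aa = as.integer(min_len_aa),
                 max_gap_frac = max_gap_frac),
            class = "length_rule")
}

#' Default length rules for contig-scale sequences
#'
#' Minimum ungapped lengths of 175 aa (hgcA) and 50 aa (hgcB) with at most
#' 50% aligned gaps, the filters applied to assembled sequences before
#' phylogenetic placement.
#'
#' @return Named list of [length_rule()] objects.
#' @export
default_length_rules <- function() {
  list(hgcA = length_rule("hgcA", 175L),
       hgcB = length_rule("hgcB", 50L))
}

#' Apply a family's length/gap rule
#'
#' TRUE iff the ungapped length meets the family minimum (175 aa for hgcA,
#' 50 aa for hgcB by default) and the aligned gap fraction does not exceed
#' the maximum. The protein may be supplied in aligned form (`-` gaps);
#' without gaps the gap fraction is zero.
#'
#' @param protein Protein sequence, possibly aligned.
#' @param family Family label; must be present in `rules`.
#' @param rules Named list of [length_rule()] objects.
#' @return Logical.
#' @export
apply_length_rules <- function(protein, family, rules = default_length_rules()) {
  rule <- rules[[family]]
  if (is.null(rule)) stop("no length rule for family '", family, "'",
                          call. = FALSE)
  chars <- strsplit(protein, "")[[1]]
  n_gap <- sum(chars %in% c("-", "."))
  len <- length(chars) - n_gap
  gap_frac <- if (length(chars)) n_gap / length(chars) else 0
  len >= rule$min_len_aa && gap_frac <= rule$max_gap_frac
}

#' Assign a nearest-reference lineage
#'
#' Globally aligns the query against every reference sequence and returns
#' the lineage label of the highest-identity reference; ties break to the
#' lexicographically first reference id. A stand-in for phylogenetic
#' placement on short sequences.
#'
#' @param protein Query protein.
#' @param references Named character vector of ungapped reference proteins.
#' @param lineages Optional named vector mapping reference ids to lineage
#'   labels (defaults to the reference ids themselves).
#' @return List with `lineage`, `ref_id` and `pid` (percent identity).
#' @export
assign_lineage <- function(protein, references, lineages = NULL) {
  stopifnot(length(references) >= 1)
  if (is.null(names(references))) {
    names(references) <- sprintf("ref%04d", seq_along(references))
  }
  lineages <- lineages %||% stats::setNames(names(references), names(references))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(rep(toupper(protein), length(references))),
    subject = Biostrings::AAStringSet(unname(toupper(references))),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pid <- Biostrings::pid(aln, type = "PID1")
  ord <- order(-pid, names(references))
  best <- ord[1]
  list(lineage = unname(lineages[names(references)[best]]),
       ref_id = names(references)[best], pid = pid[best])
}
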