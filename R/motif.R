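# Conserved-motif rules and scanning.

#' Define a conserved-motif rule
#'
#' A motif rule pairs an amino-acid pattern with a minimum occurrence count
#' and, optionally, an alignment anchor column. Patterns use a restricted
#' regular-expression syntax over the 20-letter alphabet: literal residues,
#' `.` or `x`/`X<n>` wildcards (so `"CX2CX2CX3C"` and `"C..C..C...C"` are the
#' same rule), and `[..]` residue classes.
#'
#' @param rule_id Label for the rule.
#' @param pattern Motif pattern (see Details).
#' @param min_occurrences Minimum number of non-overlapping occurrences.
#' @param anchor_column Optional 1-based reference-alignment column that must
#'   align to a specific residue of the motif (e.g. the cap-helix cysteine).
#' @param anchor_offset 1-based position of the anchored residue within the
#'   pattern (defaults to the first position).
#' @return An object of class `motif_rule`.
#' @export
#' @examples
#' ferredoxin_rule()
motif_rule <- function(rule_id, pattern, min_occurrences = 1L,
                       anchor_column = NULL, anchor_offset = 1L) {
  stopifnot(nzchar(pattern), min_occurrences >= 1)
  canon <- expand_motif_pattern(pattern)
  sets <- parse_motif_pattern(canon)
  structure(list(rule_id = rule_id, pattern = canon,
                 position_sets = sets, span = length(sets),
                 min_occurrences = as.integer(min_occurrences),
                 anchor_column = anchor_column,
                 anchor_offset = as.integer(anchor_offset)),
            class = "motif_rule")
}

# "CX2CX2CX3C" -> "C..C..C...C"; leaves plain regex-style patterns alone
expand_motif_pattern <- function(pattern) {
  out <- gsub("[xX](\\d+)", "\\1DOTS", pattern)
  while (grepl("\\d+DOTS", out)) {
    n <- as.integer(sub(".*?(\\d+)DOTS.*", "\\1", out))
    out <- sub("\\d+DOTS", paste(rep(".", n), collapse = ""), out)
  }
  gsub("[xX]", ".", out)
}

# split a canonical pattern into per-position residue sets (NULL = any)
parse_motif_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      cls <- character()
      while (j <= length(chars) && chars[j] != "]") {
        cls <- c(cls, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) stop("unterminated '[' in motif pattern", call. = FALSE)
      sets[[length(sets) + 1L]] <- cls
      i <- j + 1L
    } else if (ch == ".") {
      sets[length(sets) + 1L] <- list(NULL)
      i <- i + 1L
    } else {
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    }
  }
  sets
}

motif_regex <- function(rule) rule$pattern

#' Count non-overlapping motif occurrences
#'
#' Scans left to right and counts non-overlapping occurrences of the motif
#' in a protein sequence.
#'
#' @param protein Protein sequence (single string).
#' @param rule A [motif_rule()].
#' @return Integer count of non-overlapping occurrences.
#' @export
count_motif <- function(protein, rule) {
  stopifnot(inherits(rule, "motif_rule"))
  m <- gregexpr(motif_regex(rule), protein)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Locate non-overlapping motif occurrences
#' @inheritParams count_motif
#' @return Integer vector of 1-based match start positions.
#' @export
locate_motif <- function(protein, rule) {
  m <- gregexpr(motif_regex(rule), protein)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# sample one concrete residue string matching the rule (used for embedding)
sample_motif_instance <- function(rule) {
  vapply(rule$position_sets, function(s) {
    if (is.null(s)) sample(aa_letters(), 1L) else sample(c(s, s), 1L)
  }, character(1))
}

#' Cap-helix rule for HgcA
#'
#' Default validation rule for hgcA-like sequences: the cap-helix window
#' `N[VI]WCA[AG]GK` with the catalytic cysteine anchored at reference
#' alignment column 93 (pattern position 4). The pattern is overridable;
#' only the conserved cysteine itself is universally agreed.
#'
#' @param pattern Cap-helix pattern.
#' @param anchor_column Reference alignment column of the conserved Cys.
#' @return A [motif_rule()].
#' @export
cap_helix_rule <- function(pattern = "N[VI]WCA[AG]GK", anchor_column = 93L) {
  motif_rule("cap_helix", pattern, min_occurrences = 1L,
             anchor_column = as.integer(anchor_column), anchor_offset = 4L)
}

#' Ferredoxin metal-binding motif rule for HgcB
#'
#' Default validation rule for hgcB-like sequences: at least two strictly
#' conserved `CX2CX2CX3C` motifs.
#'
#' @return A [motif_rule()].
#' @export
ferredoxin_rule <- function() {
  motif_rule("ferredoxin_CXXC", "CX2CX2CX3C", min_occurrences = 2L)
}

#' @export
print.motif_rule <- function(x, ...) {
  cat("<motif_rule>", x$rule_id, ": ", x$pattern,
      " (>=", x$min_occurrences, " occurrence",
      if (x$min_occurrences > 1) "s", ")", "\n", sep = "")
  if (!is.null(x$anchor_column)) {
    cat("  anchored at alignment column ", x$anchor_column,
        " (pattern position ", x$anchor_offset, ")\n", sep = "")
  }
  invisible(x)
}
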