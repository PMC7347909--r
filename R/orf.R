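# Six-frame ORF prediction under the bacterial genetic code.

#' ORF prediction settings
#'
#' @param min_len_aa Minimum ORF length in residues.
#' @param start_codons Permitted start codons (translated as Met).
#' @param both_strands Scan both strands (six frames).
#' @return An object of class `orf_config`. The genetic code is fixed to
#'   NCBI translation table 11 (bacterial).
#' @export
orf_config <- function(min_len_aa = 25L,
                       start_codons = c("ATG", "GTG", "TTG"),
                       both_strands = TRUE) {
  stopifnot(min_len_aa >= 1, all(nchar(start_codons) == 3))
  structure(list(translation_table = 11L, min_len_aa = as.integer(min_len_aa),
                 start_codons = toupper(start_codons),
                 both_strands = isTRUE(both_strands)),
            class = "orf_config")
}

#' Predict ORFs in DNA sequences (six frames, table 11)
#'
#' Calls maximal open reading frames in all six frames: from a start codon
#' (ATG/GTG/TTG by default, translated as Met) to the next stop codon, with
#' an open frame at the sequence end emitted as a truncated ORF. Coordinates
#' are 1-based inclusive on the forward strand and include the stop codon
#' when present; a `strand` flag marks the reading direction. Sequences may
#' contain `N` (codons with `N` translate to `X` and never act as start or
#' stop); any other character is an error.
#'
#' @param dna Character vector of DNA sequences (or a single string).
#' @param cfg An [orf_config()].
#' @param ids Optional sequence identifiers (defaults to names or index).
#' @return Data frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `length_aa`, `protein`.
#' @export
#' @examples
#' predict_orfs("ATGAAATAA", orf_config(min_len_aa = 1))
predict_orfs <- function(dna, cfg = orf_config(), ids = NULL) {
  stopifnot(inherits(cfg, "orf_config"), all(nchar(dna) >= 3))
  dna <- toupper(dna)
  check_dna(dna, "input DNA")
  gc11 <- genetic_code_11()
  res <- predict_orfs_cpp(dna, cfg$min_len_aa, cfg$start_codons,
                          names(gc11), paste(unname(gc11), collapse = ""),
                          cfg$both_strands)
  ids <- ids %||% names(dna) %||% as.character(seq_along(dna))
  out <- data.frame(seq_id = ids[res$seq_idx], start = res$start,
                    end = res$end, strand = res$strand,
                    length_aa = nchar(res$protein), protein = res$protein,
                    stringsAsFactors = FALSE)
  out[order(res$seq_idx, out$start, out$strand), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
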