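# Adapter removal, paired-end overlap merging and quality/length filtering.

#' Quality-control settings for read processing
#'
#' Defaults follow the conventions for 2 x 250 bp shotgun libraries: merged
#' fragments with mean Phred quality below 20 or length below 300 bp are
#' discarded; pair merging requires at least 10 bp of overlap with at most a
#' 10% mismatch fraction.
#'
#' @param min_mean_q Minimum mean Phred quality of a merged read.
#' @param min_len_bp Minimum merged read length in bp.
#' @param min_overlap_bp Minimum mate overlap for merging.
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap (also
#'   used for adapter matching).
#' @param adapter_seq Adapter sequence trimmed from 3' ends.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(min_mean_q = 20, min_len_bp = 300L,
                      min_overlap_bp = 10L, max_mismatch_frac = 0.1,
                      adapter_seq = "AGATCGGAAGAGC") {
  stopifnot(min_mean_q >= 0, min_len_bp >= 0, min_overlap_bp >= 1,
            max_mismatch_frac >= 0, max_mismatch_frac <= 1)
  check_dna(adapter_seq, "adapter")
  structure(list(min_mean_q = min_mean_q, min_len_bp = as.integer(min_len_bp),
                 min_overlap_bp = as.integer(min_overlap_bp),
                 max_mismatch_frac = max_mismatch_frac,
                 adapter_seq = adapter_seq),
            class = "qc_config")
}

#' Remove 3' adapter read-through from read pairs
#'
#' For each mate, removes the longest 3'-end suffix matching a prefix of the
#' adapter with at most `max_mismatch_frac` mismatches and at least
#' `min_match` bases; qualities are trimmed in lockstep. Reads without a
#' match are returned unchanged.
#'
#' @param pairs A `read_pairs` data frame (columns `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param adapter Adapter sequence.
#' @param max_mismatch_frac Mismatch tolerance.
#' @param min_match Minimum adapter match length in bp.
#' @return The pairs table with trimmed sequences/qualities.
#' @export
remove_adapters <- function(pairs, adapter = "AGATCGGAAGAGC",
                            max_mismatch_frac = 0.1, min_match = 3L) {
  stopifnot(nzchar(adapter))
  for (m in 1:2) {
    r <- trim_adapter_cpp(pairs[[paste0("seq", m)]], pairs[[paste0("qual", m)]],
                          adapter, max_mismatch_frac, as.integer(min_match))
    pairs[[paste0("seq", m)]] <- r$seq
    pairs[[paste0("qual", m)]] <- r$qual
  }
  pairs
}

#' Merge read pairs by overlap consensus
#'
#' Evaluates all overlap offsets between the reverse complement of mate 2
#' and mate 1 and selects the offset maximizing matches minus mismatches,
#' subject to the mismatch fraction and minimum overlap in `cfg`. The
#' consensus takes the higher-quality base at conflicts (consensus quality
#' `|Q1 - Q2|`) and the shared base at agreements (quality `max(Q1, Q2)`);
#' equal-quality conflicts emit `N`. Pairs with no admissible offset are
#' flagged unmerged and excluded downstream.
#'
#' @param pairs A `read_pairs` data frame.
#' @param cfg A [qc_config()].
#' @return A data frame of class `merged_reads` with columns `id`, `seq`,
#'   `qual`, `overlap_len`, `merged`.
#' @export
merge_pairs <- function(pairs, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  r <- merge_pairs_cpp(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2,
                       cfg$min_overlap_bp, cfg$max_mismatch_frac)
  out <- data.frame(id = pairs$id %||% sprintf("read%07d", seq_along(r$seq)),
                    seq = r$seq, qual = r$qual, overlap_len = r$overlap_len,
                    merged = r$merged, stringsAsFactors = FALSE)
  class(out) <- c("merged_reads", "data.frame")
  out
}

#' Quality/length filter for merged reads
#'
#' Retains reads with mean Phred quality at or above `cfg$min_mean_q` and
#' length at or above `cfg$min_len_bp` (both boundaries inclusive), in the
#' original order. The number of removals is recorded in the `n_removed`
#' attribute. Filtering is idempotent.
#'
#' @param reads A `merged_reads` data frame (unmerged rows are dropped too).
#' @param cfg A [qc_config()].
#' @return The filtered `merged_reads` data frame.
#' @export
quality_filter <- function(reads, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  n0 <- nrow(reads)
  keep <- (if ("merged" %in% names(reads)) reads$merged else TRUE) &
    nchar(reads$seq) >= cfg$min_len_bp &
    mean_phred(reads$qual) >= cfg$min_mean_q
  keep[is.na(keep)] <- FALSE
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n0 - nrow(out)
  class(out) <- c("merged_reads", "data.frame")
  out
}

#' Full read-processing pipeline: trim, merge, filter
#'
#' @param pairs A `read_pairs` data frame.
#' @param cfg A [qc_config()].
#' @return A filtered `merged_reads` data frame; the `qc_stats` attribute
#'   records input pairs, merged pairs and retained reads.
#' @export
process_reads <- function(pairs, cfg = qc_config()) {
  trimmed <- remove_adapters(pairs, cfg$adapter_seq, cfg$max_mismatch_frac)
  merged <- merge_pairs(trimmed, cfg)
  kept <- quality_filter(merged, cfg)
  attr(kept, "qc_stats") <- list(n_pairs = nrow(pairs),
                                 n_merged = sum(merged$merged),
                                 n_retained = nrow(kept))
  kept
}

#' Write merged reads as FASTQ
#' @param reads A `merged_reads` data frame.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq_merged <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  x <- quiet_qsdss(s, reads$qual)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
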