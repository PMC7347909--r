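# Paired-end read simulation from synthetic communities.

#' Paired-end simulation settings
#'
#' Defaults mirror a typical marine shotgun library: 2 x 250 bp paired-end
#' reads from fragments of ca. 350 bp. Fragment lengths follow a truncated
#' normal with lower bound `min_fragment_bp` (by default the read length, so
#' reads never exceed their fragment); per-base qualities come from a
#' two-state high/low model so the Q < 20 filter has real work to do;
#' substitution errors are applied independently per base.
#'
#' @param n_pairs Number of read pairs.
#' @param read_length_bp Read length (default 250).
#' @param insert_mean_bp Mean fragment (insert) length (default 350).
#' @param insert_sd_bp Fragment length standard deviation.
#' @param per_base_error Per-base substitution error probability.
#' @param adapter_seq Adapter read through when fragments are shorter than
#'   the read.
#' @param min_fragment_bp Lower truncation bound for fragment length.
#' @param q_high,q_low Phred scores of the two quality states.
#' @param p_low Probability of the low-quality state per base.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 50000L, read_length_bp = 250L,
                       insert_mean_bp = 350L, insert_sd_bp = 30L,
                       per_base_error = 0.001,
                       adapter_seq = "AGATCGGAAGAGC",
                       min_fragment_bp = read_length_bp,
                       q_high = 38L, q_low = 11L, p_low = 0.05,
                       seed = NULL) {
  stopifnot(n_pairs >= 1, read_length_bp >= 1, insert_mean_bp >= 1,
            insert_sd_bp >= 0, per_base_error >= 0, per_base_error <= 1,
            p_low >= 0, p_low <= 1)
  check_dna(adapter_seq, "adapter")
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length_bp = as.integer(read_length_bp),
                 insert_mean_bp = insert_mean_bp, insert_sd_bp = insert_sd_bp,
                 per_base_error = per_base_error, adapter_seq = adapter_seq,
                 min_fragment_bp = as.integer(min_fragment_bp),
                 q_high = as.integer(q_high), q_low = as.integer(q_low),
                 p_low = p_low, seed = seed),
            class = "sim_config")
}

#' Simulate paired-end reads from a community
#'
#' Fragments are drawn from genomes with probability proportional to
#' relative abundance times genome length, at uniform positions and random
#' orientation; mate 2 reads the reverse-complement strand. When a fragment
#' is shorter than the read length the adapter is read through. Deterministic
#' for a fixed seed.
#'
#' @param community A `community` from [make_community()] (or a named
#'   character vector of genome sequences plus `abundances`).
#' @param cfg A [sim_config()].
#' @param abundances Optional named abundance vector when `community` is a
#'   plain sequence vector.
#' @return A data frame of class `read_pairs` with columns `id`,
#'   `genome_id`, `frag_start`, `frag_len`, `flipped`, `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @export
simulate_reads <- function(community, cfg = sim_config(), abundances = NULL) {
  if (inherits(community, "community")) {
    genomes <- community$genomes
    ab <- stats::setNames(community$truth$genomes$abundance,
                          community$truth$genomes$genome_id)[names(genomes)]
  } else {
    genomes <- community
    ab <- abundances %||% rep(1 / length(genomes), length(genomes))
  }
  if (length(genomes) == 0) stop("empty genome set", call. = FALSE)
  stopifnot(inherits(cfg, "sim_config"))
  w <- ab * nchar(genomes)
  cdf <- cumsum(w / sum(w))
  res <- with_seed(cfg$seed, {
    simulate_pairs_cpp(unname(genomes), cdf, cfg$n_pairs, cfg$read_length_bp,
                       cfg$insert_mean_bp, cfg$insert_sd_bp,
                       cfg$min_fragment_bp, cfg$per_base_error,
                       cfg$adapter_seq, cfg$p_low, cfg$q_low, cfg$q_high)
  })
  out <- data.frame(id = sprintf("frag%07d", seq_len(cfg$n_pairs)),
                    genome_id = names(genomes)[res$genome_idx],
                    frag_start = res$frag_start, frag_len = res$frag_len,
                    flipped = res$flipped,
                    seq1 = res$seq1, qual1 = res$qual1,
                    seq2 = res$seq2, qual2 = res$qual2,
                    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Write simulated read pairs to FASTQ (Phred+33)
#' @param pairs A `read_pairs` data frame.
#' @param r1_path,r2_path Output FASTQ paths for the two mates.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  for (m in 1:2) {
    s <- Biostrings::DNAStringSet(pairs[[paste0("seq", m)]])
    names(s) <- pairs$id
    x <- quiet_qsdss(s, pairs[[paste0("qual", m)]])
    Biostrings::writeQualityScaledXStringSet(x, if (m == 1) r1_path else r2_path)
  }
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a `read_pairs` table
#' @param r1_path,r2_path FASTQ paths (Phred+33).
#' @return A `read_pairs` data frame with `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- quiet_mcols(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- quiet_mcols(Biostrings::readQualityScaledDNAStringSet(r2_path))
  stopifnot(length(r1) == length(r2))
  out <- data.frame(id = sub("\\s.*", "", names(r1)),
                    seq1 = as.character(r1),
                    qual1 = as.character(Biostrings::quality(r1)),
                    seq2 = as.character(r2),
                    qual2 = as.character(Biostrings::quality(r2)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  out
}
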