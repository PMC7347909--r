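# Counting validated marker hits and normalizing to recA.

#' Detect and validate marker genes in merged reads
#'
#' Predicts ORFs in the merged fragments, searches every calibrated profile
#' (consensus-seeded prescreen for large ORF sets), and validates hits with
#' the profile's motif rules: anchored rules (cap helix) via
#' [validate_hgcA()], occurrence rules (ferredoxin motifs) via
#' [validate_hgcB()]; profiles without motif rules (recA) validate on score
#' alone.
#'
#' @param merged A `merged_reads` data frame (or any data frame with `id`
#'   and `seq`).
#' @param profiles Named list of calibrated `hgc_profile` objects.
#' @param orf_cfg An [orf_config()].
#' @param evalue_cutoff E-value threshold (default 1e-5).
#' @param method Search method passed to [profile_search()].
#' @return Data frame of validated/unvalidated hits with columns
#'   `fragment_id`, `family_id`, `bitscore`, `evalue`, `validated`,
#'   `reason`; the number of predicted ORFs is in the `n_orfs` attribute.
#' @export
detect_markers <- function(merged, profiles, orf_cfg = orf_config(),
                           evalue_cutoff = 1e-5, method = "auto") {
  orfs <- predict_orfs(merged$seq, orf_cfg, ids = merged$id)
  prots <- stats::setNames(orfs$protein,
                           sprintf("%s|orf%d", orfs$seq_id, seq_len(nrow(orfs))))
  out <- list()
  for (fam in names(profiles)) {
    prof <- profiles[[fam]]
    anchored <- Filter(function(r) !is.null(r$anchor_column), prof$motif_anchors)
    occur <- Filter(function(r) is.null(r$anchor_column), prof$motif_anchors)
    hits <- profile_search(prof, prots, evalue_cutoff, method = method,
                           alignment = length(anchored) > 0)
    if (!nrow(hits)) next
    validated <- rep(TRUE, nrow(hits))
    reason <- rep(NA_character_, nrow(hits))
    if (length(anchored) || length(occur)) {
      for (i in seq_len(nrow(hits))) {
        p <- prots[[hits$query_id[i]]]
        ok <- TRUE
        if (length(anchored)) {
          v <- validate_hgcA(hits[i, ], p, prof, anchored[[1]])
          ok <- isTRUE(as.logical(v))
          if (!ok) reason[i] <- attr(v, "reason")
        }
        if (ok && length(occur)) {
          ok <- validate_hgcB(p, occur[[1]])
          if (!ok) reason[i] <- "too few motif occurrences"
        }
        validated[i] <- ok
      }
    }
    out[[fam]] <- data.frame(
      fragment_id = sub("\\|orf\\d+$", "", hits$query_id),
      query_id = hits$query_id, family_id = fam,
      bitscore = hits$bitscore, evalue = hits$evalue,
      validated = validated, reason = reason, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    data.frame(fragment_id = character(), query_id = character(),
               family_id = character(), bitscore = numeric(),
               evalue = numeric(), validated = logical(),
               reason = character(), stringsAsFactors = FALSE)
  attr(res, "n_orfs") <- nrow(orfs)
  res
}

#' Count validated hits per family, one per fragment
#'
#' Counts only `validated` hits, at most once per distinct fragment and
#' family. A fragment with validated hits in more than one family is
#' assigned to the family where it achieves the lowest E-value (the others
#' are logged in the `reassigned` attribute).
#'
#' @param hits Hit table from [detect_markers()].
#' @param families Families to report (zero counts included).
#' @return Named integer vector of counts; attribute `n_orfs` is carried
#'   through when present.
#' @export
count_validated <- function(hits, families = c("hgcA", "hgcB", "recA")) {
  v <- hits[hits$validated, , drop = FALSE]
  counts <- stats::setNames(integer(length(families)), families)
  reassigned <- character(0)
  if (nrow(v)) {
    # best (lowest) E-value per fragment x family
    key <- paste(v$fragment_id, v$family_id, sep = "\r")
    best <- tapply(v$evalue, key, min)
    frag <- sub("\r.*", "", names(best))
    fam <- sub(".*\r", "", names(best))
    # cross-family duplicates: keep the family with the lower E-value
    keep <- rep(TRUE, length(best))
    for (f in unique(frag[duplicated(frag)])) {
      idx <- which(frag == f)
      win <- idx[order(unname(best[idx]), fam[idx])][1]
      keep[setdiff(idx, win)] <- FALSE
      reassigned <- c(reassigned, f)
    }
    tab <- table(factor(fam[keep], levels = families))
    counts[] <- as.integer(tab)
  }
  attr(counts, "n_orfs") <- attr(hits, "n_orfs")
  attr(counts, "reassigned") <- reassigned
  counts
}

#' Assemble a per-sample abundance record
#'
#' @param sample_id,station,depth_m Sample annotation.
#' @param counts Named counts from [count_validated()].
#' @param n_total_genes Total predicted genes (for `recA_frac_total`).
#' @return One-row data frame of class `abundance_record`.
#' @export
abundance_record <- function(sample_id, station = NA_character_,
                             depth_m = NA_real_, counts,
                             n_total_genes = attr(counts, "n_orfs") %||% NA_integer_) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  out <- data.frame(sample_id = sample_id, station = station,
                    depth_m = depth_m,
                    n_hgcA = unname(counts["hgcA"]),
                    n_hgcB = unname(counts["hgcB"]),
                    n_recA = unname(counts["recA"]),
                    n_total_genes = n_total_genes %||% NA_integer_,
                    stringsAsFactors = FALSE)
  class(out) <- c("abundance_record", "data.frame")
  out
}

#' Normalize marker counts to recA
#'
#' Adds `rel_hgcA_pct` and `rel_hgcB_pct` (`100 * count / n_recA`) and
#' `recA_frac_total`. When `n_recA` is zero the relative abundances are
#' undefined: they are set to `NA` and flagged (`rel_defined = FALSE`),
#' never zero-filled.
#'
#' @param record An `abundance_record` (one or more rows).
#' @return The record with relative-abundance columns.
#' @export
relative_abundance <- function(record) {
  if (any(record$n_hgcA < 0 | record$n_hgcB < 0 | record$n_recA < 0)) {
    stop("negative counts", call. = FALSE)
  }
  defined <- record$n_recA > 0
  record$rel_hgcA_pct <- ifelse(defined, 100 * record$n_hgcA / record$n_recA,
                                NA_real_)
  record$rel_hgcB_pct <- ifelse(defined, 100 * record$n_hgcB / record$n_recA,
                                NA_real_)
  record$rel_defined <- defined
  record$recA_frac_total <- ifelse(is.na(record$n_total_genes) |
                                     record$n_total_genes == 0, NA_real_,
                                   record$n_recA / record$n_total_genes)
  record
}

#' Quantify marker genes in one sample
#'
#' Runs the full per-sample pipeline: adapter trimming, pair merging,
#' quality filtering, ORF prediction, profile search, motif validation,
#' per-fragment counting and recA normalization.
#'
#' @param pairs A `read_pairs` data frame (raw mates), or an already
#'   processed `merged_reads` data frame.
#' @param profiles Named list of calibrated profiles (must include
#'   `"recA"`).
#' @param sample_id,station,depth_m Sample annotation.
#' @param qc A [qc_config()].
#' @param orf_cfg An [orf_config()].
#' @param evalue_cutoff E-value threshold.
#' @return One-row `abundance_record` with relative abundances.
#' @export
quantify_sample <- function(pairs, profiles, sample_id = "sample",
                            station = NA_character_, depth_m = NA_real_,
                            qc = qc_config(), orf_cfg = orf_config(),
                            evalue_cutoff = 1e-5) {
  merged <- if (inherits(pairs, "merged_reads")) pairs else process_reads(pairs, qc)
  hits <- detect_markers(merged, profiles, orf_cfg, evalue_cutoff)
  counts <- count_validated(hits, families = names(profiles))
  rec <- abundance_record(sample_id, station, depth_m, counts)
  relative_abundance(rec)
}

#' Write an abundance table as TSV
#' @param records Row-bound `abundance_record`s.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shortest informative alignment for a calibrated profile
#'
#' The expected aligned length needed to clear the E-value cutoff: the score
#' threshold implied by the Gumbel calibration divided by the profile's mean
#' per-state information (expected emission log-odds of a family member).
#'
#' @param profile Calibrated `hgc_profile`.
#' @param evalue_cutoff E-value threshold.
#' @param n_targets Expected number of target sequences per search.
#' @return Integer number of residues.
#' @export
min_alignment_length <- function(profile, evalue_cutoff = 1e-5,
                                 n_targets = 1e5) {
  cal <- profile$calibration
  if (is.null(cal)) stop("profile is not calibrated", call. = FALSE)
  s_star <- cal$mu + cal$beta * log(n_targets / evalue_cutoff)
  lo <- .emission_logodds(profile)
  info <- mean(colSums(profile$match_emissions * lo))
  max(1L, as.integer(ceiling(s_star / info)))
}

#' Expected detected copy ratio under fragment-sampling geometry
#'
#' The quantity the read pipeline is expected to report for a synthetic
#' community: the abundance-weighted copy ratio adjusted for gene-length
#' detection weighting. For every placed gene copy it computes, by Monte
#' Carlo over fragment lengths and positions, the expected number of
#' fragment start positions that yield a countable hit: the fragment must
#' pass the length filter, contain an in-frame start codon (scanned on the
#' actual placed gene sequence) followed by at least `min_aligned_aa`
#' aligned residues, and — for motif-validated families — cover the full
#' motif window, with an analytic attrition factor for sequencing errors
#' across the window. This emulator shares no code with the search pipeline
#' and serves as its independent expectation.
#'
#' @param community A `community`.
#' @param cfg The [sim_config()] used for read simulation.
#' @param num,den Numerator/denominator families.
#' @param min_aligned_aa Named or scalar minimum aligned residues (see
#'   [min_alignment_length()]).
#' @param motif_windows Named list of `c(first_res, last_res)` protein
#'   windows that must be covered for motif-validated families (`NULL`
#'   entries for score-only families).
#' @param min_len_bp Fragment length filter (QC minimum).
#' @param start_codons Permitted start codons.
#' @param n_mc Monte Carlo draws per placement.
#' @param max_placements Per family, at most this many placements are
#'   evaluated (a seeded subsample, scaled up); placements of a family are
#'   exchangeable draws from the same member pool.
#' @param seed Integer seed.
#' @param as_pct Return a percentage.
#' @return Expected detected ratio (percent by default), with per-family
#'   expected detection weights in the `weights` attribute.
#' @export
expected_detected_ratio <- function(community, cfg, num = "hgcA", den = "recA",
                                    min_aligned_aa = 40L,
                                    motif_windows = list(hgcA = c(90L, 97L),
                                                         hgcB = c(20L, 70L),
                                                         recA = NULL),
                                    min_len_bp = 300L,
                                    start_codons = c("ATG", "GTG", "TTG"),
                                    n_mc = 2000L, max_placements = 200L,
                                    seed = NULL, as_pct = TRUE) {
  stopifnot(inherits(community, "community"))
  truth <- community$truth
  ab <- stats::setNames(truth$genomes$abundance, truth$genomes$genome_id)
  glen <- stats::setNames(truth$genomes$length_bp, truth$genomes$genome_id)
  pl <- truth$placements
  minaa <- function(fam) {
    if (length(min_aligned_aa) > 1) min_aligned_aa[[fam]] else min_aligned_aa
  }
  with_seed(seed, {
    weight_one <- function(r) {
      fam <- pl$family[r]
      gid <- pl$genome_id[r]
      gene_dna <- substr(community$genomes[[gid]], pl$start_bp[r], pl$end_bp[r])
      if (pl$strand[r] == "-") gene_dna <- revcomp(gene_dna)
      ncod <- nchar(gene_dna) %/% 3L
      codons <- substring(gene_dna, 3 * (seq_len(ncod) - 1) + 1, 3 * seq_len(ncod))
      starts <- which(codons %in% start_codons)
      n_res <- ncod - 1L # trailing stop codon is not scorable
      gl <- nchar(gene_dna)
      win <- motif_windows[[fam]]
      lo_f <- max(min_len_bp, cfg$min_fragment_bp)
      # fragment lengths from the simulator's truncated normal, additionally
      # conditioned on passing the length filter
      if (cfg$insert_sd_bp <= 0) {
        flen <- rep(cfg$insert_mean_bp, n_mc)
      } else {
        flen <- numeric(0)
        while (length(flen) < n_mc) {
          f <- round(rnorm(2 * n_mc, cfg$insert_mean_bp, cfg$insert_sd_bp))
          flen <- c(flen, f[f >= lo_f & f <= glen[[gid]]])
        }
        flen <- flen[seq_len(n_mc)]
      }
      wid <- gl + flen - 1 # admissible fragment-start window
      off <- floor(runif(n_mc) * wid) # fragment start offset within window
      s_rel <- off - flen + 2 # gene-local fragment start (1 = first gene nt)
      e_rel <- s_rel + flen - 1
      a <- pmax(s_rel, 1)
      b <- pmin(e_rel, gl)
      c1 <- ceiling((a + 2) / 3) # first fully covered codon
      c2 <- pmin(floor(b / 3), n_res) # last scorable covered codon
      # first in-frame start codon at or after c1
      st <- rep(NA_integer_, n_mc)
      if (length(starts)) {
        idx <- findInterval(c1 - 1L, starts) + 1L
        ok <- idx <= length(starts)
        st[ok] <- starts[idx[ok]]
      }
      det <- !is.na(st) & c2 >= c1 & (c2 - st + 1) >= minaa(fam)
      if (!is.null(win)) det <- det & st <= win[1] & c2 >= win[2]
      err_factor <- if (is.null(win)) 1 else
        (1 - cfg$per_base_error)^(3 * (win[2] - win[1] + 1))
      # expected detected start positions, abundance-weighted per fragment
      ab[[gid]] * mean(det * wid) * err_factor / sum(ab * glen)
    }
    fam_weight <- function(fam) {
      rows <- which(pl$family == fam)
      if (!length(rows)) return(0)
      scale <- 1
      if (length(rows) > max_placements) {
        scale <- length(rows) / max_placements
        rows <- sample(rows, max_placements)
      }
      scale * sum(vapply(rows, weight_one, numeric(1)))
    }
    w_num <- fam_weight(num)
    w_den <- fam_weight(den)
    r <- w_num / w_den
    structure(if (as_pct) 100 * r else r,
              weights = c(stats::setNames(w_num, num), stats::setNames(w_den, den)))
  })
}

#' Recovery report: bias and RMSE of estimated copy ratios
#'
#' Compares replicate pipeline estimates of the hgcA:recA (or any) relative
#' abundance against the expected detected ratio for the community, and
#' reports relative bias, RMSE, and the binomial (delta-method) standard
#' error of the mean estimate.
#'
#' @param community The `community` the replicates were simulated from (or
#'   `NULL` when `expected` is supplied directly).
#' @param records Row-bound `abundance_record`s with relative abundances
#'   (>= 2 replicates).
#' @param expected Expected detected ratio in percent; computed with
#'   [expected_detected_ratio()] when omitted.
#' @param num,den Families compared.
#' @param ... Passed to [expected_detected_ratio()] (e.g. `cfg`,
#'   `min_aligned_aa`, `seed`).
#' @return List of class `recovery_report`: `expected_pct`, `mean_est_pct`,
#'   `bias_pct` (relative, percent), `rmse_pct`, `se_mean_pct`, `z`, `n`.
#' @export
recovery_report <- function(community, records, expected = NULL,
                            num = "hgcA", den = "recA", ...) {
  if (nrow(records) < 2) stop("need >= 2 replicate records", call. = FALSE)
  est_col <- paste0("rel_", num, "_pct")
  if (!est_col %in% names(records)) {
    stop("records carry no '", est_col, "' column; run relative_abundance()",
         call. = FALSE)
  }
  est <- records[[est_col]]
  if (anyNA(est)) stop("undefined relative abundances in records", call. = FALSE)
  if (is.null(expected)) {
    expected <- as.numeric(expected_detected_ratio(community, num = num,
                                                   den = den, ...))
  }
  n_num <- records[[paste0("n_", num)]]
  n_den <- records[[paste0("n_", den)]]
  se_each <- ifelse(n_num > 0, est * sqrt(1 / n_num + 1 / n_den), NA_real_)
  se_mean <- if (anyNA(se_each)) NA_real_ else
    sqrt(sum(se_each^2)) / length(se_each)
  bias <- 100 * (mean(est) - expected) / expected
  rmse <- sqrt(mean((est - expected)^2))
  structure(list(expected_pct = expected, mean_est_pct = mean(est),
                 bias_pct = bias, rmse_pct = rmse, se_mean_pct = se_mean,
                 z = if (is.na(se_mean)) NA_real_ else
                   (mean(est) - expected) / se_mean,
                 n = length(est)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> n = %d replicates\n", x$n))
  cat(sprintf("  expected %.4f%%  estimated %.4f%%  relative bias %+.2f%%\n",
              x$expected_pct, x$mean_est_pct, x$bias_pct))
  cat(sprintf("  RMSE %.4f%%  SE(mean) %.4f%%  z = %.2f\n",
              x$rmse_pct, x$se_mean_pct, x$z))
  invisible(x)
}
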