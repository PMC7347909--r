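# Position-specific profile models built from reference alignments, with
# local Viterbi scoring and Gumbel-calibrated E-values.

#' Build a profile model from an aligned protein family
#'
#' Alignment columns with a gap fraction at or below `max_col_gap_frac`
#' become match states. Match emissions are background-pseudocounted
#' observed frequencies, `(count + w * bg) / (n_nongap + w)`; the background
#' is the residue frequency pooled over the whole alignment (add-one
#' smoothed over the 20-letter alphabet so log-odds stay finite). Global
#' match/insert/delete transition probabilities are estimated from the gap
#' structure of the alignment with add-one pseudocounts.
#'
#' @param alignment A `ref_family`, or a named character vector of aligned
#'   sequences of equal length (`-` for gaps).
#' @param family_id Family label (defaults to the family's id or
#'   `"profile"`).
#' @param pseudocount_weight Weight `w` of the background pseudocount.
#' @param max_col_gap_frac Maximum gap fraction for a match column.
#' @param motif_anchors List of [motif_rule()] objects with anchor columns;
#'   every anchor column must be a match column.
#' @return An object of class `hgc_profile` with match emissions (20 x M),
#'   background frequencies, transition probabilities, `column_map`
#'   (match state -> alignment column), consensus sequence and (after
#'   [calibrate()]) Gumbel E-value parameters.
#' @export
build_profile <- function(alignment, family_id = NULL, pseudocount_weight = 1,
                          max_col_gap_frac = 0.5, motif_anchors = list()) {
  if (inherits(alignment, "ref_family")) {
    if (is.null(family_id)) family_id <- alignment$family_id
    if (!length(motif_anchors)) motif_anchors <- alignment$motif_rules
    alignment <- alignment$members
  }
  family_id <- family_id %||% "profile"
  stopifnot(length(alignment) >= 2)
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop("aligned sequences must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  letters20 <- aa_letters()
  is_gap <- mat == "-" | mat == "."
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac <= max_col_gap_frac)
  if (!length(match_cols)) stop("alignment has no match columns", call. = FALSE)

  pooled <- table(factor(mat[!is_gap], levels = letters20))
  background <- (as.numeric(pooled) + 1) / (sum(pooled) + length(letters20))
  names(background) <- letters20

  M <- length(match_cols)
  emis <- matrix(0, nrow = length(letters20), ncol = M,
                 dimnames = list(letters20, NULL))
  for (k in seq_len(M)) {
    col <- mat[, match_cols[k]]
    col <- col[col != "-" & col != "."]
    counts <- table(factor(col, levels = letters20))
    emis[, k] <- (as.numeric(counts) + pseudocount_weight * background) /
      (length(col) + pseudocount_weight)
  }

  trans <- .estimate_transitions(mat, is_gap, match_cols)

  for (r in motif_anchors) {
    if (!is.null(r$anchor_column) && !(r$anchor_column %in% match_cols)) {
      stop("motif anchor column ", r$anchor_column, " is not a match column",
           call. = FALSE)
    }
  }

  reflen <- nchar(gsub("[-.]", "", alignment))
  structure(list(family_id = family_id, n_match_states = M,
                 match_emissions = emis, background_freqs = background,
                 transition_params = trans,
                 column_map = as.integer(match_cols),
                 motif_anchors = motif_anchors,
                 consensus = paste(letters20[apply(emis, 2, which.max)],
                                   collapse = ""),
                 median_ref_len = as.integer(stats::median(reflen)),
                 n_members = length(alignment),
                 calibration = NULL),
            class = "hgc_profile")
}

# transition counts from the alignment path of every sequence
.estimate_transitions <- function(mat, is_gap, match_cols) {
  n <- c(mm = 1, mi = 1, md = 1, im = 1, ii = 1, dm = 1, dd = 1)
  col_kind <- ifelse(seq_len(ncol(mat)) %in% match_cols, "m", "i")
  for (s in seq_len(nrow(mat))) {
    prev <- "m" # begin treated as a match state
    for (j in seq_len(ncol(mat))) {
      state <- if (col_kind[j] == "m") {
        if (is_gap[s, j]) "d" else "m"
      } else {
        if (is_gap[s, j]) NA_character_ else "i"
      }
      if (is.na(state)) next
      key <- paste0(prev, state)
      if (key %in% names(n)) n[key] <- n[key] + 1
      prev <- state
    }
  }
  list(mm = unname(n["mm"] / (n["mm"] + n["mi"] + n["md"])),
       mi = unname(n["mi"] / (n["mm"] + n["mi"] + n["md"])),
       md = unname(n["md"] / (n["mm"] + n["mi"] + n["md"])),
       im = unname(n["im"] / (n["im"] + n["ii"])),
       ii = unname(n["ii"] / (n["im"] + n["ii"])),
       dm = unname(n["dm"] / (n["dm"] + n["dd"])),
       dd = unname(n["dd"] / (n["dm"] + n["dd"])))
}

.emission_logodds <- function(profile) {
  log2(profile$match_emissions / profile$background_freqs)
}

.transition_logodds <- function(profile) {
  t <- profile$transition_params
  log2(c(t$mm, t$mi, t$md, t$im, t$ii, t$dm, t$dd))
}

#' Is a profile calibrated for E-values?
#' @param profile An `hgc_profile`.
#' @return Logical.
#' @export
is_calibrated <- function(profile) !is.null(profile$calibration)

#' Calibrate a profile's E-value statistics
#'
#' Scores `n_null` random sequences drawn from the profile's background
#' residue distribution (length = median reference length) and fits a
#' Gumbel (type-I extreme value) law to the null scores by maximum
#' likelihood. E-values are then
#' `N_targets * exp(-(S - mu) / beta)`. Deterministic for a fixed seed.
#'
#' @param profile An `hgc_profile`.
#' @param n_null Number of null sequences.
#' @param seed Integer seed.
#' @param null_len Null sequence length (defaults to the median reference
#'   length).
#' @return The profile with a `calibration` record (`mu`, `beta`, `n_null`,
#'   `null_len`).
#' @export
calibrate <- function(profile, n_null = 1000L, seed = NULL, null_len = NULL) {
  stopifnot(inherits(profile, "hgc_profile"))
  null_len <- null_len %||% profile$median_ref_len
  scores <- with_seed(seed, {
    bg <- profile$background_freqs
    seqs <- vapply(seq_len(n_null), function(i) {
      paste(sample(names(bg), null_len, replace = TRUE, prob = bg),
            collapse = "")
    }, character(1))
    profile_viterbi_scores(.emission_logodds(profile),
                           .transition_logodds(profile), seqs, AA_ALPHABET)
  })
  if (stats::sd(scores) < 1e-8) {
    stop("null score variance is degenerate; cannot calibrate", call. = FALSE)
  }
  fit <- fit_gumbel(scores)
  profile$calibration <- list(mu = fit[["mu"]], beta = fit[["beta"]],
                              n_null = as.integer(n_null),
                              null_len = as.integer(null_len))
  profile
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location `mu` and scale `beta` of a Gumbel (max) distribution to a
#' numeric sample by maximum likelihood (fixed-point condition on `beta`
#' solved with [uniroot()]).
#'
#' @param x Numeric sample.
#' @return Named vector `c(mu, beta)`.
#' @export
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10, stats::sd(x) > 0)
  xbar <- mean(x)
  m <- min(x)
  g <- function(beta) {
    w <- exp(-(x - m) / beta) # center at the minimum: weights stay in (0, 1]
    beta - xbar + sum(x * w) / sum(w)
  }
  lo <- stats::sd(x) * 0.02
  hi <- stats::sd(x) * 10
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  mu <- m - beta * log(mean(exp(-(x - m) / beta)))
  c(mu = mu, beta = beta)
}

#' E-value for a bitscore under a calibrated profile
#' @param profile Calibrated `hgc_profile`.
#' @param score Bitscore(s).
#' @param n_targets Number of target sequences searched.
#' @return E-value(s).
#' @export
evalue_from_score <- function(profile, score, n_targets = 1) {
  if (!is_calibrated(profile)) {
    stop("profile '", profile$family_id, "' is not calibrated; run calibrate() ",
         "before requesting E-values", call. = FALSE)
  }
  cal <- profile$calibration
  n_targets * exp(-(score - cal$mu) / cal$beta)
}

#' Score a protein against a profile
#'
#' Local Viterbi log-odds score in bits (maximum over local alignments of
#' emission log-odds plus transition terms), with the E-value from the
#' profile's Gumbel calibration.
#'
#' @param profile An `hgc_profile`.
#' @param protein Protein sequence (single string).
#' @param n_targets Number of targets for the E-value (default 1).
#' @return Named numeric `c(bitscore, evalue)` (`evalue` is `NA` when the
#'   profile is uncalibrated and `n_targets` is `NA`).
#' @export
score_sequence <- function(profile, protein, n_targets = 1) {
  stopifnot(inherits(profile, "hgc_profile"), nchar(protein) >= 1)
  s <- profile_viterbi_scores(.emission_logodds(profile),
                              .transition_logodds(profile),
                              toupper(protein), AA_ALPHABET)
  ev <- if (is.na(n_targets)) NA_real_ else evalue_from_score(profile, s, n_targets)
  c(bitscore = s, evalue = ev)
}

#' Search proteins with a calibrated profile
#'
#' Scores every protein (optionally after a consensus k-mer prescreen for
#' large inputs), converts scores to E-values with `N_targets` equal to the
#' number of proteins searched, and returns hits at or below the cutoff,
#' sorted by E-value with ties broken by query id. Each hit carries the
#' aligned query span and the per-position match-state path used by the
#' motif validators.
#'
#' @param profile Calibrated `hgc_profile`.
#' @param proteins Named character vector of protein sequences.
#' @param evalue_cutoff E-value threshold (default 1e-5).
#' @param method `"exact"` scores everything; `"seeded"` requires a shared
#'   consensus 5-mer before scoring (suitable for large read sets);
#'   `"auto"` picks `"seeded"` above 2000 proteins.
#' @param alignment Recover the aligned span and match-state path of each
#'   hit (needed by the anchored motif validators; skip for score-only
#'   counting of large hit sets).
#' @return Data frame of class `hgc_hits`: `query_id`, `family_id`,
#'   `bitscore`, `evalue`, `qstart`, `qend`, plus a `state_path` list
#'   column (`NA`/`NULL` when `alignment = FALSE`).
#' @export
profile_search <- function(profile, proteins, evalue_cutoff = 1e-5,
                           method = c("auto", "exact", "seeded"),
                           alignment = TRUE) {
  method <- match.arg(method)
  if (!is_calibrated(profile)) {
    stop("profile '", profile$family_id, "' is not calibrated; run calibrate()",
         call. = FALSE)
  }
  n_targets <- length(proteins)
  empty <- data.frame(query_id = character(), family_id = character(),
                      bitscore = numeric(), evalue = numeric(),
                      qstart = integer(), qend = integer(),
                      stringsAsFactors = FALSE)
  empty$state_path <- list()
  class(empty) <- c("hgc_hits", "data.frame")
  if (n_targets == 0) return(empty)
  if (is.null(names(proteins))) names(proteins) <- sprintf("query%06d",
                                                           seq_along(proteins))
  if (method == "auto") method <- if (n_targets > 2000) "seeded" else "exact"
  elo <- .emission_logodds(profile)
  tlo <- .transition_logodds(profile)
  cand <- seq_along(proteins)
  if (method == "seeded") {
    hitk <- kmer_prescreen_cpp(unname(proteins), profile$consensus, 5L)
    cand <- which(hitk)
    if (!length(cand)) return(empty)
  }
  scores <- profile_viterbi_scores(elo, tlo, unname(proteins[cand]), AA_ALPHABET)
  ev <- evalue_from_score(profile, scores, n_targets)
  keep <- which(ev <= evalue_cutoff)
  if (!length(keep)) return(empty)
  idx <- cand[keep]
  if (alignment) {
    align <- lapply(idx, function(i) {
      profile_viterbi_align(elo, tlo, toupper(proteins[[i]]), AA_ALPHABET)
    })
    qstart <- vapply(align, function(a) a$qstart, integer(1))
    qend <- vapply(align, function(a) a$qend, integer(1))
    paths <- lapply(align, function(a) a$state_path)
  } else {
    qstart <- rep(NA_integer_, length(idx))
    qend <- rep(NA_integer_, length(idx))
    paths <- vector("list", length(idx))
  }
  out <- data.frame(query_id = names(proteins)[idx],
                    family_id = profile$family_id,
                    bitscore = scores[keep], evalue = ev[keep],
                    qstart = qstart, qend = qend,
                    stringsAsFactors = FALSE)
  out$state_path <- paths
  ord <- order(out$evalue, out$query_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hgc_hits", "data.frame")
  out
}

#' @export
print.hgc_profile <- function(x, ...) {
  cat("<hgc_profile> ", x$family_id, ": ", x$n_match_states,
      " match states from ", x$n_members, " sequences\n", sep = "")
  if (is_calibrated(x)) {
    cat(sprintf("  calibrated: Gumbel mu = %.2f, beta = %.2f (n = %d)\n",
                x$calibration$mu, x$calibration$beta, x$calibration$n_null))
  } else {
    cat("  not calibrated (run calibrate() before E-value search)\n")
  }
  invisible(x)
}

#' Serialize a profile to JSON
#' @param profile An `hgc_profile`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
profile_to_json <- function(profile, path) {
  x <- profile
  x$match_emissions <- as.data.frame(x$match_emissions)
  x$motif_anchors <- lapply(x$motif_anchors, function(r) {
    list(rule_id = r$rule_id, pattern = r$pattern,
         min_occurrences = r$min_occurrences,
         anchor_column = r$anchor_column, anchor_offset = r$anchor_offset)
  })
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a profile from JSON
#' @param path JSON path written by [profile_to_json()].
#' @return An `hgc_profile`.
#' @export
profile_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  emis <- as.matrix(x$match_emissions)
  rownames(emis) <- aa_letters()
  x$match_emissions <- emis
  x$background_freqs <- stats::setNames(as.numeric(x$background_freqs),
                                        aa_letters())
  x$motif_anchors <- lapply(seq_len(NROW(x$motif_anchors)), function(i) {
    r <- x$motif_anchors[i, ]
    motif_rule(r$rule_id, r$pattern, r$min_occurrences,
               if (is.na(r$anchor_column)) NULL else r$anchor_column,
               r$anchor_offset)
  })
  if (!is.null(x$calibration) && length(x$calibration)) {
    x$calibration <- as.list(x$calibration)
  } else {
    x$calibration <- NULL
  }
  structure(x, class = "hgc_profile")
}
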