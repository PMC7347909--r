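# Mercury unit conversions, detection-limit censoring, and rank
# correlation of marker-gene abundance with THg/MeHg depth profiles.

HG_ATOMIC_MASS <- 200.59 # g/mol; both analytes reported on an Hg-mass basis

#' Convert a mercury mass concentration to molar
#'
#' `pg/L -> pM` (or `ng/L -> nM`) on the mercury atomic-mass basis
#' (200.59 g/mol), the convention under which paired reports like
#' 1900 pg/L = 9.5 pM and 1.4 pg/L = 0.007 pM round-trip. Rounding is left
#' to the presentation layer.
#'
#' @param value Nonnegative mass concentration(s).
#' @param from Input unit (`"pg/L"` or `"ng/L"`).
#' @return Molar concentration in pM (for pg/L) or nM (for ng/L).
#' @export
#' @examples
#' round(mass_to_molar(1900), 1) # 9.5 pM
mass_to_molar <- function(value, from = c("pg/L", "ng/L")) {
  from <- match.arg(from)
  if (any(value < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  value / HG_ATOMIC_MASS
}

#' Convert a molar mercury concentration back to mass
#' @param value Molar concentration(s) (pM or nM).
#' @param to Output unit (`"pg/L"` or `"ng/L"`).
#' @return Mass concentration.
#' @export
molar_to_mass <- function(value, to = c("pg/L", "ng/L")) {
  to <- match.arg(to)
  if (any(value < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  value * HG_ATOMIC_MASS
}

#' Censor below-detection values to zero
#'
#' Applies the statistical rule for "not detected" chemistry values:
#' censored entries become 0, detected values pass through unchanged.
#' Idempotent.
#'
#' @param value Numeric vector of measured values.
#' @param detected Logical vector; `FALSE` marks "not detected" entries.
#' @return Numeric vector with censored entries set to 0.
#' @export
censor_nd <- function(value, detected = !is.na(value)) {
  stopifnot(length(value) == length(detected))
  out <- ifelse(detected, value, 0)
  out[is.na(out)] <- 0
  out
}

# all permutations of 1..n (n <= 10), deterministic order; cached per n
.perm_cache <- new.env(parent = emptyenv())

.permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  out <- if (n == 1) {
    matrix(1L, 1, 1)
  } else {
    sub <- .permutations(n - 1L)
    blocks <- lapply(seq_len(n), function(k) {
      rest <- setdiff(seq_len(n), k)
      cbind(rep(k, nrow(sub)),
            matrix(rest[sub], nrow(sub), n - 1L))
    })
    do.call(rbind, blocks)
  }
  storage.mode(out) <- "integer"
  .perm_cache[[key]] <- out
  out
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Mid-ranks are used for ties; rho is the Pearson correlation of the rank
#' vectors. The two-sided p-value is computed by exhaustive enumeration of
#' all `n!` orderings for `n < 10` (exact even under ties) and by the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` for `n >= 10`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return List with `rho`, `p_value`, `n`, `method`. A constant input
#'   yields `rho = NA` with a warning.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- .permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    # correlation for each permutation of the x ranks against fixed y ranks
    rhos <- as.numeric((matrix(rxc[perms], nrow(perms), n) %*% ryc) / denom)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p_value = p, n = n, method = "exact permutation")
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
    list(rho = rho, p_value = min(1, p), n = n, method = "t approximation")
  }
}

#' Correlate marker-gene abundance with mercury depth profiles
#'
#' Joins an abundance table and an Hg chemistry table on (station, depth),
#' applies the censor-to-zero rule to below-detection chemistry, and
#' computes Spearman correlations for each gene (hgcA, hgcB) against THg,
#' MeHg and the MeHg/THg fraction, over all stations and over a deep-station
#' subset. Samples with undefined relative abundance (recA = 0) are dropped
#' with a logged count, never zero-filled. Cells with fewer than 3 joined
#' rows are flagged insufficient.
#'
#' @param abundance Data frame with `station`, `depth_m`, `rel_hgcA_pct`,
#'   `rel_hgcB_pct` (e.g. row-bound [relative_abundance()] records).
#' @param hg Data frame in the [make_hg_table()] layout.
#' @param deep_stations Stations forming the deep subset.
#' @return Data frame of class `hgc_cor_table` with columns `gene`,
#'   `variable`, `subset`, `rho`, `p_value`, `n`, `note`.
#' @export
correlate_profiles <- function(abundance, hg, deep_stations = c("St0", "St1")) {
  joined <- merge(abundance, hg, by = c("station", "depth_m"))
  if (!nrow(joined)) stop("no samples joined on (station, depth)", call. = FALSE)
  joined$thg <- censor_nd(joined$thg_pM, !(joined$thg_nd %||% FALSE))
  joined$mehg <- censor_nd(joined$mehg_pM, !(joined$mehg_nd %||% FALSE))
  joined$mehg_frac <- ifelse(joined$thg > 0, joined$mehg / joined$thg, NA_real_)
  genes <- c(hgcA = "rel_hgcA_pct", hgcB = "rel_hgcB_pct")
  vars <- c(THg = "thg", MeHg = "mehg", `MeHg/THg` = "mehg_frac")
  subsets <- list(all = unique(joined$station), deep = deep_stations)
  n_dropped <- 0L
  rows <- list()
  for (g in names(genes)) {
    for (v in names(vars)) {
      for (ss in names(subsets)) {
        d <- joined[joined$station %in% subsets[[ss]], , drop = FALSE]
        gv <- d[[genes[[g]]]]
        hv <- d[[vars[[v]]]]
        keep <- !is.na(gv) & !is.na(hv)
        n_dropped <- n_dropped + sum(!keep & !is.na(hv))
        gv <- gv[keep]; hv <- hv[keep]
        if (length(gv) < 3) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, variable = v, subset = ss, rho = NA_real_,
            p_value = NA_real_, n = length(gv), note = "insufficient",
            stringsAsFactors = FALSE)
        } else {
          s <- suppressWarnings(spearman_rank(gv, hv))
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, variable = v, subset = ss, rho = s$rho,
            p_value = s$p_value, n = s$n,
            note = if (is.na(s$rho)) "constant" else "",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_dropped_undefined") <- n_dropped
  class(out) <- c("hgc_cor_table", "data.frame")
  out
}

#' @export
print.hgc_cor_table <- function(x, digits = 2, ...) {
  cat("Spearman rank correlations (rho) of marker abundance vs mercury:\n")
  for (ss in unique(x$subset)) {
    cat("  subset:", ss, "\n")
    sub <- x[x$subset == ss, , drop = FALSE]
    wide <- stats::reshape(sub[, c("gene", "variable", "rho")],
                           idvar = "variable", timevar = "gene",
                           direction = "wide")
    names(wide) <- sub("^rho\\.", "", names(wide))
    print(format(wide, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Write a correlation table as TSV
#' @param tab An `hgc_cor_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cor_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
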