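# Internal helpers shared across modules.

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

# Swiss-Prot-like amino-acid background, normalized at load time; used as the
# default residue distribution for synthetic families and null sequences.
.aa_bg_raw <- c(
  A = 0.0777, C = 0.0157, D = 0.0530, E = 0.0656, F = 0.0405,
  G = 0.0691, H = 0.0227, I = 0.0591, K = 0.0595, L = 0.0960,
  M = 0.0238, N = 0.0427, P = 0.0469, Q = 0.0393, R = 0.0526,
  S = 0.0694, T = 0.0550, V = 0.0667, W = 0.0118, Y = 0.0311
)

aa_background <- function() {
  bg <- .aa_bg_raw[strsplit(AA_ALPHABET, "")[[1]]]
  bg / sum(bg)
}

aa_letters <- function() strsplit(AA_ALPHABET, "")[[1]]

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global random stream.
#' A `NULL` seed evaluates `code` unseeded.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  revcomp_cpp(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(what, " contains characters outside A/C/G/T/N (first offender: ",
         which(bad)[1], ")", call. = FALSE)
  }
  invisible(x)
}

phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

mean_phred <- function(qual) {
  mean_phred_cpp(qual)
}

# some Biostrings versions warn about dropped (empty) metadata columns when
# constructing or reading quality-scaled sets; nothing is lost here
quiet_mcols <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

quiet_qsdss <- function(seqs, quals) {
  quiet_mcols(
    Biostrings::QualityScaledDNAStringSet(seqs, Biostrings::PhredQuality(quals)))
}

# genetic code table 11 as a named character vector (DNA codons -> residues)
genetic_code_11 <- function() {
  gc <- Biostrings::getGeneticCode("11")
  # strip attributes other than names
  stats::setNames(as.character(gc), names(gc))
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
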