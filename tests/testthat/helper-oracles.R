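# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately naive (loops, brute force) and share no code with
# the implementation paths they check.

# brute-force non-overlapping scan for the ferredoxin motif C-x2-C-x2-C-x3-C
oracle_count_cx2cx2cx3c <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  count <- 0L
  i <- 1L
  while (i + 10L <= n) {
    if (chars[i] == "C" && chars[i + 3L] == "C" && chars[i + 6L] == "C" &&
        chars[i + 10L] == "C") {
      count <- count + 1L
      i <- i + 11L
    } else {
      i <- i + 1L
    }
  }
  count
}

# brute-force six-frame ORF enumeration (start codon -> stop or sequence end)
oracle_orfs <- function(dna, min_len_aa, starts = c("ATG", "GTG", "TTG")) {
  gc11 <- Biostrings::getGeneticCode("11")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else rc
    L <- nchar(s)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3
      if (ncod < 1) next
      codons <- substring(s, frame + 3 * (seq_len(ncod) - 1) + 1,
                          frame + 3 * seq_len(ncod))
      is_stop <- !is.na(match(codons, c("TAA", "TAG", "TGA")))
      cur <- NA_integer_
      for (ci in seq_len(ncod + 1)) {
        at_end <- ci > ncod
        if (at_end || is_stop[ci]) {
          if (!is.na(cur) && (ci - cur) >= min_len_aa) {
            aa <- vapply(codons[cur:(ci - 1)], function(cd) {
              if (grepl("[^ACGT]", cd)) "X" else unname(gc11[cd])
            }, character(1))
            aa[1] <- "M"
            lstart <- frame + 3 * (cur - 1) + 1
            lend <- frame + 3 * (ci - 1) + (if (at_end) 0 else 3)
            if (strand == "+") {
              fs <- lstart; fe <- lend
            } else {
              fs <- L - lend + 1; fe <- L - lstart + 1
            }
            out[[length(out) + 1L]] <- data.frame(
              start = fs, end = fe, strand = strand,
              protein = paste(aa, collapse = ""), stringsAsFactors = FALSE)
          }
          cur <- NA_integer_
        } else if (is.na(cur) && codons[ci] %in% starts) {
          cur <- ci
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# recursive generation of all permutations of 1..n (independent of the
# package's enumerator)
oracle_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- oracle_permutations(n - 1L)
  out <- list()
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (p in sub) out[[length(out) + 1L]] <- c(k, rest[p])
  }
  out
}

# exhaustive Spearman permutation test with mid-ranks
oracle_spearman_exact <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- suppressWarnings(cor(rx, ry))
  rhos <- vapply(oracle_permutations(length(y)),
                 function(p) suppressWarnings(cor(rx, ry[p])), numeric(1))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# shared expensive fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

test_families <- function() {
  if (is.null(.fixtures$fams)) .fixtures$fams <- default_families()
  .fixtures$fams
}

test_profiles <- function() {
  if (is.null(.fixtures$profs)) {
    fams <- test_families()
    profs <- lapply(fams, build_profile)
    profs <- lapply(seq_along(profs),
                    function(i) calibrate(profs[[i]], n_null = 500L,
                                          seed = 100L + i))
    names(profs) <- names(fams)
    .fixtures$profs <- profs
  }
  .fixtures$profs
}

# a decoy family: same lengths and composition model, no motifs, unrelated
test_decoys <- function() {
  if (is.null(.fixtures$decoys)) {
    .fixtures$decoys <- list(
      decoyA = make_reference_family(family_spec("decoyA", 50, 349, 0.05,
                                                 seed = 901)),
      decoyB = make_reference_family(family_spec("decoyB", 50, 99, 0.05,
                                                 seed = 902)))
  }
  .fixtures$decoys
}

random_protein <- function(n_aa) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n_aa,
               replace = TRUE), collapse = "")
}
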