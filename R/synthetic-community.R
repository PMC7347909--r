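# Synthetic communities: genomes with marker genes placed at known
# coordinates, giving ground truth for recovery tests.

#' Describe a synthetic community with known gene placements
#'
#' @param genomes Data frame with columns `genome_id`, `length_bp` and
#'   `abundance` (relative abundances; must sum to 1 within 1e-9).
#' @param placements Data frame with columns `genome_id`, `family` and
#'   `copies` (expanded to individual gene copies), plus optional `start_bp`
#'   and `strand` ("+"/"-"); when absent, coordinates are laid out at
#'   community-construction time without overlaps.
#' @return An object of class `community_truth`.
#' @export
community_truth <- function(genomes, placements) {
  stopifnot(is.data.frame(genomes), is.data.frame(placements),
            all(c("genome_id", "length_bp", "abundance") %in% names(genomes)),
            all(c("genome_id", "family") %in% names(placements)))
  if (abs(sum(genomes$abundance) - 1) > 1e-9) {
    stop("relative abundances must sum to 1 (got ", sum(genomes$abundance), ")",
         call. = FALSE)
  }
  if (!all(placements$genome_id %in% genomes$genome_id)) {
    stop("placements refer to unknown genome ids", call. = FALSE)
  }
  if (!"copies" %in% names(placements)) placements$copies <- 1L
  if (!"start_bp" %in% names(placements)) placements$start_bp <- NA_integer_
  if (!"strand" %in% names(placements)) placements$strand <- NA_character_
  structure(list(genomes = genomes, placements = placements),
            class = "community_truth")
}

#' Expected copy ratio between two gene families
#'
#' Abundance-weighted copy ratio, the quantity the detection pipeline
#' estimates: `sum(abundance * copies(num)) / sum(abundance * copies(den))`.
#'
#' @param truth A [community_truth()] or a built community.
#' @param num,den Family labels for numerator and denominator (e.g.
#'   `"hgcA"`, `"recA"`).
#' @param as_pct Return a percentage (default) rather than a fraction.
#' @return Numeric scalar.
#' @export
expected_copy_ratio <- function(truth, num = "hgcA", den = "recA", as_pct = TRUE) {
  if (inherits(truth, "community")) truth <- truth$truth
  stopifnot(inherits(truth, "community_truth"))
  ab <- stats::setNames(truth$genomes$abundance, truth$genomes$genome_id)
  pl <- truth$placements
  wsum <- function(fam) {
    rows <- pl$family == fam
    if (!any(rows)) return(0)
    sum(ab[pl$genome_id[rows]] * pl$copies[rows])
  }
  r <- wsum(num) / wsum(den)
  if (as_pct) 100 * r else r
}

# lay out n gene lengths in [1, glen] without overlap; random gaps, seeded RNG
.layout_intervals <- function(glen, lens) {
  total <- sum(lens)
  if (total > glen) {
    stop("genes (", total, " bp) do not fit in genome of ", glen, " bp",
         call. = FALSE)
  }
  free <- glen - total
  # random composition of the free space into length(lens)+1 gaps
  cuts <- sort(sample.int(free + length(lens), length(lens)))
  gaps <- diff(c(0L, cuts)) - 1L
  starts <- integer(length(lens))
  pos <- 1L
  ord <- sample.int(length(lens))
  for (k in seq_along(ord)) {
    pos <- pos + gaps[k]
    starts[ord[k]] <- pos
    pos <- pos + lens[ord[k]]
  }
  starts
}

#' Build genome sequences from a community description
#'
#' Generates random genome backbones, back-translates a family member for
#' every placed gene copy (uniform synonymous codon choice, plus a TAA stop),
#' and inserts the genes at their coordinates (reverse-complemented on the
#' minus strand). Placements without explicit coordinates are laid out
#' randomly without overlaps. Translating any placement under genetic code
#' table 11 reproduces the source protein.
#'
#' @param truth A [community_truth()].
#' @param families Named list of `ref_family` objects covering every placed
#'   family.
#' @param seed Integer seed.
#' @return An object of class `community`: list with `genomes` (named
#'   character vector), `truth` (with resolved placement coordinates,
#'   member ids and proteins) and `families`.
#' @export
make_community <- function(truth, families, seed = NULL) {
  stopifnot(inherits(truth, "community_truth"))
  missing_fams <- setdiff(unique(truth$placements$family), names(families))
  if (length(missing_fams)) {
    stop("no reference family supplied for: ",
         paste(missing_fams, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    g <- truth$genomes
    pl <- truth$placements
    # expand copies into individual placements
    idx <- rep(seq_len(nrow(pl)), pl$copies)
    ex <- pl[idx, c("genome_id", "family", "start_bp", "strand"), drop = FALSE]
    rownames(ex) <- NULL
    ex$copies <- 1L
    ex$member_id <- NA_character_
    ex$protein <- NA_character_
    ex$gene_bp <- NA_integer_
    ex$end_bp <- NA_integer_
    genomes <- stats::setNames(character(nrow(g)), g$genome_id)
    for (gi in seq_len(nrow(g))) {
      gid <- g$genome_id[gi]
      glen <- g$length_bp[gi]
      rows <- which(ex$genome_id == gid)
      backbone <- strsplit(random_dna(glen), "")[[1]]
      if (length(rows)) {
        # pick members (cycled, shuffled) and back-translate
        for (r in rows) {
          fam <- families[[ex$family[r]]]
          mem <- sample(seq_along(fam$members), 1L)
          prot <- gsub("-", "", fam$members[[mem]])
          dna <- back_translate(prot)
          ex$member_id[r] <- names(fam$members)[mem]
          ex$protein[r] <- prot
          ex$gene_bp[r] <- nchar(dna)
          attr(ex, paste0("dna_", r)) <- dna
        }
        lens <- ex$gene_bp[rows]
        if (all(is.na(ex$start_bp[rows]))) {
          ex$start_bp[rows] <- .layout_intervals(glen, lens)
        }
        if (any(is.na(ex$strand[rows]))) {
          nas <- rows[is.na(ex$strand[rows])]
          ex$strand[nas] <- sample(c("+", "-"), length(nas), replace = TRUE)
        }
        ex$end_bp[rows] <- ex$start_bp[rows] + ex$gene_bp[rows] - 1L
        if (any(ex$end_bp[rows] > glen | ex$start_bp[rows] < 1)) {
          stop("placement extends beyond genome '", gid, "' (length ", glen,
               " bp)", call. = FALSE)
        }
        ord <- rows[order(ex$start_bp[rows])]
        if (length(ord) > 1 &&
            any(ex$start_bp[ord][-1] <= ex$end_bp[ord][-length(ord)])) {
          stop("gene placements overlap within genome '", gid, "'", call. = FALSE)
        }
        for (r in rows) {
          dna <- attr(ex, paste0("dna_", r))
          if (ex$strand[r] == "-") dna <- revcomp(dna)
          backbone[ex$start_bp[r]:ex$end_bp[r]] <- strsplit(dna, "")[[1]]
          attr(ex, paste0("dna_", r)) <- NULL
        }
      }
      genomes[gid] <- paste(backbone, collapse = "")
    }
    out_truth <- truth
    out_truth$placements <- ex
    structure(list(genomes = genomes, truth = out_truth, families = families),
              class = "community")
  })
}

#' Back-translate a protein with uniform synonymous codon choice
#'
#' Each residue is encoded by a codon drawn uniformly from its synonyms
#' under genetic code table 11; a TAA stop codon is appended. Uses the
#' current RNG stream.
#'
#' @param protein Protein sequence (no gaps).
#' @return DNA string of length `3 * (nchar(protein) + 1)`.
#' @export
back_translate <- function(protein) {
  gc11 <- genetic_code_11()
  by_aa <- split(names(gc11), gc11)
  res <- strsplit(protein, "")[[1]]
  bad <- setdiff(res, names(by_aa))
  if (length(bad)) stop("cannot back-translate residue(s): ",
                        paste(unique(bad), collapse = ", "), call. = FALSE)
  codons <- vapply(res, function(a) {
    syn <- by_aa[[a]]
    syn[sample.int(length(syn), 1L)]
  }, character(1))
  paste(c(codons, "TAA"), collapse = "")
}

#' Translate a genomic interval under genetic code table 11
#'
#' Utility for round-trip checks: extracts `[start, end]` from a genome
#' (reverse-complemented for the minus strand), drops a trailing stop codon,
#' and translates.
#'
#' @param genome Genome sequence.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Protein string.
#' @export
translate_placement <- function(genome, start, end, strand = "+") {
  dna <- substr(genome, start, end)
  if (strand == "-") dna <- revcomp(dna)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

#' Write community genomes as FASTA
#' @param community A `community`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_community_fasta <- function(community, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(community$genomes), path)
  invisible(path)
}

#' Serialize community ground truth to JSON
#' @param community A `community` (or `community_truth`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(community, path) {
  truth <- if (inherits(community, "community")) community$truth else community
  jsonlite::write_json(list(genomes = truth$genomes,
                            placements = truth$placements),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
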