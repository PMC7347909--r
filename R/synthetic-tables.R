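# Synthetic mercury chemistry and KO abundance tables.

#' Specify a synthetic Hg chemistry depth profile
#'
#' Emulates seawater THg/MeHg depth profiles: THg fluctuates around a base
#' level while MeHg increases linearly with depth, capped at THg (MeHg is a
#' fraction of total mercury). Values below the method detection limits are
#' emitted as censored ("not detected") rows. Defaults match open-ocean
#' magnitudes: THg around 0.9 pM, MeHg reaching ~0.6 pM at 800 m, MDLs of
#' 0.25 pM (THg) and 0.007 pM (MeHg).
#'
#' @param stations Character vector of station labels.
#' @param depths_m Numeric vector of sampling depths (m).
#' @param thg_base_pM Baseline THg concentration (pM).
#' @param mehg_slope_per_m MeHg increase per metre of depth (pM/m).
#' @param noise_sd_pM Gaussian noise SD applied to both analytes (pM).
#' @param mdl_pM Named vector `c(thg = , mehg = )` of detection limits (pM).
#' @param seed Integer seed.
#' @return An object of class `hg_table_spec`.
#' @export
hg_table_spec <- function(stations = c("St0", "St1"),
                          depths_m = c(0, 100, 200, 500, 800),
                          thg_base_pM = 0.9, mehg_slope_per_m = 7e-4,
                          noise_sd_pM = 0.05,
                          mdl_pM = c(thg = 0.25, mehg = 0.007),
                          seed = NULL) {
  stopifnot(length(depths_m) >= 1, thg_base_pM >= 0, noise_sd_pM >= 0)
  if (any(mdl_pM < 0)) stop("detection limits must be nonnegative", call. = FALSE)
  structure(list(stations = stations, depths_m = depths_m,
                 thg_base_pM = thg_base_pM,
                 mehg_slope_per_m = mehg_slope_per_m,
                 noise_sd_pM = noise_sd_pM, mdl_pM = mdl_pM, seed = seed),
            class = "hg_table_spec")
}

#' Generate a synthetic Hg chemistry table
#'
#' @param spec An [hg_table_spec()].
#' @return Data frame with columns `station`, `depth_m`, `thg_pM`,
#'   `mehg_pM`, `thg_nd`, `mehg_nd`. Censored (`*_nd = TRUE`) rows keep the
#'   detection-limit-censored flag; the numeric columns hold the generated
#'   value for bookkeeping but should be passed through [censor_nd()] before
#'   statistics. MeHg never exceeds THg.
#' @export
make_hg_table <- function(spec) {
  stopifnot(inherits(spec, "hg_table_spec"))
  with_seed(spec$seed, {
    grid <- expand.grid(depth_m = spec$depths_m, station = spec$stations,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, c("station", "depth_m")]
    n <- nrow(grid)
    thg <- pmax(0, spec$thg_base_pM + rnorm(n, 0, spec$noise_sd_pM))
    mehg <- spec$mehg_slope_per_m * grid$depth_m + rnorm(n, 0, spec$noise_sd_pM)
    mehg <- pmin(pmax(mehg, 0), thg)
    out <- data.frame(grid,
                      thg_pM = thg, mehg_pM = mehg,
                      thg_nd = thg < spec$mdl_pM[["thg"]],
                      mehg_nd = mehg < spec$mdl_pM[["mehg"]],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Write an Hg chemistry table as TSV with "ND" sentinels
#' @param tab Table from [make_hg_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hg_table <- function(tab, path) {
  out <- data.frame(station = tab$station, depth_m = tab$depth_m,
                    thg_pM = ifelse(tab$thg_nd, "ND",
                                    formatC(tab$thg_pM, digits = 6, format = "g")),
                    mehg_pM = ifelse(tab$mehg_nd, "ND",
                                     formatC(tab$mehg_pM, digits = 6, format = "g")),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an Hg chemistry TSV ("ND" sentinel for censored values)
#' @param path TSV path with columns station, depth_m, thg_pM, mehg_pM.
#' @return Data frame in the [make_hg_table()] layout.
#' @export
read_hg_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  data.frame(station = raw$station, depth_m = as.numeric(raw$depth_m),
             thg_pM = suppressWarnings(as.numeric(ifelse(raw$thg_pM == "ND", "0",
                                                         raw$thg_pM))),
             mehg_pM = suppressWarnings(as.numeric(ifelse(raw$mehg_pM == "ND", "0",
                                                          raw$mehg_pM))),
             thg_nd = raw$thg_pM == "ND", mehg_nd = raw$mehg_pM == "ND",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic KO abundance table
#'
#' Nonnegative integer counts with a controllable zero fraction: each cell
#' is zero with probability `sparsity`, otherwise 1 plus a negative-binomial
#' draw.
#'
#' @param n_samples Number of sample columns.
#' @param ko_ids Character vector of KO identifiers (rows).
#' @param sparsity Probability that a cell is zero, in \[0, 1\].
#' @param seed Integer seed.
#' @param mean_count Mean of the nonzero count distribution.
#' @return Integer matrix (KO x samples).
#' @export
make_ko_table <- function(n_samples, ko_ids, sparsity = 0.3, seed = NULL,
                          mean_count = 500) {
  stopifnot(length(ko_ids) >= 1, n_samples >= 1,
            sparsity >= 0, sparsity <= 1)
  with_seed(seed, {
    n <- length(ko_ids) * n_samples
    zero <- runif(n) < sparsity
    counts <- ifelse(zero, 0L, 1L + rnbinom(n, mu = mean_count, size = 2))
    matrix(as.integer(counts), nrow = length(ko_ids),
           dimnames = list(ko_ids,
                           sprintf("sample%02d", seq_len(n_samples))))
  })
}

#' Read a KO abundance TSV (KO ids as rows, samples as columns)
#' @param path TSV path; first column holds KO ids.
#' @return Integer matrix with KO row names.
#' @export
read_ko_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a KO abundance table as TSV
#' @param mat KO x sample matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ko_table <- function(mat, path) {
  out <- data.frame(KO = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged acetyl-CoA pathway KO abundance table
#'
#' The worked-example KO abundance table for the reductive acetyl-CoA
#' (Wood-Ljungdahl) module: counts of ten KEGG orthologs across 19 seawater
#' metagenome samples (four stations, depths 0-800 m), as shipped in
#' `inst/extdata/acetyl_coa_ko_table.tsv`.
#'
#' @return Integer matrix (10 KOs x 19 samples).
#' @export
acetyl_coa_ko_table <- function() {
  read_ko_table(system.file("extdata", "acetyl_coa_ko_table.tsv",
                            package = "hgcscan", mustWork = TRUE))
}

#' Packaged reductive acetyl-CoA module definition
#'
#' Ten single-KO components in table row order; a component is satisfied
#' when its KO has a nonzero count.
#'
#' @return A [module_definition()].
#' @export
acetyl_coa_module <- function() {
  read_module_json(system.file("extdata", "acetyl_coa_module.json",
                               package = "hgcscan", mustWork = TRUE))[[1]]
}
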