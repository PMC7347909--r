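# Study-level synthetic scenarios: spiked communities and depth surveys.

#' Build a community with a known hgcA:recA spike ratio
#'
#' One genome carrying `n_recA` recA copies and
#' `round(ratio_pct / 100 * n_recA)` hgcA copies at random non-overlapping
#' positions, so the abundance-weighted copy ratio is exactly the realized
#' copy count ratio. The genome length is sized so that the placed genes
#' occupy roughly half of it, the rest being random intergenic background.
#'
#' @param ratio_pct Target hgcA:recA copy ratio in percent.
#' @param families Named list with `hgcA` and `recA` `ref_family` objects.
#' @param n_recA Number of recA copies.
#' @param seed Integer seed.
#' @return A `community`.
#' @export
make_spiked_community <- function(ratio_pct, families, n_recA = 1000L,
                                  seed = NULL) {
  n_hgcA <- max(0L, as.integer(round(ratio_pct / 100 * n_recA)))
  gene_bp <- function(fam) 3L * (nchar(families[[fam]]$ancestor) + 1L)
  total_gene_bp <- n_recA * gene_bp("recA") + n_hgcA * gene_bp("hgcA")
  glen <- as.integer(ceiling(total_gene_bp * 2))
  pl <- data.frame(genome_id = "g1",
                   family = c("recA", "hgcA"),
                   copies = c(n_recA, n_hgcA),
                   stringsAsFactors = FALSE)
  pl <- pl[pl$copies > 0, , drop = FALSE]
  truth <- community_truth(
    data.frame(genome_id = "g1", length_bp = glen, abundance = 1,
               stringsAsFactors = FALSE), pl)
  make_community(truth, families, seed = seed)
}

#' Simulate a two-station depth survey with depth-spiked hgcA
#'
#' The end-to-end synthetic study: for each station and depth a community
#' is built in which the hgcA:recA copy ratio increases with depth, reads
#' are simulated and quantified through the full pipeline, and a matching
#' Hg chemistry table with MeHg increasing with depth is generated. The
#' result feeds [correlate_profiles()] directly.
#'
#' @param profiles Named list of calibrated profiles (hgcA, hgcB, recA).
#' @param families The `ref_family` list the profiles were built from.
#' @param stations Station labels.
#' @param depths_m Sampling depths.
#' @param hgcA_copies_by_depth Integer hgcA copy numbers, one per depth
#'   (recA is fixed at `n_recA` copies).
#' @param n_recA recA copies per community.
#' @param n_pairs Read pairs per sample.
#' @param seed Integer seed.
#' @param hg_spec An [hg_table_spec()]; defaults to the standard profile
#'   shape over `stations` and `depths_m`.
#' @return List with `abundance` (row-bound records), `hg` (chemistry
#'   table), and `truth_ratio_pct` per depth.
#' @export
simulate_survey <- function(profiles, families,
                            stations = c("St0", "St1"),
                            depths_m = c(0, 100, 200, 500, 800),
                            hgcA_copies_by_depth = c(0L, 1L, 2L, 4L, 8L),
                            n_recA = 100L, n_pairs = 8000L, seed = 1L,
                            hg_spec = NULL) {
  stopifnot(length(hgcA_copies_by_depth) == length(depths_m))
  hg_spec <- hg_spec %||% hg_table_spec(stations = stations,
                                        depths_m = depths_m,
                                        noise_sd_pM = 0.02,
                                        seed = seed + 7000L)
  records <- list()
  k <- 0L
  for (si in seq_along(stations)) {
    for (di in seq_along(depths_m)) {
      k <- k + 1L
      sub_seed <- seed + 100L * si + di
      comm <- make_spiked_community(100 * hgcA_copies_by_depth[di] / n_recA,
                                    families, n_recA = n_recA,
                                    seed = sub_seed)
      cfg <- sim_config(n_pairs = n_pairs, seed = sub_seed + 50000L)
      pairs <- simulate_reads(comm, cfg)
      rec <- quantify_sample(pairs, profiles,
                             sample_id = sprintf("%s_%gm", stations[si],
                                                 depths_m[di]),
                             station = stations[si], depth_m = depths_m[di])
      records[[k]] <- rec
    }
  }
  list(abundance = do.call(rbind, records),
       hg = make_hg_table(hg_spec),
       truth_ratio_pct = stats::setNames(100 * hgcA_copies_by_depth / n_recA,
                                         depths_m))
}
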