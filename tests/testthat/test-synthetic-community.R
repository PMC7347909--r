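toy_families <- function(seed = 11) {
  list(hgcA = make_reference_family(family_spec("hgcA", 5, 60, 0.05,
                                                conserved_positions = 1L,
                                                seed = seed)),
       recA = make_reference_family(family_spec("recA", 5, 60, 0.05,
                                                conserved_positions = 1L,
                                                seed = seed + 1L)))
}

test_that("expected copy ratio matches hand arithmetic", {
  g1 <- data.frame(genome_id = "g1", length_bp = 5000L, abundance = 1)
  pl1 <- data.frame(genome_id = "g1", family = c("hgcA", "recA"),
                    copies = c(1L, 1L))
  expect_equal(expected_copy_ratio(community_truth(g1, pl1)), 100)

  g2 <- data.frame(genome_id = c("g1", "g2"), length_bp = c(5000L, 5000L),
                   abundance = c(0.5, 0.5))
  pl2 <- data.frame(genome_id = c("g1", "g1", "g2"),
                    family = c("hgcA", "recA", "recA"),
                    copies = c(1L, 1L, 1L))
  expect_equal(expected_copy_ratio(community_truth(g2, pl2)), 50)
})

test_that("expected copy ratio equals independent enumeration for random truths", {
  set.seed(21)
  for (i in 1:100) {
    ng <- sample(2:5, 1)
    ab <- runif(ng); ab <- ab / sum(ab)
    g <- data.frame(genome_id = paste0("g", seq_len(ng)),
                    length_bp = 5000L, abundance = ab)
    pl <- data.frame(
      genome_id = paste0("g", sample(ng, 6, replace = TRUE)),
      family = sample(c("hgcA", "recA"), 6, replace = TRUE, prob = c(.4, .6)),
      copies = sample(1:3, 6, replace = TRUE))
    if (!any(pl$family == "recA")) next
    truth <- community_truth(g, pl)
    # naive enumeration: expand copies one by one
    num <- 0; den <- 0
    for (r in seq_len(nrow(pl))) {
      for (k in seq_len(pl$copies[r])) {
        w <- ab[match(pl$genome_id[r], g$genome_id)]
        if (pl$family[r] == "hgcA") num <- num + w else den <- den + w
      }
    }
    expect_equal(expected_copy_ratio(truth), 100 * num / den)
  }
})

test_that("abundances must sum to one", {
  g <- data.frame(genome_id = "g1", length_bp = 100L, abundance = 0.5)
  pl <- data.frame(genome_id = "g1", family = "recA")
  expect_error(community_truth(g, pl), "sum to 1")
})

test_that("placed genes translate back to their source protein (table 11)", {
  fams <- toy_families()
  for (seed in c(1, 2, 3)) {
    g <- data.frame(genome_id = "g1", length_bp = 3000L, abundance = 1)
    pl <- data.frame(genome_id = "g1", family = c("hgcA", "recA", "recA"),
                     copies = c(2L, 3L, 1L))
    comm <- make_community(community_truth(g, pl), fams, seed = seed)
    ex <- comm$truth$placements
    expect_equal(nrow(ex), 6L)
    for (r in seq_len(nrow(ex))) {
      prot <- translate_placement(comm$genomes[[ex$genome_id[r]]],
                                  ex$start_bp[r], ex$end_bp[r], ex$strand[r])
      expect_identical(prot, ex$protein[r])
    }
    # placements do not overlap
    ord <- order(ex$start_bp)
    expect_true(all(ex$start_bp[ord][-1] > ex$end_bp[ord][-length(ord)]))
  }
})

test_that("placements beyond the genome or overlapping are rejected", {
  fams <- toy_families()
  g <- data.frame(genome_id = "g1", length_bp = 200L, abundance = 1)
  pl <- data.frame(genome_id = "g1", family = "recA", copies = 1L,
                   start_bp = 150L, strand = "+")
  expect_error(make_community(community_truth(g, pl), fams, seed = 1),
               "beyond genome")
  g2 <- data.frame(genome_id = "g1", length_bp = 1000L, abundance = 1)
  pl2 <- data.frame(genome_id = "g1", family = c("recA", "recA"),
                    copies = c(1L, 1L), start_bp = c(10L, 100L),
                    strand = c("+", "+"))
  expect_error(make_community(community_truth(g2, pl2), fams, seed = 1),
               "overlap")
})

test_that("community construction is deterministic per seed", {
  fams <- toy_families()
  g <- data.frame(genome_id = "g1", length_bp = 2000L, abundance = 1)
  pl <- data.frame(genome_id = "g1", family = c("hgcA", "recA"))
  c1 <- make_community(community_truth(g, pl), fams, seed = 5)
  c2 <- make_community(community_truth(g, pl), fams, seed = 5)
  expect_identical(c1$genomes, c2$genomes)
})
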