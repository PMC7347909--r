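mk_pair <- function(seq1, seq2, q1 = strrep("I", nchar(seq1)),
                    q2 = strrep("I", nchar(seq2)), id = "p1") {
  data.frame(id = id, seq1 = seq1, qual1 = q1, seq2 = seq2, qual2 = q2,
             stringsAsFactors = FALSE)
}

test_that("adapter trimming removes exact read-through and keeps clean reads", {
  adapter <- "AGATCGGAAGAGC"
  core <- "ACGTACGTACGTACGTACGT"
  p <- mk_pair(paste0(core, adapter), core,
               q1 = strrep("I", nchar(core) + nchar(adapter)),
               q2 = strrep("I", nchar(core)))
  tr <- remove_adapters(p, adapter)
  expect_identical(tr$seq1, core)
  expect_identical(nchar(tr$qual1), nchar(core))
  expect_identical(tr$seq2, core) # unchanged: no adapter present
  # partial adapter prefix at the 3' end is also removed
  p2 <- mk_pair(paste0(core, substr(adapter, 1, 6)), core)
  expect_identical(remove_adapters(p2, adapter)$seq1, core)
})

test_that("trimmed read-through reads match the fragment-truncation oracle", {
  fams <- list(recA = make_reference_family(
    family_spec("recA", 3, 40, 0, seed = 81)))
  g <- data.frame(genome_id = "g1", length_bp = 4000L, abundance = 1)
  pl <- data.frame(genome_id = "g1", family = "recA")
  comm <- make_community(community_truth(g, pl), fams, seed = 82)
  cfg <- sim_config(n_pairs = 1000, insert_mean_bp = 200, insert_sd_bp = 25,
                    min_fragment_bp = 120L, per_base_error = 0, seed = 83)
  pr <- simulate_reads(comm, cfg)
  tr <- remove_adapters(pr, cfg$adapter_seq)
  genome <- comm$genomes[["g1"]]
  short <- which(pr$frag_len < cfg$read_length_bp)
  expect_gt(length(short), 100)
  frag <- substr(rep(genome, length(short)), pr$frag_start[short],
                 pr$frag_start[short] + pr$frag_len[short] - 1)
  frag <- ifelse(pr$flipped[short], revcomp(frag), frag)
  # oracle: the trimmed mate is the fragment itself
  expect_gt(mean(tr$seq1[short] == frag), 0.99)
  expect_gt(mean(tr$seq2[short] == revcomp(frag)), 0.99)
})

test_that("merging a perfectly overlapping pair returns mate 1", {
  s <- "ACGGTTACGGATCCAGTTACGATCGAT"
  p <- mk_pair(s, revcomp(s))
  m <- merge_pairs(p, qc_config(min_overlap_bp = 10))
  expect_true(m$merged)
  expect_identical(m$seq, s)
  expect_equal(m$overlap_len, nchar(s))
})

test_that("conflicting bases take the higher-quality mate", {
  s1 <- "ACGGTTACGGATCCAGTTACGATCGAT"
  s2 <- s1
  substr(s2, 5, 5) <- "A" # conflict at position 5 (s1 has T)
  # mate 2 higher quality everywhere
  p <- mk_pair(s1, revcomp(s2), q1 = strrep("#", nchar(s1)),
               q2 = strrep("I", nchar(s2)))
  m <- merge_pairs(p, qc_config(min_overlap_bp = 10))
  expect_true(m$merged)
  expect_identical(m$seq, s2)
  # consensus quality at the conflict is |Q1 - Q2|
  q <- as.integer(charToRaw(m$qual))[5] - 33L
  expect_equal(q, abs((utf8ToInt("I") - 33L) - (utf8ToInt("#") - 33L)))
})

test_that("pairs without an admissible overlap are flagged unmerged", {
  p <- mk_pair(strrep("A", 30), strrep("C", 30))
  m <- merge_pairs(p, qc_config(min_overlap_bp = 10))
  expect_false(m$merged)
})

test_that("merging reconstructs error-free fragments and is mate-symmetric", {
  fams <- list(recA = make_reference_family(
    family_spec("recA", 5, 80, 0.05, seed = 84)))
  g <- data.frame(genome_id = "g1", length_bp = 5000L, abundance = 1)
  pl <- data.frame(genome_id = "g1", family = "recA", copies = 2L)
  comm <- make_community(community_truth(g, pl), fams, seed = 85)
  pr <- simulate_reads(comm, sim_config(n_pairs = 500, per_base_error = 0,
                                        seed = 86))
  m <- merge_pairs(pr)
  genome <- comm$genomes[["g1"]]
  frag <- substr(rep(genome, nrow(pr)), pr$frag_start,
                 pr$frag_start + pr$frag_len - 1)
  frag <- ifelse(pr$flipped, revcomp(frag), frag)
  expect_gte(mean(m$seq[m$merged] == frag[m$merged]), 0.99)
  expect_gte(mean(m$merged), 0.99)
  # symmetry: swapping mates gives the reverse-complement consensus
  sw <- pr
  sw$seq1 <- pr$seq2; sw$qual1 <- pr$qual2
  sw$seq2 <- pr$seq1; sw$qual2 <- pr$qual1
  m2 <- merge_pairs(sw)
  both <- m$merged & m2$merged
  expect_identical(revcomp(m2$seq[both]), m$seq[both])
})

test_that("quality filter applies inclusive boundaries and is idempotent", {
  q40 <- function(n) strrep(intToUtf8(40L + 33L), n)
  mk <- function(len, qchar) data.frame(
    id = "r", seq = strrep("A", len), qual = strrep(qchar, len),
    overlap_len = 10L, merged = TRUE, stringsAsFactors = FALSE)
  cfg <- qc_config()
  # length 299, high quality -> removed
  expect_equal(nrow(quality_filter(mk(299, intToUtf8(73L)), cfg)), 0)
  # length 350, mean quality just below 20 -> removed
  r <- mk(350, intToUtf8(19L + 33L))
  expect_equal(nrow(quality_filter(r, cfg)), 0)
  # length 300, mean quality exactly 20 -> retained
  r2 <- mk(300, intToUtf8(20L + 33L))
  expect_equal(nrow(quality_filter(r2, cfg)), 1)
  # idempotence
  mixed <- rbind(mk(299, "I"), mk(300, "I"), mk(400, "#"))
  once <- quality_filter(mixed, cfg)
  twice <- quality_filter(once, cfg)
  expect_identical(once$seq, twice$seq)
  expect_equal(attr(twice, "n_removed"), 0)
})

test_that("the trim-merge-filter pipeline keeps long-insert fragments", {
  fams <- list(recA = make_reference_family(
    family_spec("recA", 4, 60, 0, seed = 87)))
  g <- data.frame(genome_id = "g1", length_bp = 4000L, abundance = 1)
  pl <- data.frame(genome_id = "g1", family = "recA")
  comm <- make_community(community_truth(g, pl), fams, seed = 88)
  cfg <- sim_config(n_pairs = 400, per_base_error = 0, p_low = 0, seed = 89)
  pr <- simulate_reads(comm, cfg)
  kept <- process_reads(pr)
  # error-free, high quality, inserts >= 300 and overlap >= 150: no losses
  eligible <- pr$frag_len >= 300
  expect_equal(nrow(kept), sum(eligible))
})
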