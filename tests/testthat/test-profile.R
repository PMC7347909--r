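test_that("gap-free alignments produce one match state per column", {
  aln <- c(a = "MKLW", b = "MKIW", c = "MRLW")
  p <- build_profile(aln)
  expect_equal(p$n_match_states, 4L)
  expect_equal(p$column_map, 1:4)
})

test_that("columns with more than 50% gaps are excluded from match states", {
  aln <- c(a = "MKL-W", b = "MK--W", c = "M-L-W", d = "MKLAW", e = "MK-AW")
  # column 4 has 3/5 = 60% gaps -> insert column; column 3 has 40% -> match
  p <- build_profile(aln)
  expect_equal(p$column_map, c(1L, 2L, 3L, 5L))
})

test_that("emissions equal the hand-computed pseudocount formula on a toy", {
  aln <- c(a = "MKL-", b = "MKI-", c = "M-LW")
  p <- build_profile(aln, pseudocount_weight = 1)
  # background: pooled residues M,K,L,M,K,I,M,L,W with add-one smoothing
  pool <- c(M = 3, K = 2, L = 2, I = 1, W = 1)
  bg <- setNames(rep(1 / (9 + 20), 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  bg[names(pool)] <- (pool + 1) / 29
  expect_equal(p$background_freqs, bg)
  # column 1: three M out of 3 -> (3 + bg_M) / 4
  expect_equal(unname(p$match_emissions["M", 1]), (3 + bg[["M"]]) / 4)
  expect_equal(unname(p$match_emissions["A", 1]), (0 + bg[["A"]]) / 4)
  # column 2: two K out of 2 non-gap -> (2 + bg_K) / 3
  expect_equal(unname(p$match_emissions["K", 2]), (2 + bg[["K"]]) / 3)
  # column 3: L,I,L -> (2 + bg_L) / 4 and (1 + bg_I) / 4
  expect_equal(unname(p$match_emissions["L", 3]), (2 + bg[["L"]]) / 4)
  expect_equal(unname(p$match_emissions["I", 3]), (1 + bg[["I"]]) / 4)
  # every emission vector sums to one (3 match columns: column 4 is 2/3 gaps)
  expect_equal(unname(colSums(p$match_emissions)), rep(1, 3), tolerance = 1e-9)
})

test_that("a degenerate alignment with no match columns errors", {
  aln <- c(a = "--", b = "A-", c = "-C")
  expect_error(build_profile(aln), "no match columns")
})

test_that("single-state all-Ala profile scores query A as log2(1/bg_A)", {
  # force emission 1 on A by an alignment of pure A columns
  aln <- c(a = "A", b = "A", c = "A")
  p <- build_profile(aln, pseudocount_weight = 0)
  s <- score_sequence(p, "A", n_targets = NA)
  expect_equal(unname(s["bitscore"]),
               log2(1 / p$background_freqs[["A"]]), tolerance = 1e-9)
})

test_that("family members score above their shuffles on the family profile", {
  profs <- test_profiles()
  fams <- test_families()
  set.seed(202)
  members <- fams$hgcA$members[seq(1, 145, by = 15)]
  for (m in members) {
    s_true <- score_sequence(profs$hgcA, m, n_targets = NA)[["bitscore"]]
    for (k in 1:10) {
      shuf <- paste(sample(strsplit(m, "")[[1]]), collapse = "")
      s_shuf <- score_sequence(profs$hgcA, shuf, n_targets = NA)[["bitscore"]]
      expect_gt(s_true, s_shuf)
    }
  }
})

test_that("scores are finite and bounded below for unrelated single residues", {
  profs <- test_profiles()
  s <- score_sequence(profs$hgcA, "W", n_targets = 1)
  expect_true(is.finite(s[["bitscore"]]))
  expect_gte(s[["bitscore"]], 0) # empty local alignment floor
  expect_gte(s[["evalue"]], 1)   # a 1-residue query is never significant
})

test_that("appending unrelated residues never lowers the local score", {
  profs <- test_profiles()
  fams <- test_families()
  set.seed(203)
  for (i in 1:20) {
    q <- fams$hgcB$members[[sample(128, 1)]]
    s1 <- score_sequence(profs$hgcB, q, n_targets = NA)[["bitscore"]]
    s2 <- score_sequence(profs$hgcB, paste0(q, random_protein(30)),
                         n_targets = NA)[["bitscore"]]
    expect_gte(s2 + 1e-9, s1)
  }
})

test_that("Gumbel ML fit recovers known parameters", {
  set.seed(204)
  x <- 5 - 2 * log(-log(runif(5000))) # Gumbel(mu = 5, beta = 2)
  fit <- fit_gumbel(x)
  expect_lt(abs(fit[["mu"]] - 5), 0.2)
  expect_lt(abs(fit[["beta"]] - 2), 0.2)
})

test_that("null E-values are approximately uniform at the tail", {
  profs <- test_profiles()
  prof <- profs$hgcB
  set.seed(205)
  n <- 400
  bg <- prof$background_freqs
  nulls <- vapply(seq_len(n), function(i) {
    paste(sample(names(bg), prof$calibration$null_len, replace = TRUE,
                 prob = bg), collapse = "")
  }, character(1))
  ev <- vapply(nulls, function(q)
    score_sequence(prof, q, n_targets = 1)[["evalue"]], numeric(1))
  frac <- mean(ev <= 0.1)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("calibration is deterministic per seed and errors on degenerate nulls", {
  fams <- test_families()
  p <- build_profile(fams$hgcB)
  c1 <- calibrate(p, n_null = 200, seed = 9)
  c2 <- calibrate(p, n_null = 200, seed = 9)
  expect_identical(c1$calibration, c2$calibration)
  expect_error(evalue_from_score(p, 10), "not calibrated")
})

test_that("every reference member is retrieved by its own profile at 1e-5", {
  profs <- test_profiles()
  fams <- test_families()
  for (fam in names(fams)) {
    hits <- profile_search(profs[[fam]], fams[[fam]]$members, 1e-5,
                           method = "exact")
    expect_setequal(hits$query_id, names(fams[[fam]]$members))
    expect_true(all(diff(hits$evalue) >= 0))
  }
})

test_that("non-homologous decoy families yield zero cross-family hits", {
  profs <- test_profiles()
  decoys <- test_decoys()
  for (fam in names(profs)) {
    for (dec in names(decoys)) {
      hits <- profile_search(profs[[fam]], decoys[[dec]]$members, 1e-5,
                             method = "exact")
      expect_equal(nrow(hits), 0)
    }
  }
  # and across the real families themselves
  fams <- test_families()
  expect_equal(nrow(profile_search(profs$hgcB, fams$hgcA$members, 1e-5,
                                   method = "exact")), 0)
  expect_equal(nrow(profile_search(profs$hgcA, fams$hgcB$members, 1e-5,
                                   method = "exact")), 0)
})

test_that("searching an empty protein set returns an empty hit table", {
  profs <- test_profiles()
  hits <- profile_search(profs$hgcA, character(0))
  expect_s3_class(hits, "hgc_hits")
  expect_equal(nrow(hits), 0)
})

test_that("profiles survive a JSON round trip", {
  profs <- test_profiles()
  fams <- test_families()
  d <- withr::local_tempdir()
  f <- file.path(d, "hgcA.json")
  profile_to_json(profs$hgcA, f)
  back <- profile_from_json(f)
  q <- fams$hgcA$members[[3]]
  expect_equal(score_sequence(back, q, 10), score_sequence(profs$hgcA, q, 10),
               tolerance = 1e-9)
  expect_equal(back$column_map, profs$hgcA$column_map)
  expect_equal(length(back$motif_anchors), length(profs$hgcA$motif_anchors))
})
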