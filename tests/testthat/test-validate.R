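test_that("hgcB validation needs two non-overlapping ferredoxin motifs", {
  two <- paste0("CAACAACAAAC", "GGGGG", "CAACAACAAAC")
  one <- paste0("CAACAACAAAC", "GGGGGGGGGG")
  expect_true(validate_hgcB(two))
  expect_false(validate_hgcB(one))
  expect_false(validate_hgcB("GGGGGGGGGGGGGGGGGGGGGG"))
})

test_that("hgcB validator agrees with the brute-force oracle on random input", {
  set.seed(301)
  # random sequences, enriched in C so motifs actually occur sometimes
  for (i in 1:1000) {
    p <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C", "C"),
                      100, replace = TRUE), collapse = "")
    expect_identical(validate_hgcB(p), oracle_count_cx2cx2cx3c(p) >= 2L)
  }
})

test_that("synthetic hgcA members pass cap-helix validation; mutants fail", {
  profs <- test_profiles()
  fams <- test_families()
  prof <- profs$hgcA
  for (idx in c(1, 50, 100, 145)) {
    m <- fams$hgcA$members[[idx]]
    hit <- profile_search(prof, setNames(m, "q"), 1e-5)
    expect_equal(nrow(hit), 1)
    expect_true(as.logical(validate_hgcA(hit[1, ], m, prof)))
    mut <- m
    substr(mut, 93, 93) <- "A" # knock out the anchored cysteine
    hit2 <- profile_search(prof, setNames(mut, "q"), 1e-5)
    if (nrow(hit2)) {
      v <- validate_hgcA(hit2[1, ], mut, prof)
      expect_false(as.logical(v))
      expect_identical(attr(v, "reason"), "anchor residue is not Cys")
    }
  }
})

test_that("hits not covering the motif window fail with a logged reason", {
  profs <- test_profiles()
  fams <- test_families()
  prof <- profs$hgcA
  # fragment downstream of the cap helix: residues 120..349
  frag <- substr(fams$hgcA$members[[7]], 120, 349)
  hit <- profile_search(prof, setNames(frag, "q"), 1e-3)
  expect_equal(nrow(hit), 1)
  v <- validate_hgcA(hit[1, ], frag, prof)
  expect_false(as.logical(v))
  expect_identical(attr(v, "reason"), "motif region not covered")
})

test_that("the validator agrees with a brute-force aligned-column oracle", {
  profs <- test_profiles()
  fams <- test_families()
  prof <- profs$hgcA
  rule <- cap_helix_rule()
  set.seed(302)
  checked <- 0L
  for (i in 1:500) {
    # random windows of random members, sometimes mutated at the anchor
    m <- fams$hgcA$members[[sample(145, 1)]]
    from <- sample(c(1, 1, sample(40:150, 1)), 1)
    frag <- substr(m, from, min(349, from + sample(120:250, 1)))
    if (runif(1) < 0.3) substr(frag, 94 - from, 94 - from) <- "P"
    hit <- profile_search(prof, setNames(frag, "q"), 1e-3)
    if (!nrow(hit)) next
    checked <- checked + 1L
    got <- as.logical(validate_hgcA(hit[1, ], frag, prof))
    # oracle: look up the query residues aligned to states 90..97 directly
    path <- hit$state_path[[1]]
    want <- FALSE
    qpos <- vapply(90:97, function(st) {
      w <- which(path == st)
      if (length(w) == 1) w else NA_integer_
    }, integer(1))
    if (!anyNA(qpos)) {
      window <- paste(strsplit(frag, "")[[1]][qpos], collapse = "")
      want <- grepl("^N[VI]WCA[AG]GK$", window) &&
        substr(window, 4, 4) == "C"
    }
    expect_identical(got, want)
  }
  expect_gt(checked, 300)
})

test_that("length and gap rules apply the documented thresholds", {
  long_prot <- strrep("A", 175)
  expect_true(apply_length_rules(long_prot, "hgcA"))
  expect_false(apply_length_rules(strrep("A", 174), "hgcA"))
  expect_true(apply_length_rules(strrep("A", 50), "hgcB"))
  expect_false(apply_length_rules(strrep("A", 49), "hgcB"))
  # 51% gaps -> rejected even when long enough
  gappy <- paste0(strrep("A", 196), strrep("-", 204))
  expect_false(apply_length_rules(gappy, "hgcA"))
  half <- paste0(strrep("A", 200), strrep("-", 200))
  expect_true(apply_length_rules(half, "hgcA"))
  expect_error(apply_length_rules("AAA", "unknown_family"), "no length rule")
})

test_that("lineage assignment is exact for identical queries and tie-stable", {
  refs <- c(b_ref = "MKLWAGSTPQRVNDEILKHG", a_ref = "MKLWAGSTPQRVNDEILKHG",
            c_ref = "MKAWAGSVPQRVNDEILAHG")
  hit <- assign_lineage("MKLWAGSTPQRVNDEILKHG", refs)
  expect_equal(hit$pid, 100)
  expect_identical(hit$ref_id, "a_ref") # lexicographic tie-break
  lin <- assign_lineage("MKLWAGSTPQRVNDEILKHG", refs,
                        lineages = c(a_ref = "Nitrospina", b_ref = "Nitrospina",
                                     c_ref = "Deltaproteobacteria"))
  expect_identical(lin$lineage, "Nitrospina")
})

test_that("lineage assignment equals the exhaustive best-identity oracle", {
  fams <- test_families()
  refs <- fams$hgcB$members[1:20]
  set.seed(303)
  for (i in 1:10) {
    q <- fams$hgcB$members[[sample(21:128, 1)]]
    got <- assign_lineage(q, refs)
    pid <- vapply(refs, function(r) {
      a <- Biostrings::pairwiseAlignment(q, r, type = "global",
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 10, gapExtension = 0.5)
      Biostrings::pid(a, type = "PID1")
    }, numeric(1))
    best <- names(refs)[order(-pid, names(refs))[1]]
    expect_identical(got$ref_id, best)
  }
})
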