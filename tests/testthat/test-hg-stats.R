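test_that("mass-to-molar conversions reproduce the reference pairs", {
  expect_equal(round(mass_to_molar(1900), 1), 9.5)
  expect_equal(round(mass_to_molar(46), 2), 0.23)
  expect_equal(round(mass_to_molar(1.4), 3), 0.007)
  expect_equal(mass_to_molar(0), 0)
  expect_error(mass_to_molar(-1), "nonnegative")
  # round trip within 1e-9 relative
  x <- c(0.3, 49, 1900)
  expect_equal(molar_to_mass(mass_to_molar(x)), x, tolerance = 1e-9)
})

test_that("censoring maps not-detected to zero, passes detections, idempotent", {
  v <- c(0.30, 0.10, 0.50)
  det <- c(TRUE, FALSE, TRUE)
  expect_equal(censor_nd(v, det), c(0.30, 0, 0.50))
  expect_equal(censor_nd(censor_nd(v, det)), censor_nd(v, det))
  expect_equal(censor_nd(0.30, TRUE), 0.30)
})

test_that("Spearman handles monotone and antitone inputs exactly", {
  x <- 1:8
  expect_equal(spearman_rank(x, x + 3)$rho, 1)
  expect_equal(spearman_rank(x, exp(x))$rho, 1)
  expect_equal(spearman_rank(x, -2 * x)$rho, -1)
  expect_warning(s <- spearman_rank(x, rep(1, 8)), "constant")
  expect_true(is.na(s$rho))
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
})

test_that("rho and exact p match exhaustive enumeration for n <= 7 with ties", {
  cases <- list(
    list(x = c(1, 2, 2, 3, 4), y = c(2, 1, 3, 3, 5)),
    list(x = c(1, 1, 2, 3), y = c(4, 2, 2, 1)),
    list(x = c(3, 1, 4, 1, 5, 9, 2), y = c(2, 7, 1, 8, 2, 8, 1)),
    list(x = c(1, 2, 3, 4, 5, 6), y = c(2, 4, 3, 1, 6, 5)))
  for (cs in cases) {
    got <- spearman_rank(cs$x, cs$y)
    want <- oracle_spearman_exact(cs$x, cs$y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  # without ties the exact p also matches cor.test's exact test
  set.seed(601)
  for (i in 1:5) {
    x <- sample(100, 7); y <- sample(100, 7)
    got <- spearman_rank(x, y)
    ct <- cor.test(x, y, method = "spearman")
    expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(602)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    base <- spearman_rank(x, y)
    tx <- spearman_rank(exp(2 * x), y)
    ty <- spearman_rank(x, y^3)
    expect_equal(tx$rho, base$rho, tolerance = 1e-12)
    expect_equal(ty$rho, base$rho, tolerance = 1e-12)
    expect_equal(tx$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("censoring only reorders below-MDL entries", {
  x <- c(0.5, 0.8, 1.2, 2.0)
  y <- c(0.02, 0.3, 0.6, 0.9)
  det <- c(FALSE, TRUE, TRUE, TRUE)
  s_raw <- spearman_rank(x, y)
  s_cen <- spearman_rank(x, censor_nd(y, det))
  # the censored value was already the smallest: ranks unchanged
  expect_equal(s_cen$rho, s_raw$rho)
  # with no censored entries the vector is untouched
  expect_identical(censor_nd(y, rep(TRUE, 4)), y)
})

mk_abundance <- function(stations, depths, hgcA, hgcB = rev(hgcA)) {
  g <- expand.grid(depth_m = depths, station = stations,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(station = g$station, depth_m = g$depth_m,
             rel_hgcA_pct = hgcA, rel_hgcB_pct = hgcB,
             stringsAsFactors = FALSE)
}

test_that("noise-free monotone studies give rho = 1 in the hgcA x MeHg cell", {
  depths <- c(0, 100, 200, 500, 800)
  hg <- make_hg_table(hg_table_spec(stations = c("St0", "St1"),
                                    depths_m = depths, noise_sd_pM = 0,
                                    seed = 1))
  ab <- mk_abundance(c("St0", "St1"), depths,
                     hgcA = rep(c(0, 0.1, 0.2, 0.5, 1.0), 2))
  tab <- correlate_profiles(ab, hg)
  cell <- tab[tab$gene == "hgcA" & tab$variable == "MeHg" &
                tab$subset == "all", ]
  expect_equal(cell$rho, 1)
  expect_equal(cell$n, 10)
  # symmetry: swapping x and y leaves rho unchanged
  s1 <- spearman_rank(ab$rel_hgcA_pct, censor_nd(hg$mehg_pM, !hg$mehg_nd))
  s2 <- spearman_rank(censor_nd(hg$mehg_pM, !hg$mehg_nd), ab$rel_hgcA_pct)
  expect_equal(s1$rho, s2$rho)
})

test_that("permuted abundance labels show no significant correlation", {
  depths <- c(0, 100, 200, 500, 800)
  hg <- make_hg_table(hg_table_spec(stations = c("St0", "St1", "St4", "St5"),
                                    depths_m = depths, noise_sd_pM = 0.01,
                                    seed = 2))
  set.seed(603)
  n_sig <- 0L
  for (i in 1:100) {
    ab <- mk_abundance(c("St0", "St1", "St4", "St5"), depths,
                       hgcA = sample(seq(0, 1, length.out = 20)))
    tab <- correlate_profiles(ab, hg)
    p <- tab$p_value[tab$gene == "hgcA" & tab$variable == "MeHg" &
                       tab$subset == "all"]
    if (!is.na(p) && p <= 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 10)
})

test_that("undefined abundances are dropped and small subsets flagged", {
  depths <- c(0, 100, 200)
  hg <- make_hg_table(hg_table_spec(stations = c("St0", "St9"),
                                    depths_m = depths, seed = 3))
  ab <- mk_abundance(c("St0", "St9"), depths, hgcA = c(0.1, 0.2, 0.3, NA, NA, NA))
  tab <- correlate_profiles(ab, hg, deep_stations = "St9")
  deep <- tab[tab$gene == "hgcA" & tab$subset == "deep", ]
  expect_true(all(deep$note == "insufficient"))
  expect_true(all(is.na(deep$rho)))
  expect_gte(attr(tab, "n_dropped_undefined"), 1)
})
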