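make_pair_records <- function(pair, a, b, cfus_a, cfus_b, transfer = 6) {
  do.call(rbind, lapply(seq_along(cfus_a), function(r) {
    data.frame(pair = pair, species_a = a, species_b = b, replicate = r,
               transfer = transfer, species = c(a, b),
               cfu = c(cfus_a[r], cfus_b[r]), stringsAsFactors = FALSE)
  }))
}

test_that("relative_abundances normalizes each pair-replicate-transfer", {
  rec <- make_pair_records("p1", "A", "B", c(100, 99), c(100, 1))
  fr <- relative_abundances(competition_dataset(rec))
  expect_equal(fr$fraction[fr$replicate == 1], c(0.5, 0.5))
  expect_equal(fr$fraction[fr$replicate == 2], c(0.99, 0.01))
  # fractions sum to 1 for random positive counts
  set.seed(61)
  rec2 <- make_pair_records("p2", "A", "B", rpois(5, 500) + 1, rpois(5, 200) + 1)
  fr2 <- relative_abundances(competition_dataset(rec2))
  sums <- tapply(fr2$fraction, fr2$replicate, sum)
  expect_equal(as.numeric(sums), rep(1, 5))
  # both-zero record flagged undefined
  rec3 <- make_pair_records("p3", "A", "B", 0, 0)
  expect_warning(fr3 <- relative_abundances(competition_dataset(rec3)), "zero total")
  expect_true(all(is.na(fr3$fraction)))
})

test_that("classify_persistence applies the strict 1% mean rule", {
  rec <- rbind(make_pair_records("co", "A", "B", c(60, 60), c(40, 40)),
               make_pair_records("excl", "C", "D", c(995, 995), c(5, 5)),
               make_pair_records("edge", "E", "F", c(99, 99), c(1, 1)))
  calls <- classify_persistence(competition_dataset(rec))
  expect_equal(calls$outcome[calls$pair == "co"], "co_persistence")
  expect_equal(calls$outcome[calls$pair == "excl"], "exclusion_of_b")
  # mean fraction exactly 0.01 is NOT persisted (strict >)
  expect_equal(calls$outcome[calls$pair == "edge"], "exclusion_of_b")
  expect_false(calls$persisted_b[calls$pair == "edge"])
})

test_that("classify_persistence is invariant to replicate order", {
  set.seed(62)
  rec <- make_pair_records("p", "A", "B", c(900, 100, 400), c(100, 900, 600))
  shuffled <- rec[sample(nrow(rec)), ]
  c1 <- classify_persistence(competition_dataset(rec))
  c2 <- classify_persistence(competition_dataset(shuffled))
  expect_equal(c1$mean_frac_a, c2$mean_frac_a)
  expect_equal(c1$outcome, c2$outcome)
})

test_that("pairwise design counts and persistence index behave", {
  dd <- default_competition_design()
  expect_equal(nrow(dd$design), 28) # C(8, 2)
  expect_equal(sum(dd$design$pair_type == "cross_kingdom"), 16)
  expect_equal(sum(dd$design$pair_type == "within_kingdom"), 12)
  # a species persisting in all its 7 pairings has index 7
  rec <- do.call(rbind, lapply(seq_len(nrow(dd$design)), function(i) {
    a <- dd$design$species_a[i]; b <- dd$design$species_b[i]
    make_pair_records(dd$design$pair[i], a, b, 60, 40)
  }))
  calls <- classify_persistence(competition_dataset(rec))
  idx <- persistence_index(calls)
  expect_true(all(idx == 7))
  expect_equal(length(idx), 8)
})

test_that("growth_persistence_correlation is exact for n = 8", {
  idx <- stats::setNames(c(7, 6, 5, 4, 3, 2, 1, 0), letters[1:8])
  growth <- stats::setNames(c(80, 70, 60, 50, 40, 30, 20, 10), letters[1:8])
  res <- growth_persistence_correlation(growth, idx)
  expect_equal(res$rho, 1)
  expect_equal(res$method, "exact permutation")
  # exact p equals enumeration of all 8! permutations: for a perfect
  # monotone pair p = 2/8! (the two strictly extreme orderings)
  expect_equal(res$p, 2 / factorial(8), tolerance = 1e-12)
  expect_error(growth_persistence_correlation(growth[1:3], idx[1:3]), "at least 4")
  expect_error(growth_persistence_correlation(unname(growth), idx), "named")
})

test_that("rank-agreement near 0.8 is recovered by the spearman machinery", {
  set.seed(63)
  rhos <- replicate(50, {
    x <- rnorm(8)
    y <- 0.85 * scale(x) + sqrt(1 - 0.85^2) * rnorm(8)
    spear <- growth_persistence_correlation(
      stats::setNames(x, letters[1:8]),
      stats::setNames(rank(y), letters[1:8]))
    spear$rho
  })
  expect_lt(abs(median(rhos) - 0.8), 0.15)
})

test_that("concordance_test reports the exact binomial tail 9/256", {
  res <- concordance_test(n_tested = 8, n_match = 7, n_draws = 2000, seed = 1)
  expect_equal(res$exact_p, 9 / 256, tolerance = 1e-12)
  expect_lt(res$mc_p, 0.05)
  # n_match = 0 -> mc_p ~ 1
  res0 <- concordance_test(n_tested = 8, n_match = 0, n_draws = 500, seed = 1)
  expect_equal(res0$mc_p, 1)
  expect_equal(res0$exact_p, 1, tolerance = 1e-12)
})

test_that("mc_p converges to the exact tail and respects the seed", {
  res <- concordance_test(n_tested = 8, n_match = 7, n_draws = 1e5, seed = 42)
  expect_lt(abs(res$mc_p - res$exact_p), 0.005)
  res_b <- concordance_test(n_tested = 8, n_match = 7, n_draws = 1e5, seed = 42)
  expect_identical(res$mc_p, res_b$mc_p)
  # without-replacement draws from the finite pool stay close for n = 8 of 16
  res_wo <- concordance_test(n_tested = 8, n_match = 7, n_draws = 2e4,
                             seed = 7, replace = FALSE)
  expect_lt(res_wo$mc_p, 0.05)
})

test_that("concordance_test wires signs to outcomes and flags missing pairs", {
  signs <- c("A|B" = "positive", "C|D" = "negative")
  outcomes <- c("A|B" = "co_persistence", "C|D" = "exclusion_of_a")
  res <- concordance_test(signs = signs, outcomes = outcomes,
                          n_draws = 200, seed = 1)
  expect_equal(res$n_match, 2)
  expect_equal(res$table$match, c(TRUE, TRUE))
  expect_error(concordance_test(signs = signs, outcomes = outcomes[1],
                                n_draws = 10),
               "C\\|D")
})

test_that("noiseless generated competitions round-trip the outcome map", {
  dd <- default_competition_design()
  data <- generate_competitions(seed = 5) # dispersion 0 -> deterministic
  calls <- classify_persistence(data)
  expect_equal(stats::setNames(calls$outcome, calls$pair)[names(dd$outcomes)],
               dd$outcomes)
  # the default design realizes 7 of 8 sign matches, significant at 0.05
  ct <- concordance_test(signs = dd$signs, outcomes = calls,
                         n_draws = 10000, seed = 9)
  expect_equal(ct$n_match, 7)
  expect_lt(ct$mc_p, 0.05)
})
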