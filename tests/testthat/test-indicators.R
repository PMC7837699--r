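test_that("indicator_r is 1 for a perfect indicator and affine-invariant", {
  g <- rep(c("in", "out"), each = 10)
  ab <- ifelse(g == "in", 0.3, 0)
  res <- indicator_r(ab, g, "in", n_perm = 199, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lte(res$p, 0.05)
  # positive affine transformation leaves r unchanged
  res2 <- indicator_r(2.5 * ab + 0.1, g, "in", n_perm = 199, seed = 1)
  expect_equal(res2$statistic, res$statistic)
  expect_equal(res2$p, res$p)
  # constant abundance -> NA with reason
  res3 <- indicator_r(rep(0.2, 20), g, "in")
  expect_true(is.na(res3$statistic))
  expect_match(res3$reason, "constant")
})

test_that("indicator_r permutation p is uniform under the null", {
  set.seed(51)
  n_rep <- 200
  ps <- vapply(seq_len(n_rep), function(i) {
    ab <- rexp(60)
    g <- sample(rep(c("a", "b"), 30))
    indicator_r(ab, g, "a", n_perm = 99)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif")) # permutation p is discrete
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(ps <= 0.05), 0.10)
})

test_that("IndVal variant lies in [0, 1] and tops out for perfect fidelity", {
  g <- rep(c("in", "out"), each = 8)
  ab <- ifelse(g == "in", 0.4, 0)
  res <- indicator_r(ab, g, "in", n_perm = 99, seed = 2, statistic = "IndVal")
  expect_equal(res$statistic, 1)
})

test_that("indicator_continuous matches a brute-force rank oracle at n = 6", {
  x <- c(0.1, 0.5, 0.2, 0.9, 0.4, 0.7)
  y <- c(2.0, 3.1, 1.0, 5.2, 2.5, 4.9)
  res <- indicator_continuous(x, y)
  expect_equal(res$rho, stats::cor(rank(x), rank(y)))
  # enumerate all 720 permutations independently
  rx <- rank(x); ry <- rank(y)
  rhos <- vapply(perm_enum(6), function(p) stats::cor(rx, ry[p]), numeric(1))
  p_oracle <- mean(abs(rhos) >= abs(res$rho) - 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  # monotone extremes
  expect_equal(indicator_continuous(1:6, (1:6)^2)$rho, 1)
  expect_equal(indicator_continuous(1:6, 7 - (1:6))$rho, -1)
  expect_error(indicator_continuous(1:3, 3:1), "at least 4")
})

test_that("indicator_screen filters on prevalence and recovers a planted shift", {
  set.seed(52)
  n <- 500
  v <- matrix(rexp(n * 6), n, 6,
              dimnames = list(paste0("s", 1:n), paste0("t", 1:6)))
  # taxon 6 rare: present in 5% of samples only
  v[, 6] <- 0
  rare_idx <- sample(n, 25)
  v[rare_idx, 6] <- 2
  grain <- sample(c("rye", "white"), n, replace = TRUE)
  # planted categorical effect on taxon 1: +2 SD in rye samples
  v[grain == "rye", 1] <- v[grain == "rye", 1] + 2 * sd(v[, 1])
  v <- v / rowSums(v)
  tab <- make_table(v, relative = TRUE)
  res <- indicator_screen(tab, data.frame(grain = grain, row.names = rownames(v)),
                          types = c(grain = "categorical"),
                          n_perm = 199, seed = 3)
  expect_false("t6" %in% res$taxon_id) # below 10% prevalence
  hit <- res[res$taxon_id == "t1", ]
  expect_equal(hit$level, "rye")
  expect_lte(hit$p_fdr, 0.05)
})

test_that("indicator_screen output is identical across runs with one seed", {
  set.seed(53)
  v <- matrix(rexp(50 * 4), 50, 4,
              dimnames = list(paste0("s", 1:50), paste0("t", 1:4)))
  v <- v / rowSums(v)
  tab <- make_table(v, relative = TRUE)
  meta <- data.frame(grp = sample(c("a", "b"), 50, replace = TRUE),
                     temp = rnorm(50), row.names = rownames(v))
  types <- c(grp = "categorical", temp = "continuous")
  r1 <- indicator_screen(tab, meta, types, n_perm = 99, seed = 11)
  r2 <- indicator_screen(tab, meta, types, n_perm = 99, seed = 11)
  expect_identical(r1, r2)
  expect_error(indicator_screen(tab, meta, c(grp = "weird")), "untyped")
  expect_error(indicator_screen(tab, meta, c(missing_var = "categorical")),
               "unknown variable")
})

test_that("no region indicator survives FDR on geographically unstructured data", {
  # k-means regions as the categorical variable on unstructured communities
  set.seed(54)
  hits <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    sv <- generate_survey(survey_spec(n_samples = 80, seed = 1000 + i))
    km <- kmeans_regions(sv$coordinates, k = 4, seed = i)
    res <- indicator_screen(sv$community,
                            data.frame(region = factor(km$labels),
                                       row.names = names(km$labels)),
                            types = c(region = "categorical"),
                            n_perm = 99, seed = i)
    if (any(res$significant, na.rm = TRUE)) hits <- hits + 1
  }
  expect_lte(hits / n_rep, 0.2)
})
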