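test_that("mantel hits rho = 1 on identical matrices and NA on constants", {
  d <- random_dist(8, seed = 31)
  m <- mantel(d, d, n_perm = 99, seed = 1)
  expect_equal(m$statistic, 1)
  expect_lte(m$p.value, 0.05)
  cm <- matrix(0.5, 8, 8) - diag(0.5, 8)
  dimnames(cm) <- dimnames(d$d)
  m2 <- mantel(d, distance_matrix(cm, "constant"))
  expect_true(is.na(m2$statistic))
  expect_match(m2$reason, "constant")
  expect_error(mantel(random_dist(3), random_dist(3)), "at least 4")
})

test_that("mantel p matches exhaustive enumeration for n = 5", {
  d1 <- random_dist(5, seed = 32)
  d2 <- random_dist(5, seed = 33)
  res <- mantel(d1, d2, n_perm = 999, seed = 1) # 5! = 120 <= 1000 -> exact
  expect_true(res$exact)
  # brute-force oracle: straight loop over an independently generated
  # permutation list
  v1 <- rank(d1$d[lower.tri(d1$d)])
  rho_obs <- NULL
  rhos <- vapply(perm_enum(5), function(p) {
    mp <- d2$d[p, p]
    stats::cor(v1, rank(mp[lower.tri(mp)]))
  }, numeric(1))
  rho_obs <- stats::cor(v1, rank(d2$d[lower.tri(d2$d)]))
  p_oracle <- mean(rhos >= rho_obs - 1e-12)
  expect_equal(res$statistic, rho_obs)
  expect_equal(res$p.value, p_oracle, tolerance = 1e-12)
})

test_that("mantel is symmetric in its arguments on the exact path", {
  d1 <- random_dist(5, seed = 34)
  d2 <- random_dist(5, seed = 35)
  expect_equal(mantel(d1, d2, n_perm = 999)$p.value,
               mantel(d2, d1, n_perm = 999)$p.value)
})

test_that("permanova equals classical one-way ANOVA on univariate data", {
  set.seed(36)
  y <- c(rnorm(10, 0), rnorm(10, 1.2), rnorm(10, 0.4))
  g <- rep(c("a", "b", "c"), each = 10)
  ids <- paste0("s", 1:30)
  d <- distance_matrix(as.matrix(stats::dist(y)), "euclidean")
  dimnames(d$d) <- list(ids, ids); d$ids <- ids
  pred <- data.frame(g = g, row.names = ids)
  res <- permanova(d, pred, n_perm = 99, seed = 1)
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  expect_equal(res$table$SS[1], an$`Sum Sq`[1], tolerance = 1e-9)
  expect_equal(res$table$F[1], an$`F value`[1], tolerance = 1e-9)
  expect_equal(res$table$R2[1], summary(fit)$r.squared, tolerance = 1e-9)
})

test_that("permanova R2 is invariant to scaling, handles degenerate terms", {
  set.seed(37)
  d <- random_dist(20, seed = 37)
  pred <- data.frame(g = sample(c("x", "y"), 20, replace = TRUE),
                     const = rep("z", 20),
                     g_copy = NA, row.names = d$ids)
  pred$g_copy <- pred$g
  r1 <- permanova(d, pred, terms = "g", n_perm = 49, seed = 1)
  d_scaled <- distance_matrix(d$d * 3.7, "scaled")
  r2 <- permanova(d_scaled, pred, terms = "g", n_perm = 49, seed = 1)
  expect_equal(r1$table$R2, r2$table$R2, tolerance = 1e-10)
  # constant predictor: zero SS, no test
  rc <- permanova(d, pred, terms = c("const", "g"), n_perm = 49, seed = 1)
  expect_equal(rc$table$SS[1], 0)
  expect_true(is.na(rc$table$p[1]))
  # collinear second term errors by name
  expect_error(permanova(d, pred, terms = c("g", "g_copy"), n_perm = 9),
               "g_copy.*collinear|collinear.*g_copy")
})

test_that("permanova drops samples with missing predictors and reports them", {
  d <- random_dist(10, seed = 38)
  pred <- data.frame(g = c(NA, rep(c("a", "b"), length.out = 9)),
                     row.names = d$ids)
  res <- permanova(d, pred, n_perm = 9, seed = 1)
  expect_equal(res$dropped_samples, "s1")
  expect_equal(res$n, 9)
})

test_that("nmds embeds metric configurations at near-zero stress", {
  set.seed(39)
  x <- matrix(rnorm(20), 10, 2)
  d <- distance_matrix(as.matrix(stats::dist(x)), "euclidean")
  fit <- nmds(d, k = 2, n_starts = 5, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_equal(unname(colMeans(fit$coordinates)), c(0, 0), tolerance = 1e-8)
  # near full-dimensional embedding drives stress to ~0
  d6 <- random_dist(6, seed = 40)
  fit6 <- nmds(d6, k = 5, n_starts = 5, seed = 1)
  expect_lt(fit6$stress, 0.02)
  # determinism given seed
  fit_b <- nmds(d, k = 2, n_starts = 5, seed = 1)
  expect_identical(fit$coordinates, fit_b$coordinates)
})

test_that("kruskal_dunn matches the chi-square KW and Mann-Whitney z", {
  set.seed(41)
  v <- c(rnorm(12), rnorm(12, 1))
  g <- rep(c("a", "b"), each = 12)
  res <- kruskal_dunn(v, g, min_group_n = 5)
  ref <- stats::kruskal.test(v, factor(g))
  expect_equal(res$H, unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value)
  # two-group KW p equals the two-sided normal-approximation Mann-Whitney p
  r <- rank(v)
  U_z <- (sum(r[g == "a"]) - 12 * 25 / 2) / sqrt(12 * 12 * 25 / 12)
  expect_equal(res$p.value, 2 * stats::pnorm(-abs(U_z)), tolerance = 1e-9)
  # all equal values -> H = 0
  res0 <- kruskal_dunn(rep(1, 20), rep(c("a", "b"), 10), min_group_n = 5)
  expect_equal(res0$H, 0)
})

test_that("kruskal_dunn drops small groups and needs two eligible ones", {
  v <- c(rnorm(10), rnorm(10, 1), rnorm(2, 5))
  g <- c(rep("a", 10), rep("b", 10), rep("tiny", 2))
  res <- kruskal_dunn(v, g, min_group_n = 5)
  expect_equal(res$groups_dropped, "tiny")
  expect_equal(nrow(res$dunn), 1)
  expect_error(kruskal_dunn(rnorm(6), c(rep("a", 4), "b", "c"), min_group_n = 4),
               "fewer than 2 groups")
})
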