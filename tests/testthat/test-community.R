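test_that("to_relative_abundance normalizes rows and is idempotent", {
  tab <- make_table(rbind(c(2, 2), c(1260, 0)))
  rel <- to_relative_abundance(tab)
  expect_equal(unname(rel$values[1, ]), c(0.5, 0.5))
  expect_equal(unname(rel$values[2, ]), c(1, 0))
  expect_equal(to_relative_abundance(rel)$values, rel$values)
  expect_error(to_relative_abundance(make_table(rbind(c(1, 1), c(0, 0)))),
               "all-zero")
})

test_that("rarefy preserves full rows at exact depth and single-taxon rows", {
  tab <- make_table(rbind(c(3, 7), c(10, 0)))
  out <- rarefy(tab, depth = 10, seed = 1)
  expect_equal(unname(out$values["s1", ]), c(3, 7))
  expect_equal(unname(out$values["s2", ]), c(10, 0))
  out5 <- rarefy(make_table(rbind(c(10, 0))), depth = 5, seed = 1)
  expect_equal(unname(out5$values[1, ]), c(5, 0))
})

test_that("rarefy errors on non-integer values and drops shallow samples", {
  expect_error(rarefy(make_table(rbind(c(1.5, 2))), 2),
               "non-integer count 1.5.*s1.*t1")
  tab <- make_table(rbind(c(100, 100), c(2, 1)))
  expect_warning(out <- rarefy(tab, 50, seed = 1), "s2")
  expect_equal(rownames(out$values), "s1")
  expect_equal(attr(out, "dropped_samples"), "s2")
})

test_that("rarefy is seed-reproducible and unbiased in expectation", {
  tab <- make_table(rbind(c(30, 70, 0, 50)))
  a <- rarefy(tab, 40, seed = 7)
  b <- rarefy(tab, 40, seed = 7)
  expect_identical(a$values, b$values)
  expect_equal(sum(a$values), 40)
  # expected post-rarefaction proportion equals pre-rarefaction proportion
  set.seed(42)
  draws <- replicate(1000, rarefy(tab, 40)$values[1, 1] / 40)
  se <- stats::sd(draws) / sqrt(1000)
  expect_lt(abs(mean(draws) - 30 / 150), 3 * se)
})

test_that("bray_curtis matches hand values and the min-sum identity", {
  tab <- make_table(rbind(c(0.7, 0.3), c(0.3, 0.7), c(1, 0), c(0, 1),
                          c(0.7, 0.3)))
  d <- bray_curtis(tab)
  expect_equal(d$d[1, 2], 0.4)
  expect_equal(d$d[3, 4], 1)
  expect_equal(d$d[1, 5], 0)
  expect_equal(d$d, t(d$d))
  # algebraic identity on random relative rows
  set.seed(3)
  v <- matrix(rexp(60), 10)
  v <- v / rowSums(v)
  dd <- bray_curtis(make_table(v))$d
  for (i in 1:9) for (j in (i + 1):10) {
    ident <- 1 - 2 * sum(pmin(v[i, ], v[j, ])) / sum(v[i, ] + v[j, ])
    expect_equal(dd[i, j], ident)
  }
  expect_error(bray_curtis(make_table(rbind(c(0, 0), c(1, 1)))), "all-zero")
})

test_that("combine_kingdoms renormalizes blocks to their weights", {
  bact <- make_table(matrix(c(1, 0), 1, dimnames = list("s1", c("b1", "b2"))),
                     groups = c("LAB", "LAB"))
  fung <- make_table(matrix(1, 1, dimnames = list("s1", "y1")),
                     groups = "yeast", kingdoms = "fungi")
  out <- combine_kingdoms(bact, fung)
  expect_equal(unname(out$values[1, ]), c(0.5, 0, 0.5))
  only_b <- combine_kingdoms(bact, fung, weights = c(1, 0))
  expect_equal(colnames(only_b$values), c("b1", "b2"))
  expect_equal(sum(only_b$values), 1)
})

test_that("combine_kingdoms row sums are 1 for random blocks and ids must match", {
  set.seed(5)
  b <- make_table(matrix(rexp(20), 5, dimnames = list(paste0("s", 1:5), paste0("b", 1:4))))
  f <- make_table(matrix(rexp(15), 5, dimnames = list(paste0("s", 1:5), paste0("y", 1:3))),
                  groups = rep("yeast", 3), kingdoms = rep("fungi", 3))
  out <- combine_kingdoms(b, f)
  expect_equal(unname(rowSums(out$values)), rep(1, 5))
  f_bad <- make_table(matrix(rexp(15), 5, dimnames = list(paste0("x", 1:5), paste0("y", 1:3))),
                      groups = rep("yeast", 3), kingdoms = rep("fungi", 3))
  expect_error(combine_kingdoms(b, f_bad), "present in one table only")
})

test_that("combine_kingdoms then bray_curtis is invariant to taxon order", {
  set.seed(6)
  b <- make_table(matrix(rexp(20), 5, dimnames = list(paste0("s", 1:5), paste0("b", 1:4))))
  f <- make_table(matrix(rexp(15), 5, dimnames = list(paste0("s", 1:5), paste0("y", 1:3))),
                  groups = rep("yeast", 3), kingdoms = rep("fungi", 3))
  d1 <- bray_curtis(combine_kingdoms(b, f))
  b_shuf <- subset_community(b, taxa = c("b3", "b1", "b4", "b2"))
  d2 <- bray_curtis(combine_kingdoms(b_shuf, f))
  expect_equal(d1$d, d2$d)
})

test_that("hierarchical_cluster reproduces Ward.D2 heights", {
  # two samples: single merge at their distance
  d2 <- distance_matrix(matrix(c(0, 0.4, 0.4, 0), 2,
                               dimnames = list(c("a", "b"), c("a", "b"))), "m")
  hc2 <- hierarchical_cluster(d2)
  expect_equal(hc2$height, 0.4)
  # three equidistant points: first merge is the lowest index pair
  m3 <- matrix(0.5, 3, 3); diag(m3) <- 0
  dimnames(m3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  hc3 <- hierarchical_cluster(distance_matrix(m3, "m"))
  expect_equal(sort(hc3$merge[1, ]), c(-2, -1))
  # agreement with the naive O(n^3) oracle on random matrices
  for (seed in 1:5) {
    d <- random_dist(10, seed = seed)
    hc <- hierarchical_cluster(d)
    oracle <- ward_d2_oracle(d$d)
    expect_equal(sort(hc$height), oracle$heights, tolerance = 1e-10)
    coph <- as.matrix(stats::cophenetic(hc$hclust))
    expect_equal(unname(coph[d$ids, d$ids]), unname(oracle$cophenetic),
                 tolerance = 1e-10)
  }
  expect_error(hierarchical_cluster(distance_matrix(matrix(0, 1, 1, dimnames = list("a", "a")), "m")),
               "at least 2")
})
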