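test_that("generators are bit-reproducible given a seed", {
  a <- generate_survey(survey_spec(n_samples = 30, seed = 101))
  b <- generate_survey(survey_spec(n_samples = 30, seed = 101))
  expect_identical(a$community$values, b$community$values)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$coordinates, b$coordinates)
  c1 <- generate_competitions(seed = 11, dispersion = 0.05)
  c2 <- generate_competitions(seed = 11, dispersion = 0.05)
  expect_identical(c1$records, c2$records)
})

test_that("generated relative abundances are proper compositions", {
  sv <- generate_survey(survey_spec(n_samples = 50, seed = 102))
  expect_equal(unname(rowSums(sv$community$values)), rep(1, 50), tolerance = 1e-9)
  expect_true(all(sv$community$values >= 0))
  # count mode produces integer tables usable by rarefy
  svc <- generate_survey(survey_spec(n_samples = 10, seed = 103),
                         as_counts = TRUE, depth = 2000)
  expect_true(all(rowSums(svc$counts$values) == 2000))
  rar <- rarefy(svc$counts, 1000, seed = 1)
  expect_true(all(rowSums(rar$values) == 1000))
})

test_that("AAB prevalence lands near the specified fraction", {
  sv <- generate_survey(survey_spec(n_samples = 500, seed = 104))
  inc <- presence_absence(sv$community)
  aab_taxa <- sv$community$annotations$taxon_id[sv$community$annotations$group == "AAB"]
  frac <- mean(rowSums(inc$presence[, aab_taxa]) > 0)
  expect_lt(abs(frac - 0.294), 3 * sqrt(0.294 * 0.706 / 500) + 0.02)
})

test_that("planted pairs drive co-occurrence signs; zero strength is null", {
  sv <- generate_survey(survey_spec(n_samples = 300, seed = 105))
  res <- cooccur_analysis(presence_absence(sv$community))
  sig <- significant_signs(res)
  expect_equal(unname(sig["Lactobacillus_brevis|Lactobacillus_plantarum"]), "positive")
  expect_equal(unname(sig["Lactobacillus_plantarum|Lactobacillus_sanfranciscensis"]), "negative")
  # zero-strength planted pairs: incidence of the pair is independent
  set.seed(106)
  chisq_p <- replicate(30, {
    spec0 <- survey_spec(n_samples = 150,
                         planted_pairs = list(
                           list(a = "Lactobacillus_plantarum",
                                b = "Lactobacillus_brevis",
                                sign = "positive", strength = 0)),
                         seed = sample.int(1e6, 1))
    inc <- presence_absence(generate_survey(spec0)$community)
    suppressWarnings(stats::chisq.test(
      table(inc$presence[, "Lactobacillus_plantarum"],
            inc$presence[, "Lactobacillus_brevis"]))$p.value)
  })
  expect_lte(mean(chisq_p < 0.05), 0.2)
})

test_that("competition generator emits the full factorial design", {
  data <- generate_competitions(seed = 1)
  r <- data$records
  expect_equal(length(unique(r$pair)), 28)
  expect_equal(sort(unique(r$transfer)), c(1, 3, 6))
  expect_equal(length(unique(r$replicate)), 5)
  # noisy CFUs still classify to the prescription most of the time
  noisy <- generate_competitions(seed = 2, dispersion = 0.02)
  calls <- classify_persistence(noisy)
  dd <- default_competition_design()
  agree <- mean(stats::setNames(calls$outcome, calls$pair)[names(dd$outcomes)] ==
                  dd$outcomes)
  expect_gte(agree, 0.9)
  expect_error(generate_competitions(winners = c("A|B" = "co_persistence"),
                                     limit = 0.45),
               "conflicts with the detection limit")
})

test_that("decay geography plants a detectable distance-decay signal", {
  spec <- survey_spec(n_samples = 100, geography = "decay", seed = 107)
  sv <- generate_survey(spec)
  comm_d <- bray_curtis(sv$community)
  geo_d <- haversine_matrix(sv$coordinates)
  res <- distance_decay(comm_d, geo_d, n_perm = 199, seed = 1)
  expect_gt(res$statistic, 0.05)
  expect_lte(res$p.value, 0.05)
})

test_that("functional generator couples rise, VOC and sensory to %AAB", {
  sv <- generate_survey(survey_spec(n_samples = 40, seed = 108))
  fx <- generate_function(function_spec(n_starters = 40, seed = 109,
                                        times = seq(0, 36, 2)), sv$community)
  expect_equal(length(fx$rise_rates), 40)
  expect_true(all(fx$rise_rates >= 0.1 & fx$rise_rates <= 1.5))
  # rise rates decline with %AAB by construction
  expect_lt(cor(fx$pct_aab, fx$rise_rates, method = "spearman"), 0)
  # blank-matched compounds are fully removed by the background filter
  filtered <- background_filter(fx$voc, fx$blanks)
  expect_false(any(grepl("^background_", colnames(filtered$values))))
  expect_true(all(grepl("^compound_", colnames(filtered$values))))
  # vinegar notes concentrate in high-AAB samples
  if (sum(fx$sensory == "vinegar") >= 3) {
    expect_gt(mean(fx$pct_aab[fx$sensory == "vinegar"]),
              mean(fx$pct_aab[fx$sensory != "vinegar"]))
  }
})
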