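#' Binarize a relative-abundance table at a within-sample threshold
#'
#' A taxon is scored present in a sample when its relative abundance is
#' strictly above `threshold` (default 1%, the conventional within-sample
#' detection cutoff for fermented-food amplicon data).
#'
#' @param table relative-abundance [community_table()].
#' @param threshold fraction in `[0, 1)`; presence requires abundance
#'   strictly greater than this value.
#' @return object of class `incidence_matrix`: binary sample-by-taxon matrix
#'   plus the threshold used.
#' @export
presence_absence <- function(table, threshold = 0.01) {
  stopifnot(inherits(table, "community_table"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 1) {
    stop("threshold must be a single fraction in [0, 1)")
  }
  presence <- (table$values > threshold) * 1L
  structure(list(presence = presence, threshold = threshold,
                 sample_ids = rownames(presence), taxon_ids = colnames(presence)),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("incidence_matrix: %d samples x %d taxa, threshold %g\n",
              nrow(x$presence), ncol(x$presence), x$threshold))
  invisible(x)
}

#' Exact distribution of the joint-occurrence count of two taxa
#'
#' Under the null that the `N1` occurrences of taxon A and the `N2`
#' occurrences of taxon B are placed independently and uniformly among `N`
#' samples, the number of joint occurrences J is hypergeometric:
#' `P(J = j) = C(N1, j) C(N - N1, N2 - j) / C(N, N2)` on the support
#' `max(0, N1 + N2 - N) <= j <= min(N1, N2)`. Probabilities are evaluated in
#' log space for numerical safety.
#'
#' @param N number of samples; `N1`, `N2` incidences of the two taxa.
#' @return numeric vector of probabilities for `j = 0, ..., min(N1, N2)`
#'   (zero outside the support), named by `j`.
#' @export
pair_distribution <- function(N, N1, N2) {
  N <- as.integer(N); N1 <- as.integer(N1); N2 <- as.integer(N2)
  if (N < 1) stop("N must be >= 1")
  if (N1 < 0 || N1 > N || N2 < 0 || N2 > N) {
    stop("N1 and N2 must lie in [0, N]")
  }
  j <- 0:min(N1, N2)
  logp <- lchoose(N1, j) + lchoose(N - N1, N2 - j) - lchoose(N, N2)
  p <- exp(logp)
  p[j < max(0L, N1 + N2 - N)] <- 0
  names(p) <- j
  p
}

#' Probabilistic pairwise co-occurrence analysis
#'
#' For every taxon pair, compares the observed number of joint occurrences
#' with its exact hypergeometric null distribution ([pair_distribution()]),
#' classifying pairs as `positive` (co-occurring more than expected),
#' `negative` (less than expected) or `random`. Pairs whose expected joint
#' count `N1*N2/N` does not exceed `min_expected` are excluded before
#' multiple-testing correction, and Bonferroni correction uses the number of
#' pairs that pass the filter.
#'
#' Both tail probabilities include the observed value:
#' `p_lt = P(J <= j_obs)` and `p_gt = P(J >= j_obs)`.
#'
#' @param inc an [presence_absence()] incidence matrix.
#' @param alpha familywise significance level applied to Bonferroni-corrected
#'   p-values (default 0.05).
#' @param min_expected pairs with expected joint count `<= min_expected`
#'   (default 1, i.e. "predicted to co-occur more than once") are filtered.
#' @return data.frame of class `cooccurrence_result` with one row per pair:
#'   `taxon_a`, `taxon_b`, `N`, `N1`, `N2`, `j_obs`, `expected`, `p_lt`,
#'   `p_gt`, `p_raw`, `p_bonferroni`, `sign`, `passed_expected_filter`.
#'   Filtered pairs keep their raw quantities but have `NA` corrected
#'   p-values and `NA` sign.
#' @export
cooccur_analysis <- function(inc, alpha = 0.05, min_expected = 1) {
  stopifnot(inherits(inc, "incidence_matrix"))
  pres <- inc$presence
  taxa <- colnames(pres)
  if (length(taxa) < 2) stop("need at least 2 taxa")
  N <- nrow(pres)
  inc_counts <- colSums(pres)
  joint <- crossprod(pres) # taxon x taxon joint occurrence counts
  pairs <- utils::combn(seq_along(taxa), 2)
  # canonical pair orientation: taxon_a < taxon_b lexicographically
  flip <- taxa[pairs[1, ]] > taxa[pairs[2, ]]
  first <- ifelse(flip, pairs[2, ], pairs[1, ])
  second <- ifelse(flip, pairs[1, ], pairs[2, ])
  res <- data.frame(
    taxon_a = taxa[first],
    taxon_b = taxa[second],
    N = N,
    N1 = inc_counts[first],
    N2 = inc_counts[second],
    j_obs = joint[cbind(first, second)],
    stringsAsFactors = FALSE
  )
  res$expected <- res$N1 * res$N2 / N
  tails <- mapply(function(N1, N2, j_obs) {
    p <- pair_distribution(N, N1, N2)
    j <- as.integer(names(p))
    c(p_lt = sum(p[j <= j_obs]), p_gt = sum(p[j >= j_obs]))
  }, res$N1, res$N2, res$j_obs)
  res$p_lt <- pmin(1, tails["p_lt", ])
  res$p_gt <- pmin(1, tails["p_gt", ])
  res$p_raw <- pmin(res$p_lt, res$p_gt)
  res$passed_expected_filter <- res$expected > min_expected
  m <- sum(res$passed_expected_filter)
  res$p_bonferroni <- ifelse(res$passed_expected_filter,
                             pmin(1, m * res$p_raw), NA_real_)
  sig <- !is.na(res$p_bonferroni) & res$p_bonferroni <= alpha
  res$sign <- ifelse(!res$passed_expected_filter, NA_character_,
                     ifelse(!sig, "random",
                            ifelse(res$p_gt < res$p_lt, "positive", "negative")))
  res <- res[order(res$taxon_a, res$taxon_b), ]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "min_expected") <- min_expected
  attr(res, "n_tested") <- m
  class(res) <- c("cooccurrence_result", "data.frame")
  res
}

#' Extract significant co-occurrence signs as a named vector
#'
#' Convenience accessor used when feeding co-occurrence calls into the
#' in-vitro concordance test: returns `"positive"`/`"negative"` for
#' significant pairs, named `"taxonA|taxonB"`.
#'
#' @param result a [cooccur_analysis()] result.
#' @return named character vector of signs for significant pairs.
#' @export
significant_signs <- function(result) {
  stopifnot(inherits(result, "cooccurrence_result"))
  sig <- !is.na(result$sign) & result$sign %in% c("positive", "negative")
  stats::setNames(result$sign[sig], paste(result$taxon_a[sig], result$taxon_b[sig],
                                          sep = "|"))
}
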