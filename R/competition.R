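#' Construct a serial-transfer competition dataset
#'
#' Long-format CFU records from pairwise competition assays: every species
#' pair is grown together, serially transferred, and plated at a set of
#' focal transfers (conventionally transfers 1, 3 and 6).
#'
#' @param records data.frame with columns `pair`, `species_a`, `species_b`,
#'   `replicate`, `transfer`, `species`, `cfu`. Every
#'   pair x replicate x transfer must carry a CFU count for both species of
#'   the pair.
#' @param species_kingdoms optional named character vector mapping species
#'   to kingdoms (used for within/cross-kingdom pair accounting).
#' @return object of class `competition_dataset`.
#' @export
competition_dataset <- function(records, species_kingdoms = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("pair", "species_a", "species_b", "replicate", "transfer",
                "species", "cfu")
  miss <- setdiff(required, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$cfu)) || any(records$cfu < 0)) {
    stop("cfu must be finite and non-negative")
  }
  bad <- records$species != records$species_a & records$species != records$species_b
  if (any(bad)) {
    stop("records where `species` is neither species_a nor species_b: rows ",
         paste(utils::head(which(bad)), collapse = ", "))
  }
  key <- interaction(records$pair, records$replicate, records$transfer, drop = TRUE)
  counts <- tapply(records$species, key, function(s) length(unique(s)))
  incomplete <- names(counts)[counts != 2]
  if (length(incomplete)) {
    stop("pair x replicate x transfer without both species measured: ",
         paste(utils::head(incomplete), collapse = ", "))
  }
  structure(list(records = records, species_kingdoms = species_kingdoms),
            class = "competition_dataset")
}

#' @export
print.competition_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("competition_dataset: %d pairs, %d replicates, transfers {%s}\n",
              length(unique(r$pair)), length(unique(r$replicate)),
              paste(sort(unique(r$transfer)), collapse = ", ")))
  invisible(x)
}

#' Enumerate the pairs of a fully factorial pairwise design
#'
#' @param species character vector of species names.
#' @param kingdoms optional named character vector of kingdoms; when given,
#'   each pair is labelled within- or cross-kingdom.
#' @return data.frame with `pair`, `species_a`, `species_b` and (optionally)
#'   `pair_type`. An `n`-species design yields `choose(n, 2)` pairs.
#' @export
pairwise_design <- function(species, kingdoms = NULL) {
  cmb <- utils::combn(species, 2)
  out <- data.frame(pair = paste(cmb[1, ], cmb[2, ], sep = "|"),
                    species_a = cmb[1, ], species_b = cmb[2, ],
                    stringsAsFactors = FALSE)
  if (!is.null(kingdoms)) {
    out$pair_type <- ifelse(kingdoms[out$species_a] == kingdoms[out$species_b],
                            "within_kingdom", "cross_kingdom")
  }
  out
}

#' Per-record relative abundances within a competed pair
#'
#' @param data a [competition_dataset()].
#' @return data.frame with columns `pair`, `replicate`, `transfer`,
#'   `species`, `cfu`, `fraction` (CFU of the species over the summed CFU of
#'   the pair) and `undefined` (both species at zero CFU; fraction is `NA`).
#' @export
relative_abundances <- function(data) {
  stopifnot(inherits(data, "competition_dataset"))
  r <- data$records
  key <- interaction(r$pair, r$replicate, r$transfer, drop = TRUE)
  totals <- as.numeric(tapply(r$cfu, key, sum)[key])
  r$fraction <- ifelse(totals > 0, r$cfu / totals, NA_real_)
  r$undefined <- totals == 0
  if (any(r$undefined)) {
    warning("pair x replicate x transfer with zero total CFU; fractions NA")
  }
  r[, c("pair", "species_a", "species_b", "replicate", "transfer",
        "species", "cfu", "fraction", "undefined")]
}

#' Classify persistence outcomes at a focal transfer
#'
#' A species persisted in a competition when its mean relative abundance
#' across replicates at the focal transfer is strictly above the detection
#' limit (default 1%, transfer 6). Both persisted: co-persistence; one:
#' exclusion of the other; neither: mutual collapse.
#'
#' @param data a [competition_dataset()].
#' @param limit detection limit on the mean relative abundance
#'   (default 0.01, strict `>`).
#' @param transfer focal transfer (default 6).
#' @return data.frame of class `persistence_calls`: `pair`, `species_a`,
#'   `species_b`, `mean_frac_a`, `mean_frac_b`, `persisted_a`,
#'   `persisted_b`, `outcome` in
#'   `{co_persistence, exclusion_of_a, exclusion_of_b, mutual_collapse}`.
#' @export
classify_persistence <- function(data, limit = 0.01, transfer = 6) {
  stopifnot(inherits(data, "competition_dataset"))
  fr <- relative_abundances(data)
  fr <- fr[fr$transfer == transfer, ]
  if (!nrow(fr)) stop("no records at transfer ", transfer)
  pairs <- unique(fr[, c("pair", "species_a", "species_b")])
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    sub <- fr[fr$pair == p$pair, ]
    if (length(unique(sub$replicate)) < 1) stop("pair with no replicate: ", p$pair)
    mean_a <- mean(sub$fraction[sub$species == p$species_a], na.rm = TRUE)
    mean_b <- mean(sub$fraction[sub$species == p$species_b], na.rm = TRUE)
    pa <- is.finite(mean_a) && mean_a > limit
    pb <- is.finite(mean_b) && mean_b > limit
    outcome <- if (pa && pb) "co_persistence"
               else if (pa) "exclusion_of_b"
               else if (pb) "exclusion_of_a"
               else "mutual_collapse"
    data.frame(pair = p$pair, species_a = p$species_a, species_b = p$species_b,
               mean_frac_a = mean_a, mean_frac_b = mean_b,
               persisted_a = pa, persisted_b = pb, outcome = outcome,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$pair), ]
  rownames(out) <- NULL
  attr(out, "limit") <- limit
  attr(out, "transfer") <- transfer
  class(out) <- c("persistence_calls", "data.frame")
  out
}

#' Persistence index: number of competitions each species survived
#'
#' @param calls a [classify_persistence()] result.
#' @return named integer vector; for an `n`-species full pairwise design the
#'   index lies in `[0, n - 1]`.
#' @export
persistence_index <- function(calls) {
  stopifnot(inherits(calls, "persistence_calls"))
  species <- sort(unique(c(calls$species_a, calls$species_b)))
  idx <- vapply(species, function(s) {
    sum(calls$persisted_a[calls$species_a == s]) +
      sum(calls$persisted_b[calls$species_b == s])
  }, numeric(1))
  stats::setNames(as.integer(idx), species)
}

#' Correlate individual growth with the persistence index
#'
#' Spearman rank correlation (exact permutation p for `n <= 9`) between
#' per-species growth alone (e.g. CFU after the final transfer in
#' monoculture) and the persistence index from pairwise competitions.
#'
#' @param growth named numeric vector of monoculture growth per species.
#' @param index named integer vector from [persistence_index()].
#' @return list with `rho`, `p`, `method`.
#' @export
growth_persistence_correlation <- function(growth, index) {
  if (is.null(names(growth)) || is.null(names(index))) {
    stop("growth and index must be named by species")
  }
  if (!setequal(names(growth), names(index))) {
    stop("species sets differ between growth and index")
  }
  if (length(growth) < 4) stop("need at least 4 species")
  spearman_test(as.numeric(growth[names(index)]), as.numeric(index))
}

#' Monte-Carlo concordance test of co-occurrence signs vs competition outcomes
#'
#' Asks whether the agreement between in-situ co-occurrence signs
#' (positive/negative) and in-vitro persistence outcomes could arise by
#' chance. The null mirrors the empirical sign pool: each tested pair's
#' sign is drawn from a pool of `pool["positive"] + pool["negative"]` signs
#' (default 8 of 16 positive, i.e. `P(positive) = 0.5`), and a drawn sign
#' matches when it agrees with the pair's experimental outcome (positive
#' matches co-persistence; negative matches any non-co-persistence
#' outcome). `mc_p` is the fraction of `n_draws` draws achieving at least
#' the observed number of matches; the closed-form tail probability
#' (`exact_p`, Poisson-binomial, reducing to the binomial tail
#' `sum_{i>=n_match} C(n,i) 0.5^n` when `P(positive) = 0.5`) is reported as
#' a cross-check.
#'
#' Either supply `signs` and `outcomes` (named by pair), or supply
#' `n_tested`/`n_match` directly (in which case the per-pair table is
#' omitted and the outcomes are taken as balanced).
#'
#' @param signs named character vector (`"positive"`/`"negative"`) of
#'   significant co-occurrence signs per tested pair.
#' @param outcomes a [classify_persistence()] result or a named character
#'   vector of outcomes covering every pair in `signs`.
#' @param n_tested,n_match alternative direct interface.
#' @param n_draws Monte-Carlo draws (default 10000).
#' @param seed RNG seed.
#' @param pool named counts of positive/negative signs in the null pool
#'   (default `c(positive = 8, negative = 8)`).
#' @param replace draw signs with replacement (i.i.d., default) or without
#'   replacement from the finite pool.
#' @return object of class `concordance_report`: `n_tested`, `n_match`,
#'   `mc_p`, `exact_p`, `mc_se`, `n_draws`, `pool`, and the per-pair
#'   `table` when signs/outcomes were supplied.
#' @export
concordance_test <- function(signs = NULL, outcomes = NULL,
                             n_tested = NULL, n_match = NULL,
                             n_draws = 10000, seed = NULL,
                             pool = c(positive = 8, negative = 8),
                             replace = TRUE) {
  if (!all(c("positive", "negative") %in% names(pool))) {
    stop("pool must have named counts `positive` and `negative`")
  }
  tab <- NULL
  if (!is.null(signs)) {
    if (inherits(outcomes, "persistence_calls")) {
      outcomes <- stats::setNames(outcomes$outcome, outcomes$pair)
    }
    if (is.null(names(signs)) || is.null(names(outcomes))) {
      stop("signs and outcomes must be named by pair")
    }
    missing <- setdiff(names(signs), names(outcomes))
    if (length(missing)) {
      stop("pairs without an experimental outcome: ",
           paste(missing, collapse = ", "))
    }
    bad <- setdiff(unique(signs), c("positive", "negative"))
    if (length(bad)) stop("signs must be positive/negative, got: ",
                          paste(bad, collapse = ", "))
    outcome_sign <- ifelse(outcomes[names(signs)] == "co_persistence",
                           "positive", "negative")
    match_vec <- signs == outcome_sign
    tab <- data.frame(pair = names(signs), sign = unname(signs),
                      outcome = unname(outcomes[names(signs)]),
                      match = unname(match_vec), stringsAsFactors = FALSE)
    n_tested <- length(signs)
    n_match <- sum(match_vec)
    outcome_signs <- unname(outcome_sign)
  } else {
    if (is.null(n_tested) || is.null(n_match)) {
      stop("supply either signs+outcomes or n_tested+n_match")
    }
    # balanced outcome signs; with a symmetric pool only the count matters
    outcome_signs <- rep(c("positive", "negative"), length.out = n_tested)
  }
  if (n_match > n_tested) stop("n_match cannot exceed n_tested")
  p_pos <- pool[["positive"]] / sum(pool)
  pool_vec <- rep(c("positive", "negative"), times = c(pool[["positive"]],
                                                       pool[["negative"]]))
  matches <- seeded(seed, {
    vapply(seq_len(n_draws), function(i) {
      drawn <- if (replace) {
        sample(c("positive", "negative"), n_tested, replace = TRUE,
               prob = c(p_pos, 1 - p_pos))
      } else {
        sample(pool_vec, n_tested, replace = FALSE)
      }
      sum(drawn == outcome_signs)
    }, numeric(1))
  })
  mc_p <- mean(matches >= n_match)
  mc_se <- sqrt(mc_p * (1 - mc_p) / n_draws)
  # Poisson-binomial tail: per-pair match probability is p_pos for pairs
  # whose outcome reads positive, 1 - p_pos otherwise (all 0.5 when the
  # pool is balanced)
  p_match <- ifelse(outcome_signs == "positive", p_pos, 1 - p_pos)
  dist <- c(1)
  for (pm in p_match) dist <- c(dist * (1 - pm), 0) + c(0, dist * pm)
  exact_p <- sum(dist[(n_match + 1):(n_tested + 1)])
  structure(list(n_tested = n_tested, n_match = n_match, mc_p = mc_p,
                 exact_p = exact_p, mc_se = mc_se, n_draws = n_draws,
                 pool = pool, replace = replace, seed = seed, table = tab),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: %d of %d signs matched experimental outcomes\n",
              x$n_match, x$n_tested))
  cat(sprintf("  Monte-Carlo p = %.4f (%d draws, SE %.4f); exact tail p = %.4f\n",
              x$mc_p, x$n_draws, x$mc_se, x$exact_p))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}
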