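#' Default taxon roster for the synthetic survey
#'
#' Focal fermentation taxa of a sourdough survey: dominant and secondary
#' yeasts, widespread LAB, and three acetic-acid-bacteria species groups,
#' plus two environmental "other" taxa. `base_prevalence` is the marginal
#' presence probability (>1% within-sample abundance) and
#' `dominance_weight` the Dirichlet weight a taxon receives when chosen as
#' the sample's dominant member.
#'
#' @return data.frame with columns `taxon_id`, `kingdom`, `group`,
#'   `base_prevalence`, `dominance_weight`.
#' @export
default_roster <- function() {
  data.frame(
    taxon_id = c("Saccharomyces_cerevisiae", "Kazachstania_humilis",
                 "Kazachstania_servazzii", "Wickerhamomyces_anomalus",
                 "Lactobacillus_sanfranciscensis", "Lactobacillus_plantarum",
                 "Lactobacillus_brevis", "Pediococcus_parvulus",
                 "Pediococcus_damnosus",
                 "Acetobacter_malorum_grp", "Acetobacter_lovaniensis_grp",
                 "Gluconobacter_frateurii_grp",
                 "Cladosporium_sp", "Pantoea_sp"),
    kingdom = c("fungi", "fungi", "fungi", "fungi",
                "bacteria", "bacteria", "bacteria", "bacteria", "bacteria",
                "bacteria", "bacteria", "bacteria",
                "fungi", "bacteria"),
    group = c("yeast", "yeast", "yeast", "yeast",
              "LAB", "LAB", "LAB", "LAB", "LAB",
              "AAB", "AAB", "AAB",
              "other", "other"),
    base_prevalence = c(0.77, 0.25, 0.15, 0.12,
                        0.45, 0.40, 0.38, 0.18, 0.15,
                        NA, NA, NA, # AAB handled by aab_prevalence
                        0.30, 0.20),
    dominance_weight = c(15, 12, 10, 8,
                         15, 12, 12, 8, 8,
                         8, 8, 8,
                         2, 2),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic community survey
#'
#' The stated world the generator emulates: single-species dominance,
#' planted positive/negative co-occurrence pairs, roughly 29% of samples
#' containing acetic acid bacteria above the 1% detection threshold
#' (147/500 in a 500-starter survey), geographically unstructured
#' composition by default, and metadata with planted indicator effects.
#'
#' @param n_samples number of samples (default 500).
#' @param roster taxon roster, see [default_roster()].
#' @param planted_pairs list of `list(a=, b=, sign=, strength=)` entries;
#'   `sign` is `"positive"` (co-presence) or `"negative"` (mutual
#'   exclusion), `strength` in `[0, 1]` the probability the constraint is
#'   enforced in a sample. Default: one strong positive LAB pair
#'   (*L. plantarum* with *L. brevis*) and one strong negative pair
#'   (*L. sanfranciscensis* against *L. plantarum*).
#' @param aab_prevalence fraction of samples containing AAB above threshold
#'   (default 0.294).
#' @param geography `"unstructured"` (default) or `"decay"`.
#' @param decay_rate strength of the planted distance-decay when
#'   `geography = "decay"` (default 1 gives a clearly detectable signal).
#' @param indicator_effects list of
#'   `list(taxon=, variable=, level=, multiplier=)` entries boosting a
#'   taxon's abundance weight in one metadata category. Default: one
#'   planted indicator (*L. plantarum* enriched under a rye grain base).
#' @param dirichlet_conc concentration of the within-sample Dirichlet
#'   (default 1).
#' @param seed RNG seed.
#' @return object of class `survey_spec`.
#' @export
survey_spec <- function(n_samples = 500, roster = default_roster(),
                        planted_pairs = list(
                          list(a = "Lactobacillus_plantarum",
                               b = "Lactobacillus_brevis",
                               sign = "positive", strength = 0.9),
                          list(a = "Lactobacillus_sanfranciscensis",
                               b = "Lactobacillus_plantarum",
                               sign = "negative", strength = 0.9)),
                        aab_prevalence = 0.294,
                        geography = c("unstructured", "decay"),
                        decay_rate = 1,
                        indicator_effects = list(
                          list(taxon = "Lactobacillus_plantarum",
                               variable = "grain_base", level = "rye",
                               multiplier = 3)),
                        dirichlet_conc = 1, seed = NULL) {
  geography <- match.arg(geography)
  assert_prob(aab_prevalence, "aab_prevalence")
  for (pp in planted_pairs) {
    if (!all(c(pp$a, pp$b) %in% roster$taxon_id)) {
      stop("planted pair references taxa missing from the roster")
    }
    if (!pp$sign %in% c("positive", "negative")) stop("pair sign must be positive/negative")
    assert_prob(pp$strength, "pair strength")
  }
  structure(list(n_samples = n_samples, roster = roster,
                 planted_pairs = planted_pairs,
                 aab_prevalence = aab_prevalence, geography = geography,
                 decay_rate = decay_rate,
                 indicator_effects = indicator_effects,
                 dirichlet_conc = dirichlet_conc, seed = seed),
            class = "survey_spec")
}

rdirichlet_one <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate a synthetic community survey
#'
#' Draws, per sample: taxon presence from marginal prevalences with the
#' planted pair constraints applied (a positive pair is forced co-present
#' or co-absent with probability `strength`; a negative pair is forced to
#' at most one member); a dominant yeast and dominant bacterium; and
#' within-sample abundances from a Dirichlet over the present taxa with a
#' floor guaranteeing present taxa exceed the 1% detection threshold while
#' absent taxa receive at most trace (<1%) abundance. Coordinates are
#' uniform over a continental-US-like box (unstructured) or latitude
#' drives part of the composition (`"decay"`). Metadata variables: starter
#' `age_years` (log-normal), `grain_base` (white/whole_wheat/rye),
#' `storage` (counter/fridge), `mean_annual_temp_c` (normal), with planted
#' indicator effects applied as abundance-weight multipliers.
#'
#' @param spec a [survey_spec()].
#' @param as_counts if `TRUE`, additionally return integer count tables
#'   (multinomial draws at `depth` reads) usable by [rarefy()].
#' @param depth reads per sample for the count tables (default 5000).
#' @return list with `community` (relative [community_table()]),
#'   `metadata` (data.frame), `coordinates` ([geo_coordinates()]), and
#'   `counts` when requested. Fully reproducible given `spec$seed`.
#' @export
generate_survey <- function(spec, as_counts = FALSE, depth = 5000) {
  stopifnot(inherits(spec, "survey_spec"))
  roster <- spec$roster
  taxa <- roster$taxon_id
  n <- spec$n_samples
  n_t <- length(taxa)
  yeasts <- taxa[roster$group == "yeast"]
  labs <- taxa[roster$group == "LAB"]
  aabs <- taxa[roster$group == "AAB"]
  seeded(spec$seed, {
    # geography
    lat <- stats::runif(n, 25, 49)
    lon <- stats::runif(n, -124, -67)
    coords <- geo_coordinates(sprintf("S%03d", seq_len(n)), lat, lon)
    # metadata
    metadata <- data.frame(
      age_years = round(exp(stats::rnorm(n, log(8), 1)), 1),
      grain_base = sample(c("white", "whole_wheat", "rye"), n, replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)),
      storage = sample(c("counter", "fridge"), n, replace = TRUE,
                       prob = c(0.6, 0.4)),
      mean_annual_temp_c = round(stats::rnorm(n, 12, 6), 1),
      row.names = coords$sample_ids, stringsAsFactors = FALSE
    )
    # presence draws
    presence <- matrix(FALSE, n, n_t, dimnames = list(coords$sample_ids, taxa))
    for (j in seq_len(n_t)) {
      bp <- roster$base_prevalence[j]
      if (!is.na(bp)) presence[, j] <- stats::runif(n) < bp
    }
    # AAB block: a sample "contains AAB" with probability aab_prevalence;
    # if so one or two AAB taxa are present
    has_aab <- stats::runif(n) < spec$aab_prevalence
    for (i in which(has_aab)) {
      k <- 1 + (stats::runif(1) < 0.3)
      presence[i, sample(aabs, k)] <- TRUE
    }
    # decay geography: a latitude gradient drives both presence and the
    # identity of the dominant yeast, so nearby samples share composition
    if (spec$geography == "decay") {
      grad <- pmin(1, pmax(0, (lat - 25) / 24 * spec$decay_rate)) # south -> north
      presence[, "Saccharomyces_cerevisiae"] <- stats::runif(n) < 0.15 + 0.85 * grad
      presence[, "Kazachstania_humilis"] <- stats::runif(n) < 0.15 + 0.85 * (1 - grad)
      presence[, "Kazachstania_servazzii"] <- stats::runif(n) < pmax(0.05, grad)
      presence[, "Wickerhamomyces_anomalus"] <- stats::runif(n) < pmax(0.05, 1 - grad)
    }
    # planted pair constraints
    for (pp in spec$planted_pairs) {
      enforce <- stats::runif(n) < pp$strength
      if (pp$sign == "positive") {
        joint <- stats::runif(n) < mean(c(
          roster$base_prevalence[roster$taxon_id == pp$a],
          roster$base_prevalence[roster$taxon_id == pp$b]), na.rm = TRUE)
        presence[enforce, pp$a] <- joint[enforce]
        presence[enforce, pp$b] <- joint[enforce]
      } else {
        both <- enforce & presence[, pp$a] & presence[, pp$b]
        drop_a <- both & (stats::runif(n) < 0.5)
        presence[drop_a, pp$a] <- FALSE
        presence[both & !drop_a, pp$b] <- FALSE
      }
    }
    # every sample needs at least one yeast and one bacterium
    no_yeast <- rowSums(presence[, yeasts, drop = FALSE]) == 0
    presence[no_yeast, "Saccharomyces_cerevisiae"] <- TRUE
    no_bact <- rowSums(presence[, c(labs, aabs), drop = FALSE]) == 0
    presence[no_bact, "Lactobacillus_sanfranciscensis"] <- TRUE
    # abundances
    values <- matrix(0, n, n_t, dimnames = dimnames(presence))
    dom_w <- stats::setNames(roster$dominance_weight, taxa)
    for (i in seq_len(n)) {
      pres <- which(presence[i, ])
      alpha <- rep(spec$dirichlet_conc, length(pres))
      names(alpha) <- taxa[pres]
      # single-species dominance: one yeast and one bacterium get their
      # dominance weight
      pres_yeast <- intersect(taxa[pres], yeasts)
      pres_bact <- intersect(taxa[pres], c(labs, aabs))
      if (length(pres_yeast)) {
        dy <- if (length(pres_yeast) == 1) pres_yeast else
          sample(pres_yeast, 1, prob = dom_w[pres_yeast])
        alpha[dy] <- dom_w[dy]
      }
      if (length(pres_bact)) {
        db <- if (length(pres_bact) == 1) pres_bact else
          sample(pres_bact, 1, prob = dom_w[pres_bact])
        alpha[db] <- dom_w[db]
      }
      # decay geography also tilts abundance weights along the gradient
      if (spec$geography == "decay") {
        g_i <- min(1, max(0, (lat[i] - 25) / 24 * spec$decay_rate))
        north <- c("Saccharomyces_cerevisiae", "Pediococcus_parvulus")
        south <- c("Kazachstania_humilis", "Pediococcus_damnosus")
        for (tx in intersect(north, names(alpha))) {
          alpha[tx] <- alpha[tx] * (1 + 4 * g_i)
        }
        for (tx in intersect(south, names(alpha))) {
          alpha[tx] <- alpha[tx] * (1 + 4 * (1 - g_i))
        }
      }
      # planted indicator effects as weight multipliers
      for (ie in spec$indicator_effects) {
        if (ie$taxon %in% names(alpha) &&
            metadata[[ie$variable]][i] == ie$level) {
          alpha[ie$taxon] <- alpha[ie$taxon] * ie$multiplier
        }
      }
      # floor of 2% per present taxon keeps "present" above the 1% rule;
      # trace (<1% total) mass goes to a couple of absent taxa
      k <- length(pres)
      floor_frac <- 0.02
      trace_total <- stats::runif(1, 0, 0.005)
      main_mass <- 1 - trace_total
      shares <- rdirichlet_one(alpha)
      values[i, pres] <- main_mass * (floor_frac + (1 - floor_frac * k) * shares)
      absent <- setdiff(seq_len(n_t), pres)
      if (length(absent) >= 2 && trace_total > 0) {
        tr <- sample(absent, 2)
        values[i, tr] <- trace_total * rdirichlet_one(c(1, 1))
      } else if (length(absent) == 1) {
        values[i, absent] <- trace_total
      } else {
        values[i, pres[1]] <- values[i, pres[1]] + trace_total
      }
    }
    values <- values / rowSums(values)
    community <- community_table(values,
                                 roster[, c("taxon_id", "kingdom", "group")],
                                 relative = TRUE)
    out <- list(community = community, metadata = metadata,
                coordinates = coords)
    if (as_counts) {
      counts <- t(apply(values, 1, function(p) stats::rmultinom(1, depth, p)))
      dimnames(counts) <- dimnames(values)
      out$counts <- community_table(counts,
                                    roster[, c("taxon_id", "kingdom", "group")],
                                    relative = FALSE)
    }
    out
  })
}

#' Default eight-species competition design
#'
#' Four yeasts and four LAB in a full pairwise design (28 pairs, 16
#' cross-kingdom and 12 within-kingdom), an outcome prescription for every
#' pair, and a set of eight "significant in situ" signs (four positive,
#' four negative) of which the outcomes recapitulate seven — the planted
#' mismatch is one positive-sign pair prescribed as an exclusion.
#'
#' @return list with `species`, `kingdoms`, `design` (from
#'   [pairwise_design()]), `outcomes` (named by pair:
#'   `"co_persistence"`/`"exclusion_of_a"`/`"exclusion_of_b"`) and `signs`
#'   (named character vector over the eight tested pairs).
#' @export
default_competition_design <- function() {
  species <- c("Saccharomyces_cerevisiae", "Kazachstania_humilis",
               "Kazachstania_servazzii", "Wickerhamomyces_anomalus",
               "Lactobacillus_sanfranciscensis", "Lactobacillus_plantarum",
               "Lactobacillus_brevis", "Pediococcus_damnosus")
  kingdoms <- stats::setNames(rep(c("fungi", "bacteria"), each = 4), species)
  design <- pairwise_design(species, kingdoms)
  # default: yeast-bacterium pairs co-persist in half the pairings;
  # within-kingdom pairs mostly exclude
  outcomes <- stats::setNames(rep("co_persistence", nrow(design)), design$pair)
  excl <- c("Saccharomyces_cerevisiae|Kazachstania_humilis" = "exclusion_of_b",
            "Saccharomyces_cerevisiae|Kazachstania_servazzii" = "exclusion_of_b",
            "Kazachstania_humilis|Kazachstania_servazzii" = "exclusion_of_b",
            "Kazachstania_humilis|Wickerhamomyces_anomalus" = "exclusion_of_a",
            "Lactobacillus_sanfranciscensis|Lactobacillus_plantarum" = "exclusion_of_a",
            "Lactobacillus_sanfranciscensis|Lactobacillus_brevis" = "exclusion_of_a",
            "Lactobacillus_plantarum|Pediococcus_damnosus" = "exclusion_of_b",
            "Saccharomyces_cerevisiae|Lactobacillus_sanfranciscensis" = "exclusion_of_b",
            "Kazachstania_humilis|Lactobacillus_brevis" = "exclusion_of_b",
            "Wickerhamomyces_anomalus|Lactobacillus_plantarum" = "exclusion_of_a",
            # planted mismatch: positive sign but the experiment excludes one
            "Kazachstania_humilis|Lactobacillus_sanfranciscensis" = "exclusion_of_b")
  outcomes[names(excl)] <- excl
  signs <- c(
    # four positive in-situ associations
    "Lactobacillus_plantarum|Lactobacillus_brevis" = "positive",
    "Kazachstania_servazzii|Pediococcus_damnosus" = "positive",
    "Saccharomyces_cerevisiae|Lactobacillus_plantarum" = "positive",
    "Kazachstania_humilis|Lactobacillus_sanfranciscensis" = "positive",
    # four negative
    "Saccharomyces_cerevisiae|Lactobacillus_sanfranciscensis" = "negative",
    "Lactobacillus_sanfranciscensis|Lactobacillus_plantarum" = "negative",
    "Lactobacillus_sanfranciscensis|Lactobacillus_brevis" = "negative",
    "Saccharomyces_cerevisiae|Kazachstania_humilis" = "negative")
  list(species = species, kingdoms = kingdoms, design = design,
       outcomes = outcomes, signs = signs)
}

#' Generate a synthetic serial-transfer competition dataset
#'
#' CFU counts per pair x replicate x transfer realizing a prescribed
#' outcome map at the final transfer: co-persisting pairs end near 60/40,
#' exclusions end with the loser below the detection limit, and earlier
#' transfers interpolate from an even start. Replicate noise is
#' negative-binomial on the CFU scale (`dispersion = 0` gives
#' deterministic counts, the Poisson-free limit).
#'
#' @param winners named outcome map (`pair` -> outcome) as in
#'   [default_competition_design()]; defaults to that design's map.
#' @param n_replicates replicates per pair (default 5).
#' @param dispersion negative-binomial dispersion of CFU noise (default 0 =
#'   noiseless).
#' @param seed RNG seed.
#' @param species,kingdoms species roster; defaults to the eight-species
#'   design.
#' @param transfers sampled transfers (default `c(1, 3, 6)`).
#' @param total_cfu total CFU per plating (default 1e6).
#' @param limit detection limit the prescription is built around
#'   (default 0.01).
#' @return a [competition_dataset()].
#' @export
generate_competitions <- function(winners = NULL, n_replicates = 5,
                                  dispersion = 0, seed = NULL,
                                  species = NULL, kingdoms = NULL,
                                  transfers = c(1, 3, 6), total_cfu = 1e6,
                                  limit = 0.01) {
  if (is.null(winners)) {
    dd <- default_competition_design()
    winners <- dd$outcomes
    species <- dd$species
    kingdoms <- dd$kingdoms
  }
  pairs <- do.call(rbind, strsplit(names(winners), "|", fixed = TRUE))
  design <- data.frame(pair = names(winners), species_a = pairs[, 1],
                       species_b = pairs[, 2], stringsAsFactors = FALSE)
  final_frac_a <- vapply(winners, function(o) {
    switch(o,
           co_persistence = 0.6,
           exclusion_of_b = 1 - limit / 2, # loser well below the limit
           exclusion_of_a = limit / 2,
           mutual_collapse = stop("mutual_collapse cannot be prescribed for a two-species pair"),
           stop("unknown outcome: ", o))
  }, numeric(1))
  co <- winners == "co_persistence"
  minor <- pmin(final_frac_a, 1 - final_frac_a)
  if (any(co & minor <= limit) || any(!co & minor > limit)) {
    stop("prescribed fraction conflicts with the detection limit")
  }
  final_transfer <- max(transfers)
  seeded(seed, {
    rows <- list()
    for (i in seq_len(nrow(design))) {
      for (tr in transfers) {
        w <- tr / final_transfer
        frac_a <- 0.5 * (1 - w) + final_frac_a[i] * w
        for (rep_i in seq_len(n_replicates)) {
          mu <- c(frac_a, 1 - frac_a) * total_cfu
          cfu <- if (dispersion > 0) {
            stats::rnbinom(2, mu = mu, size = 1 / dispersion)
          } else {
            round(mu)
          }
          rows[[length(rows) + 1]] <- data.frame(
            pair = design$pair[i], species_a = design$species_a[i],
            species_b = design$species_b[i], replicate = rep_i,
            transfer = tr,
            species = c(design$species_a[i], design$species_b[i]),
            cfu = cfu, stringsAsFactors = FALSE)
        }
      }
    }
    competition_dataset(do.call(rbind, rows), species_kingdoms = kingdoms)
  })
}

#' Specification of the synthetic functional (rise/VOC/sensory) experiment
#'
#' Emulates a 40-starter functional screen: per-starter dough-rise rates
#' decline linearly with the total relative abundance of acetic acid
#' bacteria (`r = a + b * pctAAB + noise`, `b < 0`), VOC peak areas load
#' log-linearly on the AAB axis plus independent noise, and samples rich in
#' AAB tend to draw a vinegar-like dominant sensory note.
#'
#' @param n_starters starters (default 40).
#' @param replicates rise replicates per starter (default 3).
#' @param rise_a,rise_b intercept and slope of the rise-rate model in per
#'   hour units (defaults 1.4, -1.2, keeping rates inside the plausible
#'   0.1-1.5 range).
#' @param rise_sd between-starter noise SD of the rate (default 0.08).
#' @param rep_sd within-starter replicate SD of the rate (default 0.03).
#' @param obs_sd measurement noise on heights, as a fraction of K
#'   (default 0.01).
#' @param times sampling times in hours (default every 15 min to 36 h).
#' @param n_compounds VOC compounds carrying signal (default 30).
#' @param n_blank_compounds background compounds present at blank level
#'   (default 5).
#' @param aab_loading_scale scale of compound loadings on the AAB axis
#'   (default 3; larger = stronger VOC/%AAB coupling).
#' @param voc_noise_sd log-scale independent noise on areas (default 0.3).
#' @param vinegar_threshold %AAB above which the dominant note tends to
#'   vinegar (default 0.15).
#' @param seed RNG seed.
#' @return object of class `function_spec`.
#' @export
function_spec <- function(n_starters = 40, replicates = 3,
                          rise_a = 1.4, rise_b = -1.2, rise_sd = 0.08,
                          rep_sd = 0.03, obs_sd = 0.01,
                          times = seq(0, 36, by = 0.25),
                          n_compounds = 30, n_blank_compounds = 5,
                          aab_loading_scale = 3, voc_noise_sd = 0.3,
                          vinegar_threshold = 0.15, seed = NULL) {
  if (rise_sd < 0 || rep_sd < 0 || obs_sd < 0 || voc_noise_sd < 0) {
    stop("noise SDs must be non-negative")
  }
  structure(as.list(environment()), class = "function_spec")
}

#' Generate synthetic rise curves, VOC profiles, blanks and sensory notes
#'
#' @param spec a [function_spec()].
#' @param community relative [community_table()] providing per-sample %AAB;
#'   the first `n_starters` samples are used.
#' @return list with `rise_series` (long data.frame: tube, inoculum,
#'   replicate, time_h, pixels), `calibration` (tube, X0, Th, tube_mm),
#'   `rise_rates` (true per-starter rates), `voc` ([voc_table()]),
#'   `blanks` ([voc_table()]), `sensory` (named character vector of first
#'   dominant notes), `pct_aab`.
#' @export
generate_function <- function(spec, community) {
  stopifnot(inherits(spec, "function_spec"), inherits(community, "community_table"))
  ids <- utils::head(rownames(community$values), spec$n_starters)
  if (length(ids) < spec$n_starters) {
    stop("community has fewer samples than n_starters")
  }
  comm <- subset_community(community, samples = ids)
  aab <- percent_aab(to_relative_abundance(comm))
  seeded(spec$seed, {
    rates <- pmin(pmax(spec$rise_a + spec$rise_b * aab +
                         stats::rnorm(length(ids), 0, spec$rise_sd), 0.1), 1.5)
    K <- stats::runif(length(ids), 15, 30)
    rows <- list()
    calib <- list()
    tube_id <- 0
    for (s in seq_along(ids)) {
      for (rep_i in seq_len(spec$replicates)) {
        tube_id <- tube_id + 1
        r_rep <- max(rates[s] + stats::rnorm(1, 0, spec$rep_sd), 0.05)
        N0 <- 0.5
        h <- K[s] / (1 + ((K[s] - N0) / N0) * exp(-r_rep * spec$times))
        h <- h - h[1] # series starts at zero rise
        h <- h + stats::rnorm(length(h), 0, spec$obs_sd * K[s])
        h[1] <- 0
        X0 <- 60; Th <- 515 # camera-frame calibration, px
        rows[[tube_id]] <- data.frame(
          tube = sprintf("T%03d", tube_id), inoculum = ids[s],
          replicate = rep_i, time_h = spec$times,
          pixels = X0 + h / 103 * Th, stringsAsFactors = FALSE)
        calib[[tube_id]] <- data.frame(tube = sprintf("T%03d", tube_id),
                                       X0 = X0, Th = Th, tube_mm = 103,
                                       stringsAsFactors = FALSE)
      }
    }
    # VOC: log-areas load on the AAB axis
    comp <- sprintf("compound_%02d", seq_len(spec$n_compounds))
    loadings <- stats::rnorm(spec$n_compounds, 0, 1) * spec$aab_loading_scale
    baseline <- exp(stats::rnorm(spec$n_compounds, 0, 0.5))
    areas <- sapply(seq_len(spec$n_compounds), function(cj) {
      baseline[cj] * exp(loadings[cj] * aab +
                           stats::rnorm(length(ids), 0, spec$voc_noise_sd))
    })
    dimnames(areas) <- list(ids, comp)
    # background compounds: same level in samples and blanks
    bcomp <- sprintf("background_%02d", seq_len(spec$n_blank_compounds))
    blank_level <- exp(stats::rnorm(spec$n_blank_compounds, -1, 0.2))
    bg_sample <- matrix(rep(blank_level, each = length(ids)) *
                          stats::runif(length(ids) * spec$n_blank_compounds, 0.5, 1),
                        length(ids), spec$n_blank_compounds,
                        dimnames = list(ids, bcomp))
    blanks <- matrix(rep(blank_level, each = 3) *
                       stats::runif(3 * spec$n_blank_compounds, 0.8, 1.2),
                     3, spec$n_blank_compounds,
                     dimnames = list(paste0("blank_", 1:3), bcomp))
    # ensure the blank max dominates the sample max so the filter removes them
    blanks <- pmax(blanks, matrix(rep(apply(bg_sample, 2, max), each = 3),
                                  3, spec$n_blank_compounds))
    voc <- voc_table(cbind(areas, bg_sample))
    blanks_tab <- voc_table(blanks)
    notes_other <- c("yeasty", "green_apple", "fermented_sour", "ethyl_acetate")
    sensory <- vapply(seq_along(ids), function(s) {
      if (aab[s] > spec$vinegar_threshold && stats::runif(1) < 0.85) "vinegar"
      else sample(notes_other, 1, prob = c(0.4, 0.25, 0.25, 0.1))
    }, character(1))
    names(sensory) <- ids
    list(rise_series = do.call(rbind, rows),
         calibration = do.call(rbind, calib),
         rise_rates = stats::setNames(rates, ids),
         voc = voc, blanks = blanks_tab, sensory = sensory, pct_aab = aab)
  })
}
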