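#' Indicator correlation index for a categorical condition
#'
#' Point-biserial correlation `r` between a taxon's abundance and the 0/1
#' membership vector of a target group level, with a one-sided permutation
#' p-value (`p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`). An indicator
#' strength above 0.25 is conventionally read as a strong association.
#' Alternatively `statistic = "IndVal"` computes the classical indicator
#' value `sqrt(A * B)` with group-equalized specificity A and fidelity B.
#'
#' @param abundance non-negative abundances per sample.
#' @param groups categorical labels per sample (at least 2 levels).
#' @param target_level the level whose indicator is computed.
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed.
#' @param statistic `"r"` (default, point-biserial) or `"IndVal"`.
#' @return list with `statistic` value, `p`, `n_perm`; both are `NA` with a
#'   `reason` when the abundance vector is constant.
#' @export
indicator_r <- function(abundance, groups, target_level, n_perm = 999,
                        seed = NULL, statistic = c("r", "IndVal")) {
  statistic <- match.arg(statistic)
  if (length(abundance) != length(groups)) stop("abundance and groups must align")
  if (any(abundance < 0)) stop("abundance must be non-negative")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  if (!target_level %in% groups) stop("target_level not found in groups")
  if (stats::sd(abundance) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, n_perm = 0L,
                reason = "constant abundance vector"))
  }
  stat_of <- if (statistic == "r") {
    m0 <- as.numeric(groups == target_level)
    a_c <- abundance - mean(abundance)
    denom_a <- sqrt(sum(a_c^2))
    function(m) {
      mc <- m - mean(m)
      sum(a_c * mc) / (denom_a * sqrt(sum(mc^2)))
    }
  } else {
    function(m) {
      in_mean <- mean(abundance[m == 1])
      out_mean <- mean(abundance[m == 0])
      A <- if (in_mean + out_mean == 0) 0 else in_mean / (in_mean + out_mean)
      B <- mean(abundance[m == 1] > 0)
      sqrt(A * B)
    }
  }
  m <- as.numeric(groups == target_level)
  obs <- stat_of(m)
  perm_stats <- seeded(seed, {
    vapply(seq_len(n_perm), function(i) stat_of(sample(m)), numeric(1))
  })
  p <- (sum(perm_stats >= obs - 1e-12) + 1) / (n_perm + 1)
  list(statistic = obs, p = p, n_perm = n_perm)
}

#' Spearman correlation of taxon abundance with a continuous variable
#'
#' Spearman rho with midrank ties; two-sided p-value, exact (full rank
#' permutation enumeration) for `n <= 9` and t-approximated otherwise.
#'
#' @param abundance,variable paired finite numeric vectors, `n >= 4`.
#' @return list with `rho`, `p`, `method`.
#' @export
indicator_continuous <- function(abundance, variable) {
  if (length(abundance) != length(variable)) stop("inputs must align")
  if (any(!is.finite(abundance)) || any(!is.finite(variable))) {
    stop("inputs must be finite")
  }
  spearman_test(abundance, variable)
}

#' Screen all taxa for indicator associations with metadata variables
#'
#' For each taxon passing a prevalence filter (detected, i.e. above the
#' within-sample abundance threshold, in at least `prevalence_min` of
#' samples) and each metadata variable: categorical variables get the
#' indicator correlation index of the best-matching level with a
#' max-over-levels permutation p-value; continuous variables get Spearman
#' correlations. P-values are Benjamini-Hochberg corrected within each
#' variable (one testing family per variable).
#'
#' @param table relative-abundance [community_table()].
#' @param metadata data.frame of variables, rows aligned with (or named by)
#'   the table's samples.
#' @param types named character vector mapping every screened variable to
#'   `"categorical"` or `"continuous"`.
#' @param prevalence_min minimum detection fraction (default 0.10).
#' @param detection_threshold within-sample abundance defining detection
#'   (default 0.01, strict `>`).
#' @param fdr_alpha significance level on FDR-corrected p-values
#'   (default 0.05); stored, not used to drop rows.
#' @param n_perm label permutations for categorical variables (default 999).
#' @param seed RNG seed; output is reproducible given the seed.
#' @return data.frame of class `indicator_screen_result`: `taxon_id`,
#'   `variable`, `kind`, `level` (categorical only), `statistic`, `p_raw`,
#'   `p_fdr`, `significant`, `n_samples`, sorted by `p_fdr`.
#' @export
indicator_screen <- function(table, metadata, types,
                             prevalence_min = 0.10,
                             detection_threshold = 0.01,
                             fdr_alpha = 0.05, n_perm = 999, seed = NULL) {
  stopifnot(inherits(table, "community_table"))
  metadata <- as.data.frame(metadata)
  if (!is.null(rownames(metadata)) && all(sample_ids(table) %in% rownames(metadata))) {
    metadata <- metadata[sample_ids(table), , drop = FALSE]
  } else if (nrow(metadata) != nrow(table$values)) {
    stop("metadata must cover the table's samples")
  }
  vars <- names(types)
  untyped <- setdiff(vars, colnames(metadata))
  if (length(untyped)) stop("unknown variable(s): ", paste(untyped, collapse = ", "))
  bad <- types[!types %in% c("categorical", "continuous")]
  if (length(bad)) {
    stop("untyped variable(s) (must be categorical or continuous): ",
         paste(names(bad), collapse = ", "))
  }
  v <- table$values
  prevalence <- colMeans(v > detection_threshold)
  taxa <- colnames(v)[prevalence >= prevalence_min]
  if (!length(taxa)) {
    return(structure(data.frame(), class = c("indicator_screen_result", "data.frame")))
  }
  rows <- list()
  seeded(seed, {
    for (var in vars) {
      x <- metadata[[var]]
      ok <- !is.na(x) & is.finite(v[, 1]) # per-variable complete cases
      if (types[[var]] == "continuous") ok <- ok & is.finite(as.numeric(x))
      for (taxon in taxa) {
        ab <- v[ok, taxon]
        if (types[[var]] == "categorical") {
          g <- as.character(x[ok])
          levels_g <- unique(g)
          if (length(levels_g) < 2 || stats::sd(ab) == 0) {
            rows[[length(rows) + 1]] <- data.frame(
              taxon_id = taxon, variable = var, kind = "categorical",
              level = NA_character_, statistic = NA_real_, p_raw = NA_real_,
              n_samples = sum(ok), stringsAsFactors = FALSE)
            next
          }
          # max-over-levels point-biserial r with a permutation null of the
          # same max statistic (keeps the test honest for multi-level factors)
          a_c <- ab - mean(ab)
          denom_a <- sqrt(sum(a_c^2))
          r_levels <- function(gg) {
            vapply(levels_g, function(lv) {
              m <- as.numeric(gg == lv)
              mc <- m - mean(m)
              s <- sqrt(sum(mc^2))
              if (s == 0) -Inf else sum(a_c * mc) / (denom_a * s)
            }, numeric(1))
          }
          obs_all <- r_levels(g)
          best <- which.max(obs_all)
          obs <- obs_all[best]
          perm_max <- vapply(seq_len(n_perm), function(i) max(r_levels(sample(g))),
                             numeric(1))
          p <- (sum(perm_max >= obs - 1e-12) + 1) / (n_perm + 1)
          rows[[length(rows) + 1]] <- data.frame(
            taxon_id = taxon, variable = var, kind = "categorical",
            level = levels_g[best], statistic = unname(obs), p_raw = p,
            n_samples = sum(ok), stringsAsFactors = FALSE)
        } else {
          xx <- as.numeric(x[ok])
          if (stats::sd(ab) == 0 || stats::sd(xx) == 0) {
            res <- list(rho = NA_real_, p = NA_real_)
          } else {
            res <- spearman_test(ab, xx)
          }
          rows[[length(rows) + 1]] <- data.frame(
            taxon_id = taxon, variable = var, kind = "continuous",
            level = NA_character_, statistic = res$rho, p_raw = res$p,
            n_samples = sum(ok), stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (var in vars) {
    idx <- out$variable == var & !is.na(out$p_raw)
    out$p_fdr[idx] <- stats::p.adjust(out$p_raw[idx], method = "BH")
  }
  out$significant <- !is.na(out$p_fdr) & out$p_fdr <= fdr_alpha
  out <- out[order(out$p_fdr, out$p_raw, out$taxon_id, out$variable), ]
  rownames(out) <- NULL
  attr(out, "prevalence_min") <- prevalence_min
  attr(out, "detection_threshold") <- detection_threshold
  attr(out, "fdr_alpha") <- fdr_alpha
  class(out) <- c("indicator_screen_result", "data.frame")
  out
}
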