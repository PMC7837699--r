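#' Construct a volatile-compound table
#'
#' Sample-by-compound relative peak areas (analyte / internal standard)
#' from GC/MS headspace profiling, with optional per-compound retention
#' times and Kovats retention indices.
#'
#' @param values non-negative numeric matrix, samples as rows, compounds as
#'   columns, both dimensions named.
#' @param retention_times optional numeric vector (minutes) named by
#'   compound.
#' @param retention_indices optional numeric vector named by compound; must
#'   be `>= 700` (earliest bracketing alkane C7).
#' @return object of class `voc_table`.
#' @export
voc_table <- function(values, retention_times = NULL, retention_indices = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("values must have sample and compound names")
  }
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(colnames(values))) stop("compound ids must be unique")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("peak areas must be finite and non-negative")
  }
  if (!is.null(retention_indices)) {
    if (any(!is.finite(retention_indices)) || any(retention_indices < 700)) {
      stop("retention indices must be finite and >= 700")
    }
  }
  structure(list(values = values, retention_times = retention_times,
                 retention_indices = retention_indices),
            class = "voc_table")
}

#' @export
print.voc_table <- function(x, ...) {
  cat(sprintf("voc_table: %d samples x %d compounds\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Remove compounds at or below background (blank) levels
#'
#' A compound is eliminated from the whole table when its maximum area
#' across samples does not exceed its maximum area across the blank
#' (water/flour) samples — compounds measured at concentrations less than
#' or equal to background carry no signal. Compounds absent from the blanks
#' are retained whenever any sample shows a positive area.
#'
#' @param voc sample [voc_table()].
#' @param blanks blank-sample [voc_table()] sharing the compound namespace.
#' @return a `voc_table` restricted to retained compounds (attribute
#'   `"removed_compounds"` lists the eliminated ones).
#' @export
background_filter <- function(voc, blanks) {
  stopifnot(inherits(voc, "voc_table"))
  if (missing(blanks) || is.null(blanks)) stop("no blank samples provided")
  stopifnot(inherits(blanks, "voc_table"))
  compounds <- colnames(voc$values)
  blank_max <- stats::setNames(rep(0, length(compounds)), compounds)
  shared <- intersect(compounds, colnames(blanks$values))
  blank_max[shared] <- apply(blanks$values[, shared, drop = FALSE], 2, max)
  sample_max <- apply(voc$values, 2, max)
  keep <- sample_max > blank_max
  removed <- compounds[!keep]
  out <- voc_table(voc$values[, keep, drop = FALSE],
                   retention_times = voc$retention_times[names(voc$retention_times) %in% compounds[keep]],
                   retention_indices = voc$retention_indices[names(voc$retention_indices) %in% compounds[keep]])
  attr(out, "removed_compounds") <- removed
  out
}

#' Kovats retention index by linear interpolation between n-alkanes
#'
#' Temperature-programmed convention:
#' `RI = 100 * (n + (rt - rt_n) / (rt_{n+1} - rt_n))` for the bracketing
#' alkanes with carbon numbers `n` and `n + 1`. Standard mixtures span C7
#' to C30.
#'
#' @param rt retention time(s) in minutes; must lie within the alkane range.
#' @param alkane_rts numeric vector of alkane retention times named by
#'   carbon number (e.g. `c("7" = 1.9, "8" = 2.8, ...)`).
#' @return numeric retention index (vectorized over `rt`).
#' @export
kovats_ri <- function(rt, alkane_rts) {
  carbons <- as.integer(names(alkane_rts))
  if (any(is.na(carbons))) stop("alkane_rts must be named by carbon number")
  ord <- order(carbons)
  carbons <- carbons[ord]
  rts <- as.numeric(alkane_rts)[ord]
  if (any(diff(rts) <= 0)) stop("alkane retention times must increase with carbon number")
  vapply(rt, function(x) {
    if (!is.finite(x) || x < rts[1] || x > rts[length(rts)]) {
      stop(sprintf("retention time %.4g outside alkane range [%.4g, %.4g]",
                   x, rts[1], rts[length(rts)]))
    }
    i <- findInterval(x, rts, rightmost.closed = TRUE)
    100 * (carbons[i] + (x - rts[i]) / (rts[i + 1] - rts[i]))
  }, numeric(1))
}

#' Per-compound z-scores of a VOC table
#'
#' Standardizes each compound to mean 0 and population SD 1 (dividing by
#' `sqrt(mean((x - mean)^2))`; the population convention is deliberate and
#' documented since heatmap conventions vary). Constant compounds become
#' `NA` columns.
#'
#' @param voc a [voc_table()] with at least 2 samples.
#' @return numeric matrix of z-scores, same dimensions as the input.
#' @export
zscore_matrix <- function(voc) {
  stopifnot(inherits(voc, "voc_table"))
  v <- voc$values
  if (nrow(v) < 2) stop("need at least 2 samples")
  mu <- colMeans(v)
  sd_pop <- sqrt(colMeans(sweep(v, 2, mu)^2))
  z <- sweep(sweep(v, 2, mu), 2, sd_pop, "/")
  z[, sd_pop == 0] <- NA_real_
  z
}

#' Total relative abundance of acetic acid bacteria per sample
#'
#' @param community relative-abundance [community_table()].
#' @return named numeric vector: summed relative abundance of taxa
#'   annotated `group == "AAB"`.
#' @export
percent_aab <- function(community) {
  stopifnot(inherits(community, "community_table"))
  aab <- community$annotations$taxon_id[community$annotations$group == "AAB"]
  if (!length(aab)) {
    return(stats::setNames(rep(0, nrow(community$values)),
                           rownames(community$values)))
  }
  rowSums(community$values[, aab, drop = FALSE])
}

#' Average rows of a matrix by a grouping label
#'
#' Utility for collapsing experimental replicates to per-inoculum means
#' before community-function linkage.
#'
#' @param values numeric matrix with samples as rows.
#' @param groups label per row.
#' @return matrix of group means, rows named by group.
#' @export
average_by <- function(values, groups) {
  if (nrow(values) != length(groups)) stop("groups must align with rows")
  g <- factor(groups, levels = unique(groups))
  out <- apply(values, 2, function(col) tapply(col, g, mean))
  out <- matrix(out, nrow = nlevels(g),
                dimnames = list(levels(g), colnames(values)))
  out
}

#' Link community composition to functional outputs
#'
#' Computes the community-to-function statistics in one pass over a common
#' sample set (typically per-starter means, n = 40):
#' * Mantel tests (Spearman, one-sided) of VOC Bray-Curtis dissimilarities
#'   against community Bray-Curtis dissimilarities — overall and for each
#'   functional group (LAB, AAB, yeast) — and against Euclidean distances
#'   in total %AAB;
#' * a 2-axis NMDS of the VOC dissimilarities with per-taxon Spearman
#'   correlations against each axis (FDR-corrected across taxa per axis);
#' * Spearman correlation of %AAB with the dough rise rate;
#' * Kruskal-Wallis/Dunn of %AAB across dominant sensory notes (notes
#'   dominant in fewer than `min_note_n` samples are dropped).
#'
#' Missing `rise` or `sensory` inputs skip those sub-analyses with a
#' warning.
#'
#' @param voc [voc_table()] over the linked samples.
#' @param community relative-abundance [community_table()] over the same
#'   samples.
#' @param rise named numeric vector of per-sample rise rates (optional).
#' @param sensory named character vector of per-sample dominant sensory
#'   notes, first note reported per sample (optional).
#' @param n_perm Mantel permutations (default 999).
#' @param seed RNG seed threaded through every stochastic step.
#' @param min_note_n minimum note group size (default 5).
#' @return object of class `function_link_report`.
#' @export
link_function <- function(voc, community, rise = NULL, sensory = NULL,
                          n_perm = 999, seed = NULL, min_note_n = 5) {
  stopifnot(inherits(voc, "voc_table"), inherits(community, "community_table"))
  ids <- intersect(rownames(voc$values), rownames(community$values))
  if (length(ids) < 4) stop("fewer than 4 shared samples")
  voc_sub <- voc_table(voc$values[ids, , drop = FALSE])
  comm <- subset_community(community, samples = ids)
  comm_rel <- to_relative_abundance(comm)
  voc_ct <- community_table(
    voc_sub$values,
    data.frame(taxon_id = colnames(voc_sub$values), kingdom = "bacteria",
               group = "other"),
    relative = NA)
  d_voc <- bray_curtis(voc_ct)
  aab <- percent_aab(comm_rel)
  d_aab <- distance_matrix(as.matrix(stats::dist(aab)), "euclidean_pct_aab")
  mantel_rows <- list()
  add_mantel <- function(label, d_comm) {
    m <- mantel(d_voc, d_comm, n_perm = n_perm, seed = seed)
    data.frame(comparison = label, rho = m$statistic, p = m$p.value,
               stringsAsFactors = FALSE)
  }
  mantel_rows[["community"]] <- add_mantel("voc_vs_community", bray_curtis(comm_rel))
  for (grp in c("LAB", "AAB", "yeast")) {
    taxa <- comm$annotations$taxon_id[comm$annotations$group == grp]
    if (length(taxa) >= 2) {
      sub <- subset_community(comm_rel, taxa = taxa)
      if (all(rowSums(sub$values) > 0)) {
        mantel_rows[[grp]] <- add_mantel(paste0("voc_vs_", grp), bray_curtis(sub))
      }
    }
  }
  mantel_rows[["pct_aab"]] <- add_mantel("voc_vs_pct_aab_euclidean", d_aab)
  mantel_table <- do.call(rbind, mantel_rows)
  rownames(mantel_table) <- NULL
  ord <- nmds(d_voc, k = 2, seed = seed)
  taxa_axis <- do.call(rbind, lapply(colnames(comm_rel$values), function(tx) {
    ab <- comm_rel$values[, tx]
    do.call(rbind, lapply(1:2, function(ax) {
      if (stats::sd(ab) == 0) {
        data.frame(taxon_id = tx, axis = ax, rho = NA_real_, p_raw = NA_real_)
      } else {
        st <- spearman_test(ab, ord$coordinates[, ax])
        data.frame(taxon_id = tx, axis = ax, rho = st$rho, p_raw = st$p)
      }
    }))
  }))
  taxa_axis$p_fdr <- NA_real_
  for (ax in 1:2) {
    idx <- taxa_axis$axis == ax & !is.na(taxa_axis$p_raw)
    taxa_axis$p_fdr[idx] <- stats::p.adjust(taxa_axis$p_raw[idx], method = "BH")
  }
  rise_cor <- NULL
  if (!is.null(rise)) {
    shared <- intersect(ids, names(rise))
    if (length(shared) >= 4) {
      rise_cor <- spearman_test(aab[shared], as.numeric(rise[shared]))
    } else {
      warning("rise rates missing for most samples; skipping rise analysis")
    }
  } else {
    warning("no rise rates supplied; skipping rise analysis")
  }
  sensory_test <- NULL
  if (!is.null(sensory)) {
    shared <- intersect(ids, names(sensory))
    sensory_test <- tryCatch(
      kruskal_dunn(aab[shared], sensory[shared], min_group_n = min_note_n),
      error = function(e) {
        warning("sensory analysis skipped: ", conditionMessage(e))
        NULL
      })
  } else {
    warning("no sensory notes supplied; skipping sensory analysis")
  }
  structure(list(mantel = mantel_table, nmds = ord, taxa_axis = taxa_axis,
                 pct_aab = aab, rise_cor = rise_cor, sensory = sensory_test,
                 n = length(ids)),
            class = "function_link_report")
}

#' @export
print.function_link_report <- function(x, ...) {
  cat(sprintf("function_link_report (n = %d samples)\n", x$n))
  print(x$mantel, digits = 3, row.names = FALSE)
  if (!is.null(x$rise_cor)) {
    cat(sprintf("%%AAB vs rise rate: Spearman rho = %.3f, p = %.3g\n",
                x$rise_cor$rho, x$rise_cor$p))
  }
  if (!is.null(x$sensory)) {
    cat(sprintf("%%AAB vs dominant note: Kruskal-Wallis p = %.3g\n",
                x$sensory$p.value))
  }
  invisible(x)
}
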