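#' Mantel test between two distance matrices
#'
#' Correlates the `n(n-1)/2` off-diagonal distances of two matrices and
#' assesses significance by simultaneous row/column permutation of the
#' second matrix. The default is Spearman rank correlation with 999
#' permutations and a one-sided test for positive association (the
#' convention for distance-decay analyses); the reported p-value uses the
#' plus-one rule `p = (#{rho_perm >= rho_obs} + 1) / (n_perm + 1)`. When
#' `factorial(n) <= n_perm + 1` the full permutation group is enumerated
#' instead and the p-value is exact.
#'
#' @param d1,d2 [distance_matrix()] objects over the same ids (d2 is
#'   realigned to d1's id order).
#' @param method `"spearman"` (rank, default) or `"pearson"` (linear).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return object of class `mantel_result`: `statistic` (rho), `p.value`,
#'   `n_perm`, `method`, `alternative`, `exact` flag. If either distance
#'   vector is constant the statistic is `NA` with a `reason`.
#' @export
mantel <- function(d1, d2, method = c("spearman", "pearson"),
                   n_perm = 999, seed = NULL,
                   alternative = c("greater", "two.sided", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  stopifnot(inherits(d1, "starter_dist"), inherits(d2, "starter_dist"))
  if (!setequal(d1$ids, d2$ids)) stop("distance matrices have different ids")
  m2 <- d2$d[d1$ids, d1$ids]
  m1 <- d1$d
  n <- nrow(m1)
  if (n < 4) stop("Mantel test needs at least 4 samples")
  v1 <- lower_tri(m1)
  v2 <- lower_tri(m2)
  if (method == "spearman") { v1 <- rank(v1); v2 <- rank(v2) }
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    return(structure(list(statistic = NA_real_, p.value = NA_real_,
                          n_perm = 0L, method = method,
                          alternative = alternative, exact = FALSE,
                          reason = "constant distance vector"),
                     class = "mantel_result"))
  }
  rho_of <- function(perm) {
    mp <- m2[perm, perm]
    vp <- lower_tri(mp)
    if (method == "spearman") vp <- rank(vp)
    stats::cor(v1, vp)
  }
  rho_obs <- stats::cor(v1, v2)
  exact <- factorial(n) <= n_perm + 1
  if (exact) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, rho_of)
    count <- switch(alternative,
                    greater = sum(rho_perm >= rho_obs - 1e-12),
                    less = sum(rho_perm <= rho_obs + 1e-12),
                    two.sided = sum(abs(rho_perm) >= abs(rho_obs) - 1e-12))
    p <- count / nrow(perms)
    n_used <- nrow(perms) - 1L
  } else {
    rho_perm <- seeded(seed, {
      vapply(seq_len(n_perm), function(i) rho_of(sample.int(n)), numeric(1))
    })
    count <- switch(alternative,
                    greater = sum(rho_perm >= rho_obs - 1e-12),
                    less = sum(rho_perm <= rho_obs + 1e-12),
                    two.sided = sum(abs(rho_perm) >= abs(rho_obs) - 1e-12))
    p <- (count + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(statistic = rho_obs, p.value = p, n_perm = n_used,
                 method = method, alternative = alternative, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (is.na(x$statistic)) {
    cat("Mantel test: statistic undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Mantel test (%s, %s): rho = %.4f, p = %.4g (%d permutations%s)\n",
                x$method, x$alternative, x$statistic, x$p.value, x$n_perm,
                if (x$exact) ", exact" else ""))
  }
  invisible(x)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions a distance matrix among predictors using the Gower-centered
#' inner-product (McArdle-Anderson) formulation, with sequential (Type I)
#' terms taken in the order given — term order matters in multi-predictor
#' models and is deliberately left to the caller. Significance of each
#' term's pseudo-F is assessed by free permutation of sample labels.
#'
#' Samples with missing values in any used predictor are dropped (and
#' recorded in the result). A predictor constant across samples contributes
#' zero SS and no test; a predictor collinear with earlier terms (zero
#' additional rank while varying) is an error.
#'
#' @param d a [distance_matrix()].
#' @param predictors data.frame of predictor variables, rownames = sample
#'   ids (or rows aligned with `d`).
#' @param terms character vector of predictor columns, in testing order
#'   (default: all columns in order).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return object of class `permanova_result`: per-term data.frame with
#'   `df`, `SS`, `R2`, `F`, `p`, plus residual/total rows, and
#'   `dropped_samples`.
#' @export
permanova <- function(d, predictors, terms = colnames(predictors),
                      n_perm = 999, seed = NULL) {
  stopifnot(inherits(d, "starter_dist"))
  predictors <- as.data.frame(predictors)
  if (!is.null(rownames(predictors)) &&
      all(d$ids %in% rownames(predictors))) {
    predictors <- predictors[d$ids, , drop = FALSE]
  } else if (nrow(predictors) != length(d$ids)) {
    stop("predictors must cover the samples of d")
  }
  missing_terms <- setdiff(terms, colnames(predictors))
  if (length(missing_terms)) {
    stop("unknown predictor(s): ", paste(missing_terms, collapse = ", "))
  }
  complete <- stats::complete.cases(predictors[, terms, drop = FALSE])
  dropped <- d$ids[!complete]
  ids <- d$ids[complete]
  if (length(ids) < 3) stop("fewer than 3 samples with complete predictors")
  dm <- d$d[ids, ids]
  predictors <- predictors[complete, , drop = FALSE]
  n <- length(ids)
  # Gower-centered matrix G; tr(G) is the total sum of squares
  A <- -0.5 * dm^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  ss_total <- sum(diag(G))
  # cumulative hat matrices over sequential designs
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  X <- matrix(1, n, 1)
  rank_prev <- 1L
  H_prev <- matrix(1 / n, n, n)
  hat_list <- list()
  constant <- logical(length(terms))
  for (i in seq_along(terms)) {
    v <- predictors[[terms[i]]]
    if (length(unique(v)) < 2) {
      constant[i] <- TRUE
      hats[[i]] <- H_prev
      dfs[i] <- 0L
      hat_list[[i]] <- H_prev
      next
    }
    mm <- if (is.numeric(v)) matrix(v, n, 1) else stats::model.matrix(~ factor(v))[, -1, drop = FALSE]
    X <- cbind(X, mm)
    qr_x <- qr(X)
    rank_new <- qr_x$rank
    if (rank_new == rank_prev) {
      stop(sprintf("term '%s' is collinear with earlier terms (zero df)", terms[i]))
    }
    Q <- qr.Q(qr_x)[, seq_len(rank_new), drop = FALSE]
    H <- tcrossprod(Q)
    hats[[i]] <- H
    dfs[i] <- rank_new - rank_prev
    rank_prev <- rank_new
    H_prev <- H
    hat_list[[i]] <- H
  }
  H_full <- H_prev
  df_res <- n - rank_prev
  # term and residual SS as traces of (H_i - H_{i-1}) G
  term_ss_of <- function(Gm) {
    prev <- matrix(1 / n, n, n)
    ss <- numeric(length(terms))
    for (i in seq_along(terms)) {
      ss[i] <- sum((hats[[i]] - prev) * Gm)
      prev <- hats[[i]]
    }
    ss
  }
  ss_terms <- term_ss_of(G)
  ss_res <- sum((diag(n) - H_full) * G)
  F_of <- function(ss_terms, ss_res) {
    ifelse(dfs > 0, (ss_terms / dfs) / (ss_res / df_res), NA_real_)
  }
  F_obs <- F_of(ss_terms, ss_res)
  p <- rep(NA_real_, length(terms))
  testable <- dfs > 0
  if (any(testable) && n_perm > 0) {
    exceed <- rep(0L, length(terms))
    seeded(seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        Gp <- G[perm, perm]
        ssp <- term_ss_of(Gp)
        res_p <- sum((diag(n) - H_full) * Gp)
        Fp <- F_of(ssp, res_p)
        exceed <- exceed + as.integer(!is.na(Fp) & Fp >= F_obs - 1e-12)
      }
    })
    p[testable] <- (exceed[testable] + 1) / (n_perm + 1)
  }
  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(ss_terms, ss_res, ss_total),
    R2 = c(ss_terms, ss_res, ss_total) / ss_total,
    F = c(F_obs, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, n = n, n_perm = n_perm,
                 dropped_samples = dropped),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential terms, %d samples, %d permutations)\n",
              x$n, x$n_perm))
  if (length(x$dropped_samples)) {
    cat("dropped (missing predictors):", paste(x$dropped_samples, collapse = ", "), "\n")
  }
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 over monotone regression of the input
#' distances, taking the best of a classical-scaling start plus random
#' starts (backed by [vegan::monoMDS()]). Coordinates are centered and
#' rotated to principal axes with a fixed sign convention, so axis scores
#' (e.g. for downstream taxon-axis correlations) are deterministic given
#' the seed.
#'
#' @param d a [distance_matrix()].
#' @param k number of ordination axes (default 2).
#' @param n_starts number of starts including the metric start (default 20).
#' @param max_iter iteration cap per start.
#' @param seed RNG seed for the random starts.
#' @return object of class `nmds_result`: `coordinates` (samples x k,
#'   centered, principal-axis rotated), `stress` (Kruskal stress-1, in
#'   [0, 1]), `converged`, `n_starts`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 200, seed = NULL) {
  stopifnot(inherits(d, "starter_dist"))
  if (k < 1) stop("k must be >= 1")
  n <- length(d$ids)
  if (k > n - 1) stop("k must be at most n - 1")
  dd <- stats::as.dist(d$d)
  fit_one <- function(y) {
    vegan::monoMDS(dd, y = y, k = k, model = "global", maxit = max_iter)
  }
  metric_start <- suppressWarnings(stats::cmdscale(dd, k = k))
  if (ncol(metric_start) < k) {
    metric_start <- cbind(metric_start,
                          matrix(0, n, k - ncol(metric_start)))
  }
  best <- seeded(seed, {
    fits <- vector("list", n_starts)
    fits[[1]] <- fit_one(metric_start)
    if (n_starts > 1) {
      for (i in 2:n_starts) {
        fits[[i]] <- fit_one(matrix(stats::runif(n * k, -1, 1), n, k))
      }
    }
    fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  })
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  # rotate to principal axes; fix signs so the largest-|score| sample is
  # positive on each axis
  pc <- stats::prcomp(coords, center = FALSE)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- d$ids
  colnames(coords) <- paste0("NMDS", seq_len(k))
  structure(list(coordinates = coords, stress = best$stress,
                 converged = best$icause != 1L, n_starts = n_starts),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d samples, %d axes, stress-1 = %.4f (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across groups, after dropping groups with
#' fewer than `min_group_n` observations (default 5 — e.g. only sensory
#' notes dominant in at least five samples are tested). Pairwise Dunn
#' z-statistics with two-sided p-values are reported raw (default) and
#' Benjamini-Hochberg adjusted.
#'
#' @param values numeric response per sample.
#' @param groups group labels per sample.
#' @param min_group_n minimum group size to enter the test (default 5).
#' @return object of class `kruskal_dunn_result`: `H`, `df`, `p.value`,
#'   `dunn` (pairwise table), `groups_used`, `groups_dropped`, `n`.
#' @export
kruskal_dunn <- function(values, groups, min_group_n = 5) {
  if (length(values) != length(groups)) stop("values and groups must align")
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups)[ok]
  sizes <- table(groups)
  keep <- names(sizes)[sizes >= min_group_n]
  dropped <- setdiff(names(sizes), keep)
  if (length(keep) < 2) {
    stop(sprintf("fewer than 2 groups with n >= %d", min_group_n))
  }
  sel <- groups %in% keep
  v <- values[sel]
  g <- factor(groups[sel], levels = keep)
  N <- length(v)
  r <- rank(v)
  ni <- tabulate(g)
  rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties)
  correction <- 1 - tie_term / (N^3 - N)
  H <- if (correction > 0) H / correction else 0
  df <- length(keep) - 1
  p <- stats::pchisq(H, df = df, lower.tail = FALSE)
  # Dunn pairwise z with the tie-corrected variance
  sigma2 <- (N * (N + 1) / 12) - tie_term / (12 * (N - 1))
  pairs <- utils::combn(keep, 2)
  z <- vapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    (rbar[a] - rbar[b]) / sqrt(sigma2 * (1 / ni[which(keep == a)] +
                                         1 / ni[which(keep == b)]))
  }, numeric(1))
  p_pair <- 2 * stats::pnorm(-abs(z))
  dunn <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                     z = z, p = p_pair,
                     p_fdr = stats::p.adjust(p_pair, method = "BH"),
                     stringsAsFactors = FALSE)
  structure(list(H = H, df = df, p.value = p, dunn = dunn,
                 groups_used = keep, groups_dropped = dropped, n = N),
            class = "kruskal_dunn_result")
}

#' @export
print.kruskal_dunn_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$H, x$df, x$p.value, x$n))
  if (length(x$groups_dropped)) {
    cat("dropped groups (too small):", paste(x$groups_dropped, collapse = ", "), "\n")
  }
  print(x$dunn, digits = 4, row.names = FALSE)
  invisible(x)
}
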