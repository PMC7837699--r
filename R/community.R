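#' Construct a community table
#'
#' The central container of the pipeline: a sample-by-taxon matrix of
#' non-negative counts or relative abundances, together with a per-taxon
#' annotation of kingdom (`bacteria`/`fungi`) and functional group
#' (`LAB`/`AAB`/`yeast`/`other`). Lactic acid bacteria (LAB), acetic acid
#' bacteria (AAB) and yeasts are the fermentation-relevant groups that
#' downstream analyses subset on.
#'
#' @param values numeric matrix, samples as rows, taxa as columns; both
#'   dimensions must be named. Use `transpose = TRUE` for tables stored
#'   taxa-by-samples.
#' @param annotations data.frame with columns `taxon_id`, `kingdom`
#'   (`bacteria` or `fungi`) and `group` (`LAB`, `AAB`, `yeast` or `other`),
#'   covering every taxon in `values`.
#' @param relative logical; `TRUE` declares the rows to be relative
#'   abundances (each row must sum to 1 within 1e-9). `NA` (default) leaves
#'   the scale undeclared.
#' @param transpose if `TRUE`, `values` is taxa-by-samples and is transposed
#'   on input.
#' @return An object of class `community_table` with elements `values`,
#'   `annotations` and `relative`.
#' @export
community_table <- function(values, annotations, relative = NA, transpose = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (transpose) values <- t(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have sample (row) and taxon (column) names")
  }
  if (anyDuplicated(colnames(values))) stop("taxon ids must be unique")
  if (anyDuplicated(rownames(values))) stop("sample ids must be unique")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("community values must be finite and non-negative")
  }
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  required <- c("taxon_id", "kingdom", "group")
  if (!all(required %in% names(annotations))) {
    stop("annotations must have columns taxon_id, kingdom, group")
  }
  missing <- setdiff(colnames(values), annotations$taxon_id)
  if (length(missing)) {
    stop("taxa without annotation: ", paste(missing, collapse = ", "))
  }
  annotations <- annotations[match(colnames(values), annotations$taxon_id), , drop = FALSE]
  rownames(annotations) <- NULL
  bad_k <- setdiff(unique(annotations$kingdom), c("bacteria", "fungi"))
  if (length(bad_k)) stop("unknown kingdom: ", paste(bad_k, collapse = ", "))
  bad_g <- setdiff(unique(annotations$group), c("LAB", "AAB", "yeast", "other"))
  if (length(bad_g)) stop("unknown group: ", paste(bad_g, collapse = ", "))
  if (isTRUE(relative)) {
    rs <- rowSums(values)
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off)) {
      stop("rows declared relative do not sum to 1: ",
           paste(rownames(values)[off], collapse = ", "))
    }
  }
  structure(
    list(values = values, annotations = annotations, relative = relative),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa (%s)\n",
              nrow(x$values), ncol(x$values),
              if (isTRUE(x$relative)) "relative abundances" else "counts/undeclared"))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$annotations$group)),
                               table(x$annotations$group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$values)

sample_ids <- function(table) rownames(table$values)
taxon_ids <- function(table) colnames(table$values)

#' Subset a community table by samples and/or taxa
#'
#' @param table a [community_table()].
#' @param samples,taxa character vectors of ids to keep (default: all).
#' @return a `community_table`.
#' @export
subset_community <- function(table, samples = NULL, taxa = NULL) {
  stopifnot(inherits(table, "community_table"))
  s <- samples %||% sample_ids(table)
  t <- taxa %||% taxon_ids(table)
  missing_s <- setdiff(s, sample_ids(table))
  missing_t <- setdiff(t, taxon_ids(table))
  if (length(missing_s)) stop("unknown samples: ", paste(missing_s, collapse = ", "))
  if (length(missing_t)) stop("unknown taxa: ", paste(missing_t, collapse = ", "))
  community_table(table$values[s, t, drop = FALSE],
                  table$annotations[table$annotations$taxon_id %in% t, , drop = FALSE],
                  relative = NA)
}

#' Construct a distance matrix object
#'
#' @param d square symmetric numeric matrix with zero diagonal and row/column
#'   names giving the sample ids.
#' @param metric_name label for the metric.
#' @return An object of class `starter_dist`.
#' @export
distance_matrix <- function(d, metric_name = "unknown") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must have ids as dimnames")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-12) stop("distance matrix must have a zero diagonal")
  if (any(d < -1e-12)) stop("distances must be non-negative")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  colnames(d) <- rownames(d)
  structure(list(ids = rownames(d), d = d, metric_name = metric_name),
            class = "starter_dist")
}

#' @export
print.starter_dist <- function(x, ...) {
  cat(sprintf("starter_dist: %d x %d (%s)\n", length(x$ids), length(x$ids),
              x$metric_name))
  invisible(x)
}

#' @export
as.dist.starter_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to a fixed depth, the
#' standard normalization before converting amplicon counts to relative
#' abundances. Conventional depths for this pipeline are 1260 reads for
#' bacterial (16S) tables and 4000 for fungal (ITS) tables.
#'
#' @param counts a [community_table()] of integer counts.
#' @param depth target reads per sample; samples with fewer total reads are
#'   dropped (with a warning naming them).
#' @param seed integer seed for the subsampling RNG.
#' @return a `community_table` of counts in which every row sums to `depth`.
#'   Dropped samples are recorded in attribute `"dropped_samples"`.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  stopifnot(inherits(counts, "community_table"))
  v <- counts$values
  nonint <- which(abs(v - round(v)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint)) {
    stop(sprintf("non-integer count %g at sample '%s', taxon '%s'",
                 v[nonint[1, 1], nonint[1, 2]],
                 rownames(v)[nonint[1, 1]], colnames(v)[nonint[1, 2]]))
  }
  v <- round(v)
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be a positive integer")
  totals <- rowSums(v)
  keep <- totals >= depth
  dropped <- rownames(v)[!keep]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " sample(s) below depth ", depth,
            ": ", paste(dropped, collapse = ", "))
  }
  v <- v[keep, , drop = FALSE]
  out <- seeded(seed, {
    t(apply(v, 1, function(row) {
      total <- sum(row)
      if (total == depth) return(row)
      # sample read indices without replacement; map back to taxa via the
      # cumulative count boundaries
      picked <- sample.int(total, depth)
      boundaries <- cumsum(row)
      tabulate(findInterval(picked, c(0, boundaries), left.open = TRUE),
               nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(v)
  res <- community_table(out, counts$annotations, relative = FALSE)
  attr(res, "dropped_samples") <- dropped
  res
}

#' Convert counts to relative abundances
#'
#' @param counts a [community_table()].
#' @return a `community_table` with each row summing to 1.
#' @export
to_relative_abundance <- function(counts) {
  stopifnot(inherits(counts, "community_table"))
  rs <- rowSums(counts$values)
  zero <- which(rs == 0)
  if (length(zero)) {
    stop("all-zero sample(s): ", paste(rownames(counts$values)[zero], collapse = ", "))
  }
  community_table(counts$values / rs, counts$annotations, relative = TRUE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computes `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between all sample
#' pairs. On relative-abundance rows this equals
#' `1 - 2 * sum(min(x_i, y_i)) / sum(x_i + y_i)`.
#'
#' @param table a [community_table()].
#' @return a [distance_matrix()] with entries in `[0, 1]` for same-scale rows.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "community_table"))
  v <- table$values
  rs <- rowSums(v)
  if (any(rs == 0)) {
    zero <- rownames(v)[rs == 0]
    stop("Bray-Curtis undefined for all-zero sample(s): ",
         paste(zero, collapse = ", "))
  }
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) {
    xi <- v[i, ]
    rest <- (i + 1):n
    num <- colSums(abs(t(v[rest, , drop = FALSE]) - xi))
    den <- rs[rest] + rs[i]
    d[i, rest] <- d[rest, i] <- num / den
  }
  distance_matrix(d, "bray_curtis")
}

#' Combine bacterial and fungal tables with kingdom weighting
#'
#' Merges two kingdom-specific relative-abundance tables into one table in
#' which each kingdom block is renormalized to a fixed total weight
#' (default 0.5/0.5, i.e. bacteria weighted equally to fungi). The fungal
#' block is restricted to yeast taxa before weighting; non-yeast fungi
#' (molds, plant endophytes) are discarded here because they play little
#' role in the fermentation.
#'
#' @param bacteria,fungi [community_table()]s over the same sample set.
#' @param weights length-2 non-negative vector `(w_bacteria, w_fungi)`
#'   summing to 1. A zero weight drops that block entirely.
#' @param yeast_only if `TRUE` (default) the fungal block keeps only taxa
#'   annotated `group == "yeast"`.
#' @return a relative `community_table` whose rows sum to 1.
#' @export
combine_kingdoms <- function(bacteria, fungi, weights = c(0.5, 0.5),
                             yeast_only = TRUE) {
  stopifnot(inherits(bacteria, "community_table"), inherits(fungi, "community_table"))
  if (length(weights) != 2 || any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be two non-negative fractions summing to 1")
  }
  only_b <- setdiff(sample_ids(bacteria), sample_ids(fungi))
  only_f <- setdiff(sample_ids(fungi), sample_ids(bacteria))
  if (length(only_b) || length(only_f)) {
    stop("sample sets differ; present in one table only: ",
         paste(c(only_b, only_f), collapse = ", "))
  }
  fungi <- subset_community(fungi, samples = sample_ids(bacteria))
  if (yeast_only) {
    yeasts <- fungi$annotations$taxon_id[fungi$annotations$group == "yeast"]
    if (!length(yeasts)) stop("fungal table contains no yeast taxa")
    fungi <- subset_community(fungi, taxa = yeasts)
  }
  scale_block <- function(tab, w) {
    if (w == 0) return(NULL)
    rs <- rowSums(tab$values)
    zero <- which(rs == 0)
    if (length(zero)) {
      stop("cannot renormalize all-zero block row(s): ",
           paste(rownames(tab$values)[zero], collapse = ", "))
    }
    tab$values / rs * w
  }
  blocks <- list(scale_block(bacteria, weights[1]), scale_block(fungi, weights[2]))
  anns <- list(bacteria$annotations, fungi$annotations)
  keep <- !vapply(blocks, is.null, logical(1))
  combined <- do.call(cbind, blocks[keep])
  annotations <- do.call(rbind, anns[keep])
  community_table(combined, annotations, relative = TRUE)
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering, by default with Ward.D2 linkage (the
#' Murtagh-Legendre squared-distance update), as used to order samples in
#' community heatmaps.
#'
#' @param d a [distance_matrix()].
#' @param linkage linkage method passed to [stats::hclust()]; default
#'   `"ward.D2"`.
#' @return An object of class `starter_dendro` with elements `merge`,
#'   `height`, `labels`, `linkage_name` and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(d, linkage = "ward.D2") {
  stopifnot(inherits(d, "starter_dist"))
  if (length(d$ids) < 2) stop("need at least 2 samples to cluster")
  hc <- stats::hclust(stats::as.dist(d$d), method = linkage)
  structure(
    list(merge = hc$merge, height = hc$height, labels = hc$labels,
         linkage_name = linkage, hclust = hc),
    class = "starter_dendro"
  )
}

#' @export
print.starter_dendro <- function(x, ...) {
  cat(sprintf("starter_dendro: %d leaves, linkage %s\n",
              length(x$labels), x$linkage_name))
  invisible(x)
}
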