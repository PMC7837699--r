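# Independent oracles and fixture builders used across the suite. These are
# deliberately naive implementations, separate from the package's code paths.

# small community table from a plain matrix; groups/kingdoms default sensibly
make_table <- function(values, groups = NULL, kingdoms = NULL, relative = NA) {
  if (is.null(colnames(values))) colnames(values) <- paste0("t", seq_len(ncol(values)))
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  groups <- groups %||% rep("LAB", ncol(values))
  kingdoms <- kingdoms %||% ifelse(groups == "yeast", "fungi", "bacteria")
  community_table(values,
                  data.frame(taxon_id = colnames(values), kingdom = kingdoms,
                             group = groups, stringsAsFactors = FALSE),
                  relative = relative)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random symmetric distance matrix with zero diagonal
random_dist <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::runif(n * n, 0.1, 1), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  distance_matrix(m, "random")
}

# naive O(n^3) Ward.D2 agglomeration (Lance-Williams squared-distance
# update), returning sorted merge heights and the cophenetic matrix
ward_d2_oracle <- function(d) {
  dm <- d
  n <- nrow(dm)
  sizes <- rep(1, n)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  cur <- dm
  while (length(active) > 1) {
    k <- length(active)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (cur[i, j] < best_d - 1e-12) {
        best_d <- cur[i, j]; best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, best_d)
    mi <- members[[i]]; mj <- members[[j]]
    coph[mi, mj] <- best_d
    coph[mj, mi] <- best_d
    ni <- sizes[i]; nj <- sizes[j]
    new_row <- numeric(k)
    for (l in seq_len(k)) {
      if (l == i || l == j) next
      nl <- sizes[l]
      new_row[l] <- sqrt(((ni + nl) * cur[i, l]^2 + (nj + nl) * cur[j, l]^2 -
                            nl * best_d^2) / (ni + nj + nl))
    }
    keep <- setdiff(seq_len(k), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], new_row[keep]),
                 c(new_row[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    members <- c(members[keep], list(c(mi, mj)))
    active <- seq_len(k - 1)
  }
  list(heights = sort(heights), cophenetic = coph)
}

# exhaustive co-occurrence null: enumerate every placement of N1 and N2
# occupied samples among N and tabulate the joint count
cooccur_enum_oracle <- function(N, N1, N2) {
  A <- utils::combn(N, N1, simplify = FALSE)
  if (N1 == 0) A <- list(integer(0))
  B <- utils::combn(N, N2, simplify = FALSE)
  if (N2 == 0) B <- list(integer(0))
  counts <- numeric(min(N1, N2) + 1)
  for (a in A) for (b in B) {
    j <- length(intersect(a, b))
    counts[j + 1] <- counts[j + 1] + 1
  }
  counts / sum(counts)
}

# simple recursive permutation enumerator, independent of the package's
perm_enum <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perm_enum(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# Floyd-Warshall shortest paths over a tree's edge graph, restricted to tips
floyd_warshall_patristic <- function(tree) {
  n_nodes <- max(tree$edge)
  D <- matrix(Inf, n_nodes, n_nodes)
  diag(D) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    w <- tree$edge.length[e]
    D[a, b] <- D[b, a] <- w
  }
  for (k in seq_len(n_nodes)) for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  tips <- seq_len(length(tree$tip.label))
  out <- D[tips, tips]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}
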