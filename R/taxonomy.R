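#' Patristic distances between the leaves of a phylogenetic tree
#'
#' Sum of branch lengths along the unique path between every pair of
#' leaves, computed from an `ape` `phylo` object (rooted or unrooted).
#'
#' @param tree an [ape::read.tree()] `phylo` object with branch lengths.
#' @return a [distance_matrix()] over the leaf labels.
#' @export
patristic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  bad <- which(is.na(tree$edge.length))
  if (length(bad)) {
    stop(sprintf("missing branch length on edge %d (%d -> %d)",
                 bad[1], tree$edge[bad[1], 1], tree$edge[bad[1], 2]))
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  d <- ape::cophenetic.phylo(tree)
  distance_matrix(d[tree$tip.label, tree$tip.label], "patristic")
}

#' Curated species groups for cluster naming
#'
#' Editable default mapping of group name to the set of reference species
#' documented as too closely related to separate at marker resolution
#' (e.g. the *L. plantarum* spp. group). Used by [assign_species()] when a
#' cluster contains more than two reference species.
#'
#' @return named list of character vectors of species names.
#' @export
curated_species_groups <- function() {
  list(
    "L. plantarum spp. group" = c("L. plantarum", "L. pentosus", "L. fabifermentans"),
    "L. casei spp. group" = c("L. casei", "L. paracasei", "L. zeae", "L. rhamnosus"),
    "L. crustorum spp. group" = c("L. crustorum", "L. mindensis", "L. farcisminis"),
    "A. lovaniensis spp. group" = c("A. lambici", "A. lovaniensis", "A. okinawensis",
                                    "A. syzygii", "A. ghanensis", "A. fabarum"),
    "A. malorum spp. group" = c("A. orientalis", "A. farinalis", "A. malorum",
                                "A. cerevisiae", "A. persici", "A. cibinongensis"),
    "G. frateurii spp. group" = c("G. wanchernii", "G. jabonicus", "G. thailandicus",
                                  "G. cerinus", "G. nephelii")
  )
}

#' Assign species labels to query sequences by patristic clustering
#'
#' Single-linkage clusters all leaves (queries plus references) at a
#' patristic-distance threshold (default 0.97). Each query is named from
#' the reference species in its cluster: one reference — that species; two
#' — both names joined with `"/"`; more than two — a curated group name if
#' the cluster's reference species are all members of one curated group,
#' otherwise the cluster number. Queries whose cluster contains no
#' reference are unassigned.
#'
#' @param d a [distance_matrix()] of patristic distances
#'   ([patristic_distances()]).
#' @param queries character vector of query leaf ids.
#' @param references named character vector mapping reference leaf ids to
#'   species names; must be disjoint from `queries` and present in `d`.
#' @param threshold single-linkage clustering height (default 0.97, raw
#'   branch-length units).
#' @param curated_groups named list of species sets, see
#'   [curated_species_groups()].
#' @return data.frame of class `species_assignment`: `query`, `label`,
#'   `rule` in `{single_ref, dual_ref, named_group, cluster_number,
#'   unassigned}`, `cluster`, `n_refs`.
#' @export
assign_species <- function(d, queries, references, threshold = 0.97,
                           curated_groups = curated_species_groups()) {
  stopifnot(inherits(d, "starter_dist"))
  if (is.null(names(references))) stop("references must be named by leaf id")
  if (length(intersect(queries, names(references)))) {
    stop("queries and references must be disjoint leaf sets")
  }
  absent <- setdiff(c(queries, names(references)), d$ids)
  if (length(absent)) {
    stop("leaves absent from the tree/distance matrix: ",
         paste(absent, collapse = ", "))
  }
  leaves <- c(queries, names(references))
  sub <- d$d[leaves, leaves]
  if (length(leaves) == 1) {
    clusters <- stats::setNames(1L, leaves)
  } else {
    hc <- stats::hclust(stats::as.dist(sub), method = "single")
    clusters <- stats::cutree(hc, h = threshold)
  }
  out <- lapply(queries, function(q) {
    cl <- clusters[[q]]
    members <- names(clusters)[clusters == cl]
    refs_in <- intersect(members, names(references))
    species <- sort(unique(references[refs_in]))
    if (length(species) == 0) {
      label <- NA_character_; rule <- "unassigned"
    } else if (length(species) == 1) {
      label <- species; rule <- "single_ref"
    } else if (length(species) == 2) {
      label <- paste(species, collapse = "/"); rule <- "dual_ref"
    } else {
      hit <- names(curated_groups)[vapply(curated_groups, function(g)
        all(species %in% g), logical(1))]
      if (length(hit)) {
        label <- hit[1]; rule <- "named_group"
      } else {
        label <- paste0("cluster_", cl); rule <- "cluster_number"
      }
    }
    data.frame(query = q, label = label, rule = rule, cluster = cl,
               n_refs = length(species), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("species_assignment", "data.frame")
  res
}
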