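#' Read a community table from TSV/CSV
#'
#' Expected dialect: first column sample id, header row taxon ids; a
#' sidecar annotation table with columns `taxon_id`, `kingdom`, `group`.
#'
#' @param path path to the abundance table (TSV by default; `sep = ","` for
#'   CSV).
#' @param annotations_path path to the taxon-annotation TSV.
#' @param sep field separator (default tab).
#' @param transpose if `TRUE` the file is taxa-by-samples.
#' @param relative declared scale, passed to [community_table()].
#' @return a [community_table()].
#' @export
read_community_table <- function(path, annotations_path, sep = "\t",
                                 transpose = FALSE, relative = NA) {
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  ann <- utils::read.table(annotations_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  community_table(as.matrix(tab), ann, relative = relative,
                  transpose = transpose)
}

#' Read a metadata table
#'
#' @param path TSV with first column sample id.
#' @param sep field separator.
#' @return data.frame with sample ids as rownames.
#' @export
read_metadata <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a long-format competition CFU table
#'
#' @param path TSV with columns pair, species_a, species_b, replicate,
#'   transfer, species, cfu.
#' @param sep field separator.
#' @return a [competition_dataset()].
#' @export
read_competition_tsv <- function(path, sep = "\t") {
  competition_dataset(utils::read.table(path, header = TRUE, sep = sep,
                                        stringsAsFactors = FALSE))
}

#' Write a result table as TSV
#'
#' @param x data.frame-like result.
#' @param path output path.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a square distance matrix as TSV with an id header
#'
#' @param d a [distance_matrix()].
#' @param path output path.
#' @export
write_distance_tsv <- function(d, path) {
  stopifnot(inherits(d, "starter_dist"))
  utils::write.table(data.frame(id = d$ids, d$d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square distance matrix written by [write_distance_tsv()]
#'
#' @param path input path.
#' @param metric_name label for the metric.
#' @return a [distance_matrix()].
#' @export
read_distance_tsv <- function(path, metric_name = "unknown") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  distance_matrix(as.matrix(tab), metric_name)
}
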