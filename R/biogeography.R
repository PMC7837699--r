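#' Construct a set of sample coordinates
#'
#' @param sample_ids character vector of sample identifiers.
#' @param latitude degrees in `[-90, 90]`.
#' @param longitude degrees in `[-180, 180]`.
#' @return object of class `geo_coordinates`.
#' @export
geo_coordinates <- function(sample_ids, latitude, longitude) {
  if (length(sample_ids) != length(latitude) ||
      length(sample_ids) != length(longitude)) {
    stop("sample_ids, latitude and longitude must have equal length")
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (any(!is.finite(latitude)) || any(latitude < -90) || any(latitude > 90)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(!is.finite(longitude)) || any(longitude < -180) || any(longitude > 180)) {
    stop("longitude out of range [-180, 180]")
  }
  structure(list(sample_ids = as.character(sample_ids),
                 latitude = as.numeric(latitude),
                 longitude = as.numeric(longitude)),
            class = "geo_coordinates")
}

#' Great-circle (Haversine) distance matrix
#'
#' @param coords a [geo_coordinates()] object.
#' @param radius_km Earth radius in km (default 6371).
#' @return a [distance_matrix()] in kilometres.
#' @export
haversine_matrix <- function(coords, radius_km = 6371) {
  stopifnot(inherits(coords, "geo_coordinates"))
  lat <- coords$latitude * pi / 180
  lon <- coords$longitude * pi / 180
  n <- length(lat)
  dlat <- outer(lat, lat, "-")
  dlon <- outer(lon, lon, "-")
  a <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  d <- 2 * radius_km * asin(sqrt(a))
  diag(d) <- 0
  dimnames(d) <- list(coords$sample_ids, coords$sample_ids)
  distance_matrix(d, "haversine_km")
}

#' Distance-decay test of community similarity against geographic distance
#'
#' Mantel test (Spearman rank correlation of community against geographic
#' distances, one-sided for positive association, 999 permutations by
#' default). A positive, significant rho indicates distance-decay: samples
#' further apart are compositionally more dissimilar.
#'
#' @param comm community [distance_matrix()] (e.g. Bray-Curtis).
#' @param geo geographic [distance_matrix()] from [haversine_matrix()].
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return a `mantel_result`, see [mantel()].
#' @export
distance_decay <- function(comm, geo, n_perm = 999, seed = NULL) {
  mantel(comm, geo, method = "spearman", n_perm = n_perm, seed = seed,
         alternative = "greater")
}

#' k-means clustering of sample coordinates into geographic regions
#'
#' Lloyd's algorithm on latitude/longitude treated as planar coordinates
#' (optionally an equirectangular local projection), restarted `n_restarts`
#' times and keeping the solution with the lowest within-cluster sum of
#' squares. Empty clusters arising during iteration are re-seeded at the
#' point currently farthest from its assigned centroid. Typical regioning
#' scales for a continental survey are `k = 4` (broad regions) and `k = 15`
#' (fine regions).
#'
#' @param coords a [geo_coordinates()] object.
#' @param k number of clusters; must not exceed the number of distinct
#'   coordinate points.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param n_restarts independent restarts (default 10).
#' @param max_iter iteration cap per restart.
#' @param project if `TRUE`, cluster on an equirectangular projection
#'   (km east/north about the mean latitude) instead of raw degrees.
#' @return object of class `region_clustering` with `k`, `labels`
#'   (1..k per sample), `centroids`, `inertia` and `inertia_trace` (the
#'   within-SS after each Lloyd iteration of the winning restart).
#' @export
kmeans_regions <- function(coords, k, seed = NULL, n_restarts = 10,
                           max_iter = 100, project = FALSE) {
  stopifnot(inherits(coords, "geo_coordinates"))
  if (project) {
    lat0 <- mean(coords$latitude) * pi / 180
    x <- cbind(x = coords$longitude * pi / 180 * cos(lat0) * 6371,
               y = coords$latitude * pi / 180 * 6371)
  } else {
    x <- cbind(lon = coords$longitude, lat = coords$latitude)
  }
  distinct <- nrow(unique(x))
  if (k > distinct) {
    stop(sprintf("k = %d exceeds the %d distinct coordinate points", k, distinct))
  }
  n <- nrow(x)
  run_once <- function() {
    centers <- x[sample.int(n, k, prob = NULL), , drop = FALSE]
    # resample until initial centers are distinct
    tries <- 0
    while (nrow(unique(centers)) < k && tries < 100) {
      centers <- x[sample.int(n, k), , drop = FALSE]
      tries <- tries + 1
    }
    labels <- rep(1L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
      new_labels <- max.col(-d2, ties.method = "first")
      for (c_id in seq_len(k)) {
        if (!any(new_labels == c_id)) {
          # empty cluster: reseed at the point farthest from its centroid
          far <- which.max(d2[cbind(seq_len(n), new_labels)])
          new_labels[far] <- c_id
        }
      }
      centers <- do.call(rbind, lapply(seq_len(k), function(c_id) {
        colMeans(x[new_labels == c_id, , drop = FALSE])
      }))
      inertia <- sum((x - centers[new_labels, , drop = FALSE])^2)
      trace <- c(trace, inertia)
      if (identical(new_labels, labels) && it > 1) break
      labels <- new_labels
    }
    list(labels = labels, centers = centers, inertia = inertia, trace = trace)
  }
  best <- seeded(seed, {
    runs <- lapply(seq_len(n_restarts), function(i) run_once())
    runs[[which.min(vapply(runs, `[[`, numeric(1), "inertia"))]]
  })
  centroids <- best$centers
  colnames(centroids) <- colnames(x)
  structure(list(k = k,
                 labels = stats::setNames(best$labels, coords$sample_ids),
                 centroids = centroids,
                 inertia = best$inertia,
                 inertia_trace = best$trace,
                 projected = project),
            class = "region_clustering")
}

#' @export
print.region_clustering <- function(x, ...) {
  cat(sprintf("region_clustering: k = %d, inertia = %.4g\n", x$k, x$inertia))
  print(table(cluster = x$labels))
  invisible(x)
}
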