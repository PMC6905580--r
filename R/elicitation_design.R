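# Elicitation design: choose which sites the experts view. Observed sites
# are grouped by hierarchical clustering on a Gower dissimilarity over
# mixed-type habitat features (ordinal vegetation height and density,
# distance to water, FPC, and the binary presence label), then one site is
# drawn at random per cluster to form a ten-image subset per expert.

#' Assemble the mixed-type features used for site clustering
#'
#' Ordinal vegetation height (1-5) and density (1-4), distance to fresh
#' water, FPC, and the presence/absence label. Covariate tables from
#' [generate_landscape()] already carry the ordinals; otherwise they are
#' derived from FPC class boundaries (a synthetic stand-in for field
#' estimates).
#'
#' @param covariates Covariate table for the observed sites.
#' @param observations Matching observation table (for the presence label).
#' @return Data frame: `site_id`, `veg_height`, `veg_density`, `dist_water`,
#'   `fpc`, `presence`.
#' @export
clustering_features <- function(covariates, observations) {
  idx <- match(observations$site_id, covariates$site_id)
  cov <- covariates[idx, , drop = FALSE]
  vh <- if ("veg_height" %in% names(cov)) {
    cov$veg_height
  } else {
    6L - as.integer(cut(cov$fpc, c(-Inf, 15, 35, 55, 75, Inf)))
  }
  vd <- if ("veg_density" %in% names(cov)) {
    cov$veg_density
  } else {
    5L - as.integer(cut(cov$fpc, c(-Inf, 10, 30, 70, Inf)))
  }
  stopifnot(all(vh %in% 1:5), all(vd %in% 1:4))
  data.frame(
    site_id = observations$site_id,
    veg_height = vh, veg_density = vd,
    dist_water = cov$dist_water, fpc = cov$fpc,
    presence = as.integer(observations$y),
    stringsAsFactors = FALSE
  )
}

#' Gower dissimilarity over mixed-type site features
#'
#' Mean over variables of the range-normalized absolute difference for
#' continuous and ordinal variables (ordinals treated as interval-scaled)
#' and simple mismatch for the binary presence label. Constant variables
#' carry no information and are dropped with a warning.
#'
#' @param features Feature table from [clustering_features()] (a `site_id`
#'   column, if present, labels the result; every other column enters the
#'   dissimilarity; a column named `presence` is treated as binary).
#' @return A `dist` object with entries in \[0, 1\], labelled by site id.
#' @export
gower_distance <- function(features) {
  ids <- if ("site_id" %in% names(features)) {
    as.character(features$site_id)
  } else {
    as.character(seq_len(nrow(features)))
  }
  vars <- features[setdiff(names(features), "site_id")]
  if (nrow(vars) < 2L) stop("need at least 2 rows", call. = FALSE)
  constant <- vapply(vars, function(x) length(unique(x)) < 2L, logical(1))
  if (all(constant)) stop("all features are constant", call. = FALSE)
  if (any(constant)) {
    warning(
      "dropping constant feature(s): ",
      paste(names(vars)[constant], collapse = ", ")
    )
    vars <- vars[!constant]
  }
  if ("presence" %in% names(vars)) {
    vars$presence <- factor(vars$presence, levels = c(0, 1))
  }
  d <- cluster::daisy(vars, metric = "gower", warnBin = FALSE)
  attr(d, "Labels") <- ids
  d
}

#' Hierarchically cluster sites from a dissimilarity matrix
#'
#' Agglomerative clustering of the Gower dissimilarities, cut at
#' `n_clusters`. The default linkage is complete; average linkage (UPGMA)
#' is available since both are defensible groupings for this design.
#'
#' @param dist A `dist` object (e.g. from [gower_distance()]).
#' @param n_clusters Number of clusters, between 1 and the number of sites.
#' @param linkage `"complete"` (default) or `"average"`.
#' @return Integer cluster labels named by site id.
#' @export
cluster_sites <- function(dist, n_clusters, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  n <- attr(dist, "Size")
  if (n_clusters < 1L || n_clusters > n) {
    stop("n_clusters must lie between 1 and ", n, call. = FALSE)
  }
  hc <- stats::hclust(dist, method = linkage)
  stats::cutree(hc, k = n_clusters)
}

#' Sample one representative site per cluster
#'
#' Uniform random draw within each cluster, reproducible under the seed;
#' the drawn sites form the image subset one expert views.
#'
#' @param labels Cluster labels named by site id (from [cluster_sites()]).
#' @param seed Integer seed.
#' @return Character vector of site ids, one per cluster, ordered by
#'   cluster label.
#' @export
sample_image_subset <- function(labels, seed = 1L) {
  if (is.null(names(labels))) {
    stop("labels must be named by site id", call. = FALSE)
  }
  with_seed(seed, {
    vapply(
      split(names(labels), labels),
      function(ids) ids[sample.int(length(ids), 1L)],
      character(1)
    )
  })
}
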