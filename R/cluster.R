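#' Cluster networks across atlases by spatial similarity
#'
#' Symmetrizes the (possibly non-symmetric) all-network Dice similarity
#' matrix as `(S + t(S)) / 2`, converts it to the distance `1 - S`, and runs
#' average-linkage agglomerative clustering, cutting the dendrogram at
#' `n_clusters`. The default cluster count mirrors the convention of using
#' the average number of networks across the input atlases. Deterministic:
#' merge-distance ties resolve by the lowest pair index (the `hclust`
#' convention).
#'
#' @param similarity square numeric matrix with entries in `[0, 1]`,
#'   ideally from [stack_similarity()] (its `network_ids` attribute is
#'   carried along when present).
#' @param n_clusters number of clusters, between 1 and the matrix side.
#' @return An object of class `cluster_assignment`: `network_ids` data
#'   frame, `cluster_labels` (1..n_clusters, every cluster nonempty),
#'   `n_clusters`, and the `hclust` merge history in `$linkage`.
#' @export
cluster_networks <- function(similarity, n_clusters) {
  m <- unclass(as.matrix(similarity))
  if (nrow(m) != ncol(m)) stopf("similarity matrix must be square")
  if (anyNA(m) || min(m) < 0 || max(m) > 1)
    stopf("similarity entries must lie in [0, 1] with no missing values")
  if (!is_count(n_clusters, min = 1L) || n_clusters > nrow(m))
    stopf("n_clusters must be an integer in 1..%d", nrow(m))
  s_sym <- (m + t(m)) / 2
  d <- as.dist(1 - s_sym)
  hc <- hclust(d, method = "average")
  labels <- unname(cutree(hc, k = n_clusters))
  ids <- attr(similarity, "network_ids")
  if (is.null(ids)) {
    nm <- rownames(m) %||% paste0("item", seq_len(nrow(m)))
    split_nm <- strsplit(nm, "::", fixed = TRUE)
    ids <- data.frame(
      atlas = vapply(split_nm, function(p) if (length(p) > 1L) p[[1L]] else "atlas",
                     character(1L)),
      network = vapply(split_nm, function(p) p[[length(p)]], character(1L)),
      stringsAsFactors = FALSE)
  }
  structure(list(network_ids = ids, cluster_labels = labels,
                 n_clusters = as.integer(n_clusters), linkage = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d networks from %d atlases into %d clusters\n",
              length(x$cluster_labels), length(unique(x$network_ids$atlas)),
              x$n_clusters))
  print(table(cluster = x$cluster_labels))
  invisible(x)
}

#' Default cluster count: rounded mean network count across atlases
#'
#' @param atlases list of [atlas()] objects.
#' @return Integer.
#' @export
default_n_clusters <- function(atlases) {
  as.integer(round(mean(vapply(atlases, function(a) length(a$network_names),
                               integer(1L)))))
}

#' Export a cluster dendrogram as a Newick tree
#'
#' @param assignment a [cluster_networks()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  hc <- assignment$linkage
  hc$labels <- paste(assignment$network_ids$atlas,
                     assignment$network_ids$network, sep = ".")
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Per-cluster cross-atlas probability maps
#'
#' For each cluster, the value at a vertex is the fraction of contributing
#' atlases that assign that vertex to any network belonging to the cluster
#' (each atlas counted at most once per vertex); warmer values mean greater
#' concordance across atlases. Medial-wall vertices are 0. An atlas
#' contributes to a cluster's denominator if it has at least one member
#' network in it.
#'
#' @param assignment a [cluster_networks()] result.
#' @param atlases list of [atlas()] objects, all resampled to `mesh`.
#' @param mesh the common [sphere_mesh()].
#' @return List of `probability_map` objects (one per cluster): `values` in
#'   `[0, 1]`, `cluster_id`, `n_contributing_atlases`.
#' @export
cluster_probability_maps <- function(assignment, atlases, mesh) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(mesh, "sphere_mesh"))
  by_name <- setNames(atlases, vapply(atlases, `[[`, character(1L), "name"))
  nv <- n_locations(mesh)
  lapply(seq_len(assignment$n_clusters), function(cl) {
    members <- which(assignment$cluster_labels == cl)
    mem_atl <- assignment$network_ids$atlas[members]
    counts <- integer(nv)
    for (anm in unique(mem_atl)) {
      atl <- by_name[[anm]]
      if (is.null(atl)) stopf("cluster member atlas '%s' not supplied", anm)
      nets <- assignment$network_ids$network[members][mem_atl == anm]
      miss <- setdiff(nets, atl$network_names)
      if (length(miss))
        stopf("network '%s' not found in atlas '%s'", miss[[1L]], anm)
      if (length(atl$label_map$values) != nv)
        stopf("atlas '%s' is not on the target mesh (resample first)", anm)
      labs <- atl$labels[match(nets, atl$network_names)]
      counts <- counts + (atl$label_map$values %in% labs)
    }
    vals <- counts / length(unique(mem_atl))
    vals[!mesh$cortex_mask] <- 0
    structure(list(values = vals, cluster_id = cl,
                   n_contributing_atlases = length(unique(mem_atl))),
              class = "probability_map")
  })
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> cluster %d over %d atlases; coverage %.1f%%, max %.2f\n",
              x$cluster_id, x$n_contributing_atlases,
              100 * mean(x$values > 0), max(x$values)))
  invisible(x)
}

#' Reorder a similarity matrix by cluster assignment
#'
#' Rows and columns are grouped by cluster id, ordered within a cluster by
#' atlas name then network name; cluster boundary indices are returned for
#' block overlays in heatmap renderings.
#'
#' @param similarity square matrix (same side as the assignment).
#' @param assignment a [cluster_networks()] result.
#' @return List with `matrix` (the permuted similarity), `order` (the
#'   permutation applied) and `boundaries` (last index of each cluster
#'   block).
#' @export
reorder_similarity <- function(similarity, assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  m <- as.matrix(similarity)
  if (nrow(m) != length(assignment$cluster_labels))
    stopf("similarity side (%d) does not match assignment size (%d)",
          nrow(m), length(assignment$cluster_labels))
  ord <- order(assignment$cluster_labels, assignment$network_ids$atlas,
               assignment$network_ids$network)
  sizes <- table(assignment$cluster_labels)
  list(matrix = m[ord, ord, drop = FALSE], order = ord,
       boundaries = cumsum(as.integer(sizes)))
}

#' Chord-diagram edge list from clustered similarities
#'
#' Flattens the upper triangle of the symmetrized similarity into an edge
#' list (one row per network pair at or above `min_similarity`) with cluster
#' annotations, suitable for chord/graph renderers.
#'
#' @param similarity square matrix.
#' @param assignment a [cluster_networks()] result.
#' @param min_similarity drop edges below this Dice value.
#' @return Data frame `from_atlas`, `from_network`, `to_atlas`,
#'   `to_network`, `similarity`, `from_cluster`, `to_cluster`.
#' @export
chord_edges <- function(similarity, assignment, min_similarity = 0.1) {
  m <- (as.matrix(similarity) + t(as.matrix(similarity))) / 2
  ids <- assignment$network_ids
  idx <- which(upper.tri(m) & m >= min_similarity, arr.ind = TRUE)
  data.frame(
    from_atlas = ids$atlas[idx[, 1L]], from_network = ids$network[idx[, 1L]],
    to_atlas = ids$atlas[idx[, 2L]], to_network = ids$network[idx[, 2L]],
    similarity = m[idx],
    from_cluster = assignment$cluster_labels[idx[, 1L]],
    to_cluster = assignment$cluster_labels[idx[, 2L]],
    stringsAsFactors = FALSE)
}
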