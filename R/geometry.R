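#' Spherical mesh, label-map and atlas containers
#'
#' `sphere_mesh()`, `label_map()` and `atlas()` are the validating
#' constructors for the package's three core containers: a triangulated
#' unit-sphere mesh with a cortex mask (medial-wall exclusion), a per-location
#' integer network labelling with a label table (0 = unassigned/background),
#' and a named atlas wrapping a label map with its ordered network names.
#'
#' @param vertices numeric n x 3 matrix of unit-length vertex coordinates.
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param hemisphere one of `"left"`, `"right"`, `"both"`.
#' @param cortex_mask logical vector, one entry per vertex; `FALSE` marks the
#'   medial wall / excluded locations.
#' @param space_id character space identifier (e.g. `"ico4_left"`).
#' @return An object of class `sphere_mesh`.
#' @seealso [build_icosphere()]
#' @export
sphere_mesh <- function(vertices, triangles, hemisphere = "left",
                        cortex_mask = NULL, space_id = "custom") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stopf("`vertices` must be an n x 3 matrix")
  nrm <- sqrt(rowSums(vertices^2))
  if (any(abs(nrm - 1) > 1e-9))
    stopf("vertex coordinates must have unit norm (max deviation %.2e)",
          max(abs(nrm - 1)))
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L) stopf("`triangles` must be an m x 3 matrix")
  if (nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > nrow(vertices))
      stopf("triangle indices out of range")
    if (any(triangles[, 1L] == triangles[, 2L] |
            triangles[, 1L] == triangles[, 3L] |
            triangles[, 2L] == triangles[, 3L]))
      stopf("degenerate triangles (repeated vertex index)")
  }
  hemisphere <- match.arg(hemisphere, c("left", "right", "both"))
  if (is.null(cortex_mask)) cortex_mask <- rep(TRUE, nrow(vertices))
  cortex_mask <- as.logical(cortex_mask)
  if (length(cortex_mask) != nrow(vertices))
    stopf("`cortex_mask` length (%d) != vertex count (%d)",
          length(cortex_mask), nrow(vertices))
  structure(
    list(vertices = vertices, triangles = triangles, hemisphere = hemisphere,
         cortex_mask = cortex_mask, space_id = space_id),
    class = "sphere_mesh")
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat(sprintf("<sphere_mesh '%s'> %d vertices, %d triangles, hemisphere=%s, %d cortical (%.1f%%)\n",
              x$space_id, nrow(x$vertices), nrow(x$triangles), x$hemisphere,
              sum(x$cortex_mask), 100 * mean(x$cortex_mask)))
  invisible(x)
}

#' Number of locations (vertices) of a mesh
#' @param mesh a [sphere_mesh()].
#' @return Integer vertex count.
#' @export
n_locations <- function(mesh) nrow(mesh$vertices)

#' @param values integer vector of per-location labels; 0 means unassigned.
#' @param label_table named character vector mapping label (as name, e.g.
#'   `"1"`) to network name; must cover every nonzero value.
#' @rdname sphere_mesh
#' @export
label_map <- function(values, space_id, label_table = NULL) {
  values <- as.integer(values)
  if (anyNA(values)) stopf("label values must be non-missing integers")
  if (any(values < 0L)) stopf("label values must be non-negative")
  lev <- sort(unique(values[values > 0L]))
  if (is.null(label_table))
    label_table <- setNames(paste0("net_", lev), as.character(lev))
  label_table <- setNames(as.character(label_table), names(label_table))
  missing_lab <- setdiff(as.character(lev), names(label_table))
  if (length(missing_lab))
    stopf("labels without a label_table entry: %s",
          paste(missing_lab, collapse = ", "))
  structure(list(values = values, space_id = space_id,
                 label_table = label_table),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  k <- length(unique(x$values[x$values > 0L]))
  cat(sprintf("<label_map on '%s'> %d locations, %d networks, %d unassigned\n",
              x$space_id, length(x$values), k, sum(x$values == 0L)))
  invisible(x)
}

#' @param name atlas identifier.
#' @param map a `label_map`.
#' @param network_names optional ordered network names, one per nonzero label;
#'   defaults to the map's label table in label order.
#' @param source_space space the atlas is natively defined on.
#' @rdname sphere_mesh
#' @export
atlas <- function(name, map, network_names = NULL, source_space = map$space_id) {
  stopifnot(inherits(map, "label_map"))
  lev <- sort(unique(map$values[map$values > 0L]))
  if (is.null(network_names))
    network_names <- unname(map$label_table[as.character(lev)])
  if (length(network_names) != length(lev))
    stopf("atlas '%s': %d network names for %d nonzero labels",
          name, length(network_names), length(lev))
  if (anyDuplicated(network_names))
    stopf("atlas '%s': duplicated network names", name)
  structure(list(name = name, label_map = map, network_names = network_names,
                 labels = lev, source_space = source_space),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("<atlas '%s'> %d networks on '%s': %s\n", x$name,
              length(x$network_names), x$source_space,
              paste(head(x$network_names, 6L), collapse = ", ")))
  invisible(x)
}

# base icosahedron: 12 vertices / 20 faces, projected to the unit sphere
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = unitize(v), triangles = f)
}

# one 4-to-1 subdivision step: split every edge at its midpoint, reproject
subdivide_once <- function(v, f) {
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  uk <- !duplicated(key)
  eu <- e[uk, , drop = FALSE]
  mid_id <- nrow(v) + match(key, key[uk])
  mid <- unitize((v[eu[, 1L], , drop = FALSE] + v[eu[, 2L], , drop = FALSE]) / 2)
  nf <- nrow(f)
  a <- mid_id[seq_len(nf)]                # midpoint of (1,2)
  b <- mid_id[nf + seq_len(nf)]           # midpoint of (2,3)
  c_ <- mid_id[2L * nf + seq_len(nf)]     # midpoint of (1,3)
  list(vertices = rbind(v, mid),
       triangles = rbind(cbind(f[, 1L], a, c_),
                         cbind(f[, 2L], b, a),
                         cbind(f[, 3L], c_, b),
                         cbind(a, b, c_)))
}

#' Build a geodesic icosphere mesh
#'
#' Repeated 4-to-1 subdivision of the regular icosahedron, projected to the
#' unit sphere; vertex and face counts follow `V(s) = 10 * 4^s + 2` and
#' `F(s) = 20 * 4^s`. Serves as a stand-in for registration spheres such as
#' fsaverage6 (subdivisions 6 gives 40,962 vertices, the fsaverage6 count).
#' A contiguous south-polar cap of roughly `medial_wall_frac` of the vertices
#' is flagged non-cortical to emulate the medial wall.
#'
#' @inheritParams sphere_mesh
#' @param subdivisions non-negative integer number of subdivision steps
#'   (at most 7).
#' @param medial_wall_frac fraction of vertices (a south-polar cap) flagged
#'   non-cortical; set 0 for an all-cortical sphere.
#' @return A [sphere_mesh()] with `space_id` `"ico<subdivisions>_<hemisphere>"`.
#' @examples
#' m <- build_icosphere(2)
#' nrow(m$vertices)  # 162
#' @export
build_icosphere <- function(subdivisions, hemisphere = "left",
                            medial_wall_frac = 0.05) {
  if (!is_count(subdivisions)) stopf("`subdivisions` must be a non-negative integer")
  if (subdivisions > 7L) stopf("`subdivisions` must be <= 7 (got %d)", subdivisions)
  hemisphere <- match.arg(hemisphere, c("left", "right", "both"))
  ico <- icosahedron()
  for (i in seq_len(subdivisions)) ico <- subdivide_once(ico$vertices, ico$triangles)
  v <- unitize(ico$vertices)
  mask <- rep(TRUE, nrow(v))
  if (medial_wall_frac > 0) {
    n_wall <- max(1L, round(medial_wall_frac * nrow(v)))
    wall <- order(v[, 3L])[seq_len(n_wall)]  # lowest-z polar cap
    mask[wall] <- FALSE
  }
  sphere_mesh(v, ico$triangles, hemisphere, mask,
              space_id = sprintf("ico%d_%s", subdivisions, hemisphere))
}

#' Nearest mesh vertex for arbitrary query points
#'
#' Queries are normalized onto the unit sphere; each returns the index of the
#' mesh vertex minimizing Euclidean distance, with exact-distance ties broken
#' by the lowest vertex index. Backed by a pruned exact search in C++.
#'
#' @param mesh a [sphere_mesh()].
#' @param query_points numeric q x 3 matrix (or length-3 vector) of nonzero
#'   query vectors.
#' @return Integer vector of 1-based vertex indices, one per query.
#' @export
nearest_vertex <- function(mesh, query_points) {
  stopifnot(inherits(mesh, "sphere_mesh"))
  if (is.null(dim(query_points))) query_points <- matrix(query_points, ncol = 3L)
  query_points <- as.matrix(query_points)
  if (ncol(query_points) != 3L) stopf("query points must be 3-vectors")
  storage.mode(query_points) <- "double"
  if (nrow(mesh$vertices) == 0L) stopf("mesh has no vertices")
  .nn_index_cpp(unitize(query_points), mesh$vertices)
}

#' Resample a label map between spherical meshes
#'
#' Nearest-neighbour label projection: each target vertex receives the label
#' of its nearest source vertex. Target vertices outside the target cortex
#' mask, and targets whose nearest source vertex is non-cortical, receive 0
#' (unassigned). The label table is carried over unchanged.
#'
#' @param source_mesh,target_mesh [sphere_mesh()] objects with the same
#'   hemisphere tag.
#' @param labels a [label_map()] living on `source_mesh`.
#' @return A [label_map()] on `target_mesh`.
#' @export
resample_labels <- function(source_mesh, labels, target_mesh) {
  stopifnot(inherits(source_mesh, "sphere_mesh"),
            inherits(labels, "label_map"),
            inherits(target_mesh, "sphere_mesh"))
  if (length(labels$values) != n_locations(source_mesh))
    stopf("label map length (%d) does not match source mesh (%d)",
          length(labels$values), n_locations(source_mesh))
  if (source_mesh$hemisphere != target_mesh$hemisphere)
    stopf("hemisphere mismatch: source '%s' vs target '%s'",
          source_mesh$hemisphere, target_mesh$hemisphere)
  if (identical(source_mesh$space_id, target_mesh$space_id) &&
      n_locations(source_mesh) == n_locations(target_mesh))
    return(label_map(ifelse(target_mesh$cortex_mask, labels$values, 0L),
                     target_mesh$space_id, labels$label_table))
  idx <- nearest_vertex(source_mesh, target_mesh$vertices)
  vals <- labels$values[idx]
  vals[!target_mesh$cortex_mask | !source_mesh$cortex_mask[idx]] <- 0L
  label_map(vals, target_mesh$space_id, labels$label_table)
}

#' Generate a synthetic network atlas on a sphere
#'
#' Draws `n_networks` seed vertices uniformly from the cortical vertices and
#' assigns every cortical vertex to its nearest seed (a spherical Voronoi
#' parcellation). With `jitter > 0` each seed is first displaced along a
#' random tangent direction by `jitter` radians, so repeated calls with the
#' same `seed` but different jitter produce correlated atlas variants —
#' useful for emulating families of related published atlases. Medial-wall
#' vertices stay unassigned (label 0). Deterministic given `(seed, jitter)`.
#'
#' @param mesh a [sphere_mesh()].
#' @param n_networks number of networks (at most the cortical vertex count).
#' @param seed RNG seed.
#' @param jitter non-negative angular seed perturbation in radians.
#' @param variant optional integer: draws the jitter directions from a
#'   sub-stream derived from `(seed, variant)`, so several distinct but
#'   correlated variants of one template (same `seed`) can be generated.
#' @param name atlas name.
#' @return An [atlas()] on `mesh`'s space.
#' @export
generate_synthetic_atlas <- function(mesh, n_networks, seed, jitter = 0,
                                     variant = NULL,
                                     name = sprintf("synth%d", seed)) {
  stopifnot(inherits(mesh, "sphere_mesh"))
  if (!is_count(n_networks, min = 1L)) stopf("`n_networks` must be a positive integer")
  if (jitter < 0) stopf("`jitter` must be non-negative")
  ctx <- which(mesh$cortex_mask)
  if (n_networks > length(ctx))
    stopf("n_networks (%d) exceeds cortical vertex count (%d)",
          n_networks, length(ctx))
  pick <- with_seed(seed, sample(ctx, n_networks))
  seeds <- mesh$vertices[pick, , drop = FALSE]
  if (jitter > 0) {
    jseed <- if (is.null(variant)) seed
             else (as.integer(seed) %% 48611L) * 44159L + as.integer(variant)
    seeds <- with_seed(jseed, {
      if (is.null(variant)) sample(ctx, n_networks)  # replay the pick draw
      # random unit tangent at each seed, then rotate by `jitter` towards it
      r <- matrix(rnorm(3L * n_networks), ncol = 3L)
      tang <- unitize(r - seeds * rowSums(r * seeds))
      unitize(cos(jitter) * seeds + sin(jitter) * tang)
    })
  }
  vals <- integer(n_locations(mesh))
  vals[ctx] <- .nn_index_cpp(mesh$vertices[ctx, , drop = FALSE], seeds)
  atlas(name,
        label_map(vals, mesh$space_id,
                  setNames(paste0(name, "_net", seq_len(n_networks)),
                           as.character(seq_len(n_networks)))),
        source_space = mesh$space_id)
}

#' Read a precomputed location correspondence table
#'
#' Two-column whitespace/comma-separated plain text of 0-based indices
#' `(source_index, target_index)`, one row per target location. This is the
#' pluggable alternative to nonlinear template-to-template registration:
#' any externally computed surface-to-surface or volume-to-surface mapping
#' can be supplied this way.
#'
#' @param path file path.
#' @return Integer matrix with columns `source`, `target` (1-based).
#' @export
read_correspondence_table <- function(path) {
  if (!file.exists(path)) stopf("correspondence table not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("source", "target"))
  if (ncol(tab) != 2L || !all(tab >= 0L))
    stopf("correspondence table must have two non-negative 0-based columns")
  m <- as.matrix(tab) + 1L
  storage.mode(m) <- "integer"
  m
}

#' Project values through a correspondence table
#'
#' Applies a precomputed location mapping: target location `t` receives the
#' value at source location `s` for every `(s, t)` row; unmapped targets get
#' `fill` (0 for labels, `NA` for metrics).
#'
#' @param values numeric or integer source values.
#' @param table correspondence matrix from [read_correspondence_table()].
#' @param n_target number of target locations.
#' @param fill value for unmapped targets.
#' @return Vector of length `n_target`.
#' @export
project_with_table <- function(values, table, n_target,
                               fill = if (is.integer(values)) 0L else NA_real_) {
  if (max(table[, "source"]) > length(values))
    stopf("table source index %d exceeds source length %d",
          max(table[, "source"]), length(values))
  if (max(table[, "target"]) > n_target)
    stopf("table target index %d exceeds n_target %d",
          max(table[, "target"]), n_target)
  out <- rep(fill, n_target)
  out[table[, "target"]] <- values[table[, "source"]]
  out
}
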