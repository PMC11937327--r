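#' Sample uniform random rotations for the spin test
#'
#' Draws `n` rotations uniformly from SO(3) by QR-orthonormalizing a
#' standard-normal 3 x 3 draw, fixing the signs of the triangular factor's
#' diagonal, and correcting the determinant to +1. Each rotation's mirrored
#' partner `X R X` (with `X = diag(-1, 1, 1)`, a reflection across the
#' midsagittal x = 0 plane) is stored for contralateral-hemisphere use, so a
#' single permutation applies a bilaterally symmetric spin.
#'
#' @param n number of rotations (the permutation count; 1000 by default
#'   downstream).
#' @param seed RNG seed; regeneration with the same `(n, seed)` reproduces
#'   the set exactly.
#' @return An object of class `rotation_set`: list with `rotations` and
#'   `mirrored` (3 x 3 x n arrays), `n`, `seed`.
#' @export
sample_rotations <- function(n, seed = 1L) {
  if (!is_count(n, min = 1L)) stopf("`n` must be a positive integer")
  rot <- with_seed(seed, {
    out <- array(NA_real_, c(3L, 3L, n))
    for (i in seq_len(n)) {
      qrd <- qr(matrix(rnorm(9L), 3L, 3L))
      q <- qr.Q(qrd)
      q <- q %*% diag(sign(diag(qr.R(qrd))))
      if (det(q) < 0) q[, 3L] <- -q[, 3L]
      out[, , i] <- q
    }
    out
  })
  X <- diag(c(-1, 1, 1))
  mir <- array(NA_real_, dim(rot))
  for (i in seq_len(n)) mir[, , i] <- X %*% rot[, , i] %*% X
  structure(list(rotations = rot, mirrored = mir, n = n, seed = seed),
            class = "rotation_set")
}

#' @export
print.rotation_set <- function(x, ...) {
  cat(sprintf("<rotation_set> %d uniform rotations (seed %s), mirrored pairs stored\n",
              x$n, format(x$seed)))
  invisible(x)
}

check_rotation <- function(rotation, tol = 1e-8) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stopf("rotation must be a 3 x 3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stopf("matrix is not orthogonal within tolerance %g", tol)
  if (abs(det(rotation) - 1) > tol)
    stopf("matrix is not a proper rotation (det = %.6f)", det(rotation))
  rotation
}

# Source-vertex index for every mesh vertex under one rotation: value at
# target v is taken from the source vertex nearest to R^-1 v.  Entries are 0
# where the target is non-cortical or the nearest source vertex is
# non-cortical.  On a "both"-hemisphere mesh the mirrored rotation is applied
# to the right side (x >= 0), keeping the spin bilaterally symmetric.
rotation_source_index <- function(mesh, rotation, mirrored = NULL) {
  v <- mesh$vertices
  q <- v %*% rotation          # row form of R^-1 v for orthogonal R
  if (mesh$hemisphere == "both" && !is.null(mirrored)) {
    right <- v[, 1L] >= 0
    q[right, ] <- v[right, , drop = FALSE] %*% mirrored
  }
  idx <- .nn_index_cpp(q, v)
  idx[!mesh$cortex_mask | !mesh$cortex_mask[idx]] <- 0L
  idx
}

#' Rotate a map over its spherical mesh
#'
#' Nearest-neighbour remap under a rotation of the sphere: the value at each
#' target vertex is taken from the source vertex nearest to the back-rotated
#' target coordinate. Vertices whose source lands on the medial wall become
#' unassigned (0 for labels, `FALSE` for masks, `NA` for metrics).
#'
#' @param map a [label_map()], [metric_map()], or logical mask on `mesh`.
#' @param mesh the [sphere_mesh()] the map lives on.
#' @param rotation proper 3 x 3 rotation matrix (checked).
#' @param mirrored optional mirrored rotation for the right side of a
#'   `"both"`-hemisphere mesh.
#' @return A map of the same type as the input.
#' @export
rotate_map <- function(map, mesh, rotation, mirrored = NULL) {
  stopifnot(inherits(mesh, "sphere_mesh"))
  rotation <- check_rotation(rotation)
  idx <- rotation_source_index(mesh, rotation, mirrored)
  ok <- idx > 0L
  if (inherits(map, "label_map")) {
    vals <- integer(length(idx))
    vals[ok] <- map$values[idx[ok]]
    label_map(vals, map$space_id, map$label_table)
  } else if (inherits(map, "metric_map")) {
    vals <- rep(NA_real_, length(idx))
    vals[ok] <- map$values[idx[ok]]
    metric_map(vals, map$space_id)
  } else if (is.logical(map)) {
    if (length(map) != n_locations(mesh))
      stopf("mask length (%d) does not match mesh (%d)",
            length(map), n_locations(mesh))
    out <- logical(length(idx))
    out[ok] <- map[idx[ok]]
    out
  } else stopf("`map` must be a label_map, metric_map, or logical mask")
}

#' Spin-test p-value from observed and null Dice values
#'
#' The permutation p-value convention: the number of rotations whose Dice
#' coefficient is strictly larger than the observed one, divided by the
#' total number of rotations (so the minimum attainable p is 0). The
#' `"plus-one"` variant computes the conservative `(c + 1) / (N + 1)`.
#'
#' @param observed observed Dice coefficient.
#' @param null numeric vector of null (rotated) Dice coefficients.
#' @param variant `"paper"` (strict, `/N`) or `"plus-one"`.
#' @return A p-value in `[0, 1]`.
#' @examples
#' spin_pvalue(0.5, c(0.6, 0.4, 0.3, 0.2))  # 1/4
#' @export
spin_pvalue <- function(observed, null, variant = c("paper", "plus-one")) {
  variant <- match.arg(variant)
  if (!length(null)) stopf("empty null distribution")
  c_ <- sum(null > observed)
  if (variant == "paper") c_ / length(null) else (c_ + 1) / (length(null) + 1)
}

#' Type-I calibration of the spin test under a rotation-generated null
#'
#' Simulates the spin test's own null model: in each replicate the input
#' data mask is a uniformly rotated copy of `template_mask` — spatially
#' unrelated to the target network by construction — and its overlap is
#' tested against a fresh `n_rotations`-permutation null. The rotated
#' data mask's observed Dice is computed under the same remap-and-exclude
#' convention as the null draws (it is the first of `n_rotations + 1`
#' independent spins), so the observed and null statistics are exactly
#' exchangeable and the returned p-values are uniform up to the
#' discreteness of the `1/N` lattice. The fraction below 0.05 should be
#' close to the nominal rate.
#'
#' @param mesh a [sphere_mesh()].
#' @param template_mask logical mask rotated to generate null data.
#' @param network_mask logical target-network mask (defaults to the
#'   template itself).
#' @param n_rotations permutations per spin test.
#' @param n_replicates number of simulated null data sets.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param variant p-value convention, see [spin_pvalue()].
#' @return Numeric vector of `n_replicates` p-values.
#' @export
spin_calibration <- function(mesh, template_mask,
                             network_mask = template_mask,
                             n_rotations = 200L, n_replicates = 200L,
                             seed = 1L, variant = "paper") {
  stopifnot(inherits(mesh, "sphere_mesh"))
  sub_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max, n_replicates))
  vapply(seq_len(n_replicates), function(r) {
    rot <- sample_rotations(n_rotations + 1L, seed = sub_seeds[r])
    d <- spin_test(template_mask, network_mask, mesh, rot,
                   variant = variant)$null_dice
    # first rotation generates the data mask; the rest form its null
    spin_pvalue(d[1L], d[-1L], variant = variant)
  }, numeric(1L))
}

#' Spin-test a single Dice overlap
#'
#' Permutation test of the spatial overlap between a data mask and one
#' network mask: the data mask is rotated by each member of `rotations` and
#' the Dice coefficient recomputed, giving a spatial null that preserves the
#' map's autocorrelation. The p-value is the number of rotations whose Dice
#' exceeds the observed value, divided by the number of rotations (strict
#' inequality; `variant = "plus-one"` gives the conservative
#' `(c + 1) / (N + 1)` alternative).
#'
#' @param data_mask,network_mask logical masks on `mesh`.
#' @param mesh the [sphere_mesh()].
#' @param rotations a [sample_rotations()] set.
#' @param variant p-value convention.
#' @return An object of class `spin_result`: `observed_dice`, `null_dice`
#'   (length N), `p_value`.
#' @export
spin_test <- function(data_mask, network_mask, mesh, rotations,
                      variant = c("paper", "plus-one")) {
  stopifnot(inherits(rotations, "rotation_set"))
  variant <- match.arg(variant)
  if (rotations$n < 1L) stopf("empty rotation set")
  keep <- mesh$cortex_mask
  observed <- dice_coefficient(data_mask[keep], network_mask[keep])
  null_dice <- vapply(seq_len(rotations$n), function(i) {
    idx <- rotation_source_index(mesh, rotations$rotations[, , i],
                                 rotations$mirrored[, , i])
    # vertices whose rotated source is off-cortex carry no information and
    # are excluded from both masks, not counted as absent
    valid <- keep & idx > 0L
    rot <- logical(length(idx))
    rot[valid] <- data_mask[idx[valid]]
    dice_coefficient(rot[valid], network_mask[valid])
  }, numeric(1L))
  structure(list(observed_dice = observed, null_dice = null_dice,
                 p_value = spin_pvalue(observed, null_dice, variant)),
            class = "spin_result")
}

#' @export
print.spin_result <- function(x, ...) {
  cat(sprintf("<spin_result> observed Dice %.4f vs %d-rotation null (mean %.4f): p = %.4g\n",
              x$observed_dice, length(x$null_dice), mean(x$null_dice), x$p_value))
  invisible(x)
}

#' Overlap matrix with spin-test p-values
#'
#' Computes the (data mask) x (atlas network) Dice matrix together with a
#' spin-test p-value per cell. One rotation set is shared across all cells,
#' so every (row, column) test sees the same spatial null. Data and atlas
#' must live on the same surface mesh; volumetric inputs must first be
#' projected to a surface (see [project_with_table()]).
#'
#' @param data named list of logical data masks (or a single mask).
#' @param atl an [atlas()] in the mesh's space.
#' @param mesh the [sphere_mesh()].
#' @param n number of rotations (default 1000).
#' @param seed RNG seed for the rotation set.
#' @param alpha significance level recorded with the result (default 0.05).
#' @param variant p-value convention, see [spin_test()].
#' @param rotations optional pre-sampled [sample_rotations()] set (overrides
#'   `n`/`seed`), so several atlases can share one null.
#' @return An `overlap_matrix` with `attr(, "p_values")`.
#' @export
spin_test_matrix <- function(data, atl, mesh, n = 1000L, seed = 1L,
                             alpha = 0.05, variant = c("paper", "plus-one"),
                             rotations = NULL) {
  stopifnot(inherits(atl, "atlas"), inherits(mesh, "sphere_mesh"))
  variant <- match.arg(variant)
  if (is.logical(data)) data <- list(input = data)
  if (!length(data) || is.null(names(data)))
    stopf("`data` must be a named list of logical masks")
  nv <- n_locations(mesh)
  for (d in data)
    if (!is.logical(d) || length(d) != nv)
      stopf("every data mask must be logical of length %d", nv)
  if (length(atl$label_map$values) != nv)
    stopf("atlas '%s' is not in the mesh space '%s' (%d vs %d locations); project it first",
          atl$name, mesh$space_id, length(atl$label_map$values), nv)
  if (is.null(rotations)) rotations <- sample_rotations(n, seed)
  keep <- mesh$cortex_mask
  lev <- setNames(atl$labels, atl$network_names)
  observed <- dice_masks_vs_labels(data, atl$label_map$values, keep, lev)
  exceed <- matrix(0L, nrow(observed), ncol(observed))
  for (i in seq_len(rotations$n)) {
    idx <- rotation_source_index(mesh, rotations$rotations[, , i],
                                 rotations$mirrored[, , i])
    # targets whose rotated source is off-cortex are dropped from the Dice
    # computation entirely (both masks), not treated as absent
    valid <- keep & idx > 0L
    rot_masks <- lapply(data, function(d) {
      out <- logical(nv); out[valid] <- d[idx[valid]]; out
    })
    null_d <- dice_masks_vs_labels(rot_masks, atl$label_map$values, valid, lev)
    exceed <- exceed + (null_d > observed)
  }
  pv <- if (variant == "paper") exceed / rotations$n
        else (exceed + 1) / (rotations$n + 1)
  dimnames(pv) <- dimnames(observed)
  new_overlap_matrix(observed, "input_data", atl$name,
                     p_values = pv, alpha = alpha)
}
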