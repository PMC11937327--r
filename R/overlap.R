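#' Dice coefficient between two location sets
#'
#' `2|A n B| / (|A| + |B|)`: 0 is no spatial correspondence, 1 is total
#' correspondence. Both masks must be drawn from the same space with
#' non-cortical locations already removed; two empty masks give 0 by
#' convention.
#'
#' @param mask_a,mask_b integer index vectors, or logical masks of equal
#'   length.
#' @return A number in `[0, 1]`.
#' @examples
#' dice_coefficient(c(1, 2, 3), c(2, 3, 4))  # 2*2/(3+3)
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (is.logical(mask_a) || is.logical(mask_b)) {
    if (!is.logical(mask_a) || !is.logical(mask_b) ||
        length(mask_a) != length(mask_b))
      stopf("logical masks must both be logical and of equal length")
    na <- sum(mask_a); nb <- sum(mask_b)
    inter <- sum(mask_a & mask_b)
  } else {
    mask_a <- unique(as.integer(mask_a)); mask_b <- unique(as.integer(mask_b))
    na <- length(mask_a); nb <- length(mask_b)
    inter <- length(intersect(mask_a, mask_b))
  }
  if (na + nb == 0L) return(0)
  2 * inter / (na + nb)
}

new_overlap_matrix <- function(values, reference_atlas, other_atlas,
                               p_values = NULL, alpha = NULL) {
  structure(values, class = c("overlap_matrix", "matrix"),
            reference_atlas = reference_atlas, other_atlas = other_atlas,
            p_values = p_values, alpha = alpha)
}

#' @export
print.overlap_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<overlap_matrix> reference '%s' (%d networks) vs '%s' (%d networks)%s\n",
              attr(x, "reference_atlas"), nrow(x), attr(x, "other_atlas"), ncol(x),
              if (is.null(attr(x, "p_values"))) "" else ", with spin-test p-values"))
  v <- matrix(as.vector(x), nrow(x), ncol(x), dimnames = dimnames(x))
  print(round(v, digits), ...)
  invisible(x)
}

# Dice matrix between the masks listed in `rows` (named list of logical
# masks) and the nonzero labels of `labels_other`, over locations where
# `keep` is TRUE.  Vectorized through tabulate().
dice_masks_vs_labels <- function(rows, labels_other, keep, other_levels) {
  lv <- labels_other[keep]
  nK <- length(other_levels)
  code <- match(lv, other_levels)          # NA for background / other labels
  n_m <- tabulate(code, nbins = nK)
  out <- matrix(0, nrow = length(rows), ncol = nK,
                dimnames = list(names(rows), names(other_levels) %||% NULL))
  for (i in seq_along(rows)) {
    r <- rows[[i]][keep]
    n_k <- sum(r)
    joint <- tabulate(code[r], nbins = nK)
    denom <- n_k + n_m
    out[i, ] <- ifelse(denom == 0L, 0, 2 * joint / denom)
  }
  out
}

atlas_masks <- function(atl) {
  v <- atl$label_map$values
  setNames(lapply(atl$labels, function(l) v == l), atl$network_names)
}

#' K x M network overlap matrix between a reference and another atlas
#'
#' Row `k`, column `m` holds the Dice coefficient between network `k` of the
#' reference and network `m` of the other atlas, computed over cortical
#' locations of the reference space. The other atlas must already live in
#' the reference space (see [resample_labels()]): the input-data space is
#' always treated as the reference space and atlases are projected into it.
#'
#' @param reference an [atlas()] or a named list of logical masks (rows).
#' @param other an [atlas()] in the same space.
#' @param space the reference-space [sphere_mesh()] (supplies the cortex
#'   mask); `NULL` to use all locations.
#' @return An `overlap_matrix` (matrix subclass with atlas annotations).
#' @export
overlap_matrix <- function(reference, other, space = NULL) {
  stopifnot(inherits(other, "atlas"))
  if (inherits(reference, "atlas")) {
    rows <- atlas_masks(reference)
    ref_name <- reference$name
    ref_len <- length(reference$label_map$values)
  } else {
    if (!is.list(reference) || is.null(names(reference)))
      stopf("`reference` must be an atlas or a named list of logical masks")
    rows <- reference
    ref_name <- "input_data"
    ref_len <- length(rows[[1L]])
  }
  if (length(other$label_map$values) != ref_len)
    stopf("space mismatch: reference has %d locations, other atlas '%s' has %d (project it first)",
          ref_len, other$name, length(other$label_map$values))
  keep <- if (is.null(space)) rep(TRUE, ref_len) else space$cortex_mask
  if (length(keep) != ref_len)
    stopf("space mismatch: mesh has %d locations, data has %d", length(keep), ref_len)
  vals <- dice_masks_vs_labels(rows, other$label_map$values, keep,
                               setNames(other$labels, other$network_names))
  new_overlap_matrix(vals, ref_name, other$name)
}

#' Reorder overlap-matrix columns so best matches fall on the diagonal
#'
#' Greedy assignment: reference rows are processed in descending order of
#' their row maximum; each claims its highest-Dice still-unclaimed column
#' for its diagonal position. Remaining columns are appended in original
#' order; ties break to the lowest original column index. The row order and
#' the multiset of entries are preserved.
#'
#' @param matrix an `overlap_matrix` (or plain matrix).
#' @return The column-permuted matrix, with the permutation in
#'   `attr(, "column_order")`.
#' @export
order_by_best_match <- function(matrix) {
  m <- unclass(matrix)
  K <- nrow(m); M <- ncol(m)
  claimed <- logical(M)
  claim_of_row <- rep(NA_integer_, K)
  row_order <- order(apply(m, 1L, max), decreasing = TRUE)
  for (r in row_order) {
    if (all(claimed)) break
    avail <- which(!claimed)
    best <- avail[which.max(m[r, avail])]   # which.max -> lowest index on ties
    claimed[best] <- TRUE
    claim_of_row[r] <- best
  }
  # diagonal position r holds row r's claimed column; columns claimed by rows
  # without a diagonal slot (r > M) and never-claimed columns follow in
  # original column order
  diag_cols <- claim_of_row[seq_len(min(K, M))]
  diag_cols <- diag_cols[!is.na(diag_cols)]
  perm <- c(diag_cols, setdiff(seq_len(M), diag_cols))
  out <- m[, perm, drop = FALSE]
  pv <- attr(matrix, "p_values")
  new_overlap_matrix(structure(out, column_order = perm),
                     attr(matrix, "reference_atlas") %||% "reference",
                     attr(matrix, "other_atlas") %||% "other",
                     p_values = if (!is.null(pv)) pv[, perm, drop = FALSE],
                     alpha = attr(matrix, "alpha"))
}

#' All ordered-pair correspondence matrices for a set of atlases
#'
#' For every ordered pair (reference, other) of distinct atlases, projects
#' the other atlas into the reference's space and computes the K x M overlap
#' matrix; `n` atlases yield `n * (n - 1)` matrices.
#'
#' @param atlases list of [atlas()] objects (at least 2).
#' @param spaces named list of [sphere_mesh()]es keyed by space id, covering
#'   every atlas source space.
#' @return Named list of `overlap_matrix` objects
#'   (`"<reference>__vs__<other>"`).
#' @export
all_pairs_correspondence <- function(atlases, spaces) {
  if (length(atlases) < 2L)
    stopf("need at least 2 atlases (got %d)", length(atlases))
  nms <- vapply(atlases, `[[`, character(1L), "name")
  out <- list()
  for (i in seq_along(atlases)) {
    ref <- atlases[[i]]
    ref_mesh <- spaces[[ref$source_space]]
    if (is.null(ref_mesh)) stopf("no mesh for space '%s'", ref$source_space)
    for (j in seq_along(atlases)) {
      if (i == j) next
      oth <- atlases[[j]]
      oth_proj <- if (identical(oth$source_space, ref$source_space)) oth
        else {
          src_mesh <- spaces[[oth$source_space]]
          if (is.null(src_mesh)) stopf("no mesh for space '%s'", oth$source_space)
          atlas(oth$name, resample_labels(src_mesh, oth$label_map, ref_mesh),
                network_names = oth$network_names, source_space = ref$source_space)
        }
      out[[paste0(nms[i], "__vs__", nms[j])]] <-
        overlap_matrix(ref, oth_proj, space = ref_mesh)
    }
  }
  out
}

#' Stack pairwise matrices into one all-network similarity matrix
#'
#' Builds the square network-by-network matrix over all atlases (side =
#' total network count; e.g. 16 atlases with 230 networks give a 230 x 230
#' matrix). Within-atlas blocks hold each atlas's self-comparison Dice
#' (diagonal 1); cross-atlas blocks come from the pairwise matrices. The
#' result is deliberately not symmetrized: block (i, j) is computed in atlas
#' i's space and block (j, i) in atlas j's, so the two triangles differ by
#' the choice of reference.
#'
#' @param matrices result of [all_pairs_correspondence()].
#' @param atlases the same atlas list.
#' @param spaces named list of meshes keyed by space id.
#' @return A square matrix with `atlas::network` dimnames and an
#'   `attr(, "network_ids")` data frame (`atlas`, `network`).
#' @export
stack_similarity <- function(matrices, atlases, spaces) {
  nms <- vapply(atlases, `[[`, character(1L), "name")
  counts <- vapply(atlases, function(a) length(a$network_names), integer(1L))
  offs <- cumsum(c(0L, counts))
  side <- sum(counts)
  ids <- data.frame(
    atlas = rep(nms, counts),
    network = unlist(lapply(atlases, `[[`, "network_names")),
    stringsAsFactors = FALSE)
  out <- matrix(NA_real_, side, side,
                dimnames = list(paste(ids$atlas, ids$network, sep = "::"),
                                paste(ids$atlas, ids$network, sep = "::")))
  for (i in seq_along(atlases)) {
    ri <- offs[i] + seq_len(counts[i])
    self <- overlap_matrix(atlases[[i]], atlases[[i]],
                           space = spaces[[atlases[[i]]$source_space]])
    out[ri, ri] <- unclass(self)
    for (j in seq_along(atlases)) {
      if (i == j) next
      key <- paste0(nms[i], "__vs__", nms[j])
      if (is.null(matrices[[key]]))
        stopf("missing pairwise matrix '%s'", key)
      out[ri, offs[j] + seq_len(counts[j])] <- unclass(matrices[[key]])
    }
  }
  structure(out, network_ids = ids)
}

#' Flatten overlap results into the standard summary table
#'
#' One row per (reference network / input map, other network) cell with the
#' exact Dice coefficient and, when available, the spin-test p-value.
#'
#' @param matrices an `overlap_matrix` or list of them.
#' @param alpha significance level for the `significant` column.
#' @return A data frame with columns `reference_atlas`, `reference_network`,
#'   `other_atlas`, `other_network`, `dice`, `p_value`, `significant`.
#' @export
summary_table <- function(matrices, alpha = 0.05) {
  if (inherits(matrices, "overlap_matrix")) matrices <- list(matrices)
  rows <- lapply(matrices, function(m) {
    pv <- attr(m, "p_values")
    v <- unclass(m)
    data.frame(
      reference_atlas = attr(m, "reference_atlas"),
      reference_network = rep(rownames(v) %||% paste0("row", seq_len(nrow(v))),
                              times = ncol(v)),
      other_atlas = attr(m, "other_atlas"),
      other_network = rep(colnames(v) %||% paste0("col", seq_len(ncol(v))),
                          each = nrow(v)),
      dice = as.vector(v),
      p_value = if (is.null(pv)) NA_real_ else as.vector(pv),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
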