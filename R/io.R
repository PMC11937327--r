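#' Per-location metric (continuous statistic) map
#'
#' Container for a continuous spatial statistic (e.g. a z-stat map) on a
#' surface mesh or volumetric lattice. Masked locations carry `NA`.
#'
#' @param values numeric vector; `NA`/`NaN` marks masked locations.
#' @param space_id space identifier string.
#' @return An object of class `metric_map`.
#' @export
metric_map <- function(values, space_id) {
  values <- as.numeric(values)
  values[is.nan(values)] <- NA_real_
  structure(list(values = values, space_id = space_id), class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  ok <- !is.na(x$values)
  cat(sprintf("<metric_map on '%s'> %d locations (%d masked), range [%.3g, %.3g]\n",
              x$space_id, length(x$values), sum(!ok),
              min(x$values[ok]), max(x$values[ok])))
  invisible(x)
}

file_kind <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.gii$", path)) "gifti"
  else stopf("unrecognized spatial file extension: %s", basename(path))
}

#' Load a surface or volumetric spatial data file
#'
#' Reads GIFTI label/metric files and NIfTI volumes into the package's typed
#' containers. Integer-coded label files yield a [label_map()] whose label
#' table comes from the file's name table, or synthesized `net_<k>` names.
#' Multi-array metric files yield a named list of [metric_map()]s
#' (`dim_1`, `dim_2`, ...).
#'
#' @param path file path (`.label.gii`, `.func.gii`, `.nii`, `.nii.gz`).
#' @param kind `"label"` or `"metric"`.
#' @param space_id identifier of the space the data lives on.
#' @param n_locations optional expected location count; a mismatch is a
#'   format error naming both counts.
#' @return A [label_map()], [metric_map()], or named list of metric maps.
#' @export
load_spatial_data <- function(path, kind = c("label", "metric"),
                              space_id = "unknown", n_locations = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  fmt <- file_kind(path)
  if (fmt == "gifti") {
    g <- read_gifti(path)
    vals <- g$data
    lt <- g$label_table
  } else {
    img <- RNifti::readNifti(path)
    vals <- matrix(as.numeric(img), ncol = 1L)
    lt <- NULL
  }
  if (!is.null(n_locations) && nrow(vals) != n_locations)
    stopf("location count mismatch: file '%s' has %d values, space '%s' expects %d",
          basename(path), nrow(vals), space_id, n_locations)
  if (kind == "label") {
    if (ncol(vals) != 1L) stopf("label file must contain a single data array")
    v <- vals[, 1L]
    if (anyNA(v) || any(v != round(v)) || any(v < 0))
      stopf("cannot load '%s' as labels: values are not non-negative integers",
            basename(path))
    label_map(as.integer(v), space_id, lt)
  } else {
    if (ncol(vals) == 1L) metric_map(vals[, 1L], space_id)
    else setNames(lapply(seq_len(ncol(vals)),
                         function(j) metric_map(vals[, j], space_id)),
                  paste0("dim_", seq_len(ncol(vals))))
  }
}

#' Write a label or metric map to disk
#'
#' Dispatches on file extension: `.gii` files use the GIFTI writers, `.nii` /
#' `.nii.gz` are written as NIfTI (labels as integer volumes). Volumetric
#' output reshapes the value vector to `vol_dim`.
#'
#' @param map a [label_map()] or [metric_map()].
#' @param path output path.
#' @param vol_dim integer dimensions for volumetric output.
#' @return `path`, invisibly.
#' @export
write_spatial_data <- function(map, path, vol_dim = NULL) {
  fmt <- file_kind(path)
  if (fmt == "gifti") {
    if (inherits(map, "label_map")) write_gifti_label(map, path)
    else write_gifti_metric(map$values, path)
  } else {
    v <- map$values
    dim_use <- vol_dim %||% c(length(v), 1L, 1L)
    if (prod(dim_use) != length(v))
      stopf("vol_dim %s incompatible with %d values",
            paste(dim_use, collapse = "x"), length(v))
    arr <- array(if (inherits(map, "label_map")) as.integer(v) else v, dim = dim_use)
    RNifti::writeNifti(RNifti::asNifti(arr), path,
                       datatype = if (inherits(map, "label_map")) "int32" else "float")
  }
  invisible(path)
}

config_keys <- c("name", "space", "type", "threshold", "mixture", "dimensionality")

#' Load and validate a run configuration file
#'
#' JSON with keys `name`, `space`, `type` (`"Metric"` or `"Hard"`), optional
#' `threshold`, optional logical `mixture` and optional `dimensionality`
#' (`"single"`/`"multi"`). A Metric config must carry either a threshold or
#' the mixture-model flag; a Hard config must carry neither. Unknown keys are
#' rejected.
#'
#' @param path path to the JSON configuration.
#' @return An object of class `nct_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stopf("unknown config keys: %s (allowed: %s)",
          paste(unknown, collapse = ", "), paste(config_keys, collapse = ", "))
  for (k in c("name", "space", "type"))
    if (is.null(cfg[[k]])) stopf("config is missing required key '%s'", k)
  if (!cfg$type %in% c("Metric", "Hard"))
    stopf("config 'type' must be \"Metric\" or \"Hard\" (got \"%s\")", cfg$type)
  mixture <- isTRUE(cfg$mixture)
  if (cfg$type == "Metric" && is.null(cfg$threshold) && !mixture)
    stopf("Metric config requires a 'threshold' or 'mixture': true")
  if (cfg$type == "Hard" && !is.null(cfg$threshold))
    stopf("Hard config must not carry a 'threshold'")
  if (cfg$type == "Hard" && mixture)
    stopf("Hard config must not carry 'mixture': true")
  dim_ <- cfg$dimensionality %||% "single"
  if (!dim_ %in% c("single", "multi"))
    stopf("config 'dimensionality' must be \"single\" or \"multi\"")
  structure(list(data_name = cfg$name, data_space = cfg$space,
                 data_type = cfg$type,
                 threshold = if (is.null(cfg$threshold)) NULL else as.numeric(cfg$threshold),
                 mixture = mixture, dimensionality = dim_),
            class = "nct_config")
}

#' @export
print.nct_config <- function(x, ...) {
  thr <- if (x$mixture) "mixture model" else if (!is.null(x$threshold))
    sprintf("threshold %.3g", x$threshold) else "none"
  cat(sprintf("<nct_config> '%s' [%s, %s] on '%s'; thresholding: %s\n",
              x$data_name, x$data_type, x$dimensionality, x$data_space, thr))
  invisible(x)
}

#' Load an atlas registry
#'
#' A registry maps atlas names to their files, native space and network
#' names. Accepted as JSON or YAML of the form
#' `{"atlases": {"name": {"file": ..., "space": ..., "networks": [...]}}}`;
#' `file` may instead be an object `{"left": ..., "right": ...}` for a
#' two-hemisphere atlas (hemispheres are concatenated left-then-right on
#' load). Relative paths resolve against the registry file's directory.
#'
#' @param path registry file (`.json`, `.yaml`, `.yml`).
#' @return An object of class `atlas_registry`.
#' @export
load_atlas_registry <- function(path) {
  if (!file.exists(path)) stopf("registry file not found: %s", path)
  reg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(reg$atlases) || !length(reg$atlases))
    stopf("registry has no 'atlases' entries")
  if (anyDuplicated(names(reg$atlases)))
    stopf("duplicate atlas names in registry")
  base <- dirname(normalizePath(path))
  entries <- lapply(names(reg$atlases), function(nm) {
    e <- reg$atlases[[nm]]
    if (is.null(e$file) || is.null(e$space))
      stopf("registry entry '%s' needs 'file' and 'space'", nm)
    files <- if (is.character(e$file)) c(main = e$file) else unlist(e$file)
    files <- vapply(files, function(f)
      if (grepl("^/", f)) f else file.path(base, f), character(1L))
    missing_f <- files[!file.exists(files)]
    if (length(missing_f))
      stopf("registry entry '%s': file not found: %s", nm, missing_f[[1L]])
    list(name = nm, files = files, space = e$space,
         networks = e$networks %||% NULL)
  })
  structure(list(entries = setNames(entries, names(reg$atlases))),
            class = "atlas_registry")
}

#' @export
print.atlas_registry <- function(x, ...) {
  cat(sprintf("<atlas_registry> %d atlases:\n", length(x$entries)))
  for (e in x$entries)
    cat(sprintf("  %s  [%s] %s\n", e$name, e$space,
                if (is.null(e$networks)) "" else sprintf("(%d networks)", length(e$networks))))
  invisible(x)
}

#' @rdname load_atlas_registry
#' @export
registry_names <- function(registry) names(registry$entries)

#' Resolve atlas names against a registry
#'
#' Loads each requested atlas from its registered file(s) and masks
#' non-cortical locations to 0 using the matching mesh in `spaces`. Order of
#' the request is preserved; requesting a name twice yields the same loaded
#' object twice.
#'
#' @param registry an [load_atlas_registry()] result.
#' @param names character vector of atlas names to load.
#' @param spaces named list of [sphere_mesh()]es keyed by space id (used for
#'   length checks and cortex masking); entries may be `NULL` for volumetric
#'   atlases.
#' @return List of [atlas()] objects, in request order.
#' @export
resolve_atlases <- function(registry, names, spaces = list()) {
  stopifnot(inherits(registry, "atlas_registry"))
  unknown <- setdiff(names, registry_names(registry))
  if (length(unknown))
    stopf("unknown atlas name(s): %s. Registered atlases: %s",
          paste(unknown, collapse = ", "),
          paste(registry_names(registry), collapse = ", "))
  cache <- new.env(parent = emptyenv())
  lapply(names, function(nm) {
    if (!is.null(cache[[nm]])) return(cache[[nm]])
    e <- registry$entries[[nm]]
    mesh <- spaces[[e$space]]
    if (length(e$files) == 1L) {
      m <- load_spatial_data(e$files[[1L]], "label", space_id = e$space,
                             n_locations = if (!is.null(mesh)) n_locations(mesh))
      if (!is.null(mesh)) {
        v <- m$values
        v[!mesh$cortex_mask] <- 0L
        m <- label_map(v, e$space, m$label_table)
      }
    } else {
      if (!all(c("left", "right") %in% names(e$files)))
        stopf("registry entry '%s': multi-file atlases need 'left' and 'right'", nm)
      parts <- lapply(c("left", "right"), function(h) {
        mh <- if (is.list(mesh)) mesh[[h]] else NULL
        mp <- load_spatial_data(e$files[[h]], "label",
                                space_id = paste0(e$space, "_", h),
                                n_locations = if (!is.null(mh)) n_locations(mh))
        if (!is.null(mh)) mp$values[!mh$cortex_mask] <- 0L
        mp
      })
      lt <- parts[[1L]]$label_table
      m <- label_map(c(parts[[1L]]$values, parts[[2L]]$values), e$space, lt)
    }
    a <- atlas(nm, m, network_names = e$networks, source_space = e$space)
    cache[[nm]] <- a
    a
  })
}

#' Read a numeric component-ID list
#'
#' One integer ID per line; blank lines and `#` comments ignored. Used for
#' good-component bookkeeping of ICA decompositions.
#'
#' @param path text file of IDs.
#' @return Integer vector.
#' @export
read_component_list <- function(path) {
  if (!file.exists(path)) stopf("component list not found: %s", path)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  ids <- suppressWarnings(as.integer(unlist(strsplit(ln, "\\s+"))))
  if (anyNA(ids)) stopf("non-integer entries in component list: %s", path)
  ids
}

#' Filter a component-ID list
#'
#' Drops excluded IDs (e.g. a cerebellar component that falls outside the
#' cortical analysis mask) from a good-component list, with bookkeeping
#' errors if an excluded ID is absent.
#'
#' @param ids integer component IDs.
#' @param exclude IDs to drop.
#' @return Integer vector of the retained IDs, original order.
#' @export
filter_components <- function(ids, exclude = integer()) {
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stopf("duplicate component IDs")
  exclude <- as.integer(exclude)
  absent <- setdiff(exclude, ids)
  if (length(absent))
    stopf("cannot exclude absent component(s): %s", paste(absent, collapse = ", "))
  ids[!ids %in% exclude]
}
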