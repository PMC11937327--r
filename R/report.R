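#' Network correspondence between input data and reference atlases
#'
#' The package's main entry point: computes, for each atlas, the Dice
#' overlap between every input data mask and every atlas network, together
#' with spin-test p-values, and assembles the standard report forms —
#' Network Clock rows (one map vs all networks of all atlases), per-atlas
#' Network Radar profiles, and Overlap Heatmap matrices for multidimensional
#' input. One rotation set (from `seed`) is shared across all atlases and
#' cells. Atlases are always projected into the input data's space, never
#' the reverse.
#'
#' @param data a single logical mask or named list of logical masks on
#'   `mesh` (already thresholded; see [threshold_map()] /
#'   [mixture_threshold()]).
#' @param atlases list of [atlas()] objects; any atlas not in `mesh`'s space
#'   is resampled into it via `spaces`.
#' @param mesh the input-data [sphere_mesh()] (the reference space).
#' @param n_rotations spin-test permutation count (default 1000).
#' @param seed RNG seed for the rotation set.
#' @param alpha significance level (default 0.05, uncorrected; set
#'   `bonferroni = TRUE` to divide by the number of tests).
#' @param variant spin p-value convention, see [spin_test()].
#' @param spaces named list of meshes keyed by space id, needed only when
#'   atlases must be resampled.
#' @param bonferroni apply Bonferroni correction to `alpha`.
#' @param data_name label for the input data used in outputs.
#' @return An object of class `nct_report` with `clock_rows`,
#'   `radar_groups`, `heatmaps`, `summary_table`, and the run parameters.
#' @export
build_report <- function(data, atlases, mesh, n_rotations = 1000L, seed = 1L,
                         alpha = 0.05, variant = c("paper", "plus-one"),
                         spaces = list(), bonferroni = FALSE,
                         data_name = "input_data") {
  variant <- match.arg(variant)
  if (is.logical(data)) data <- list(input = data)
  if (!length(atlases)) stopf("no atlases supplied")
  for (nm in names(data))
    if (!any(data[[nm]] & mesh$cortex_mask))
      stopf("data mask '%s' is empty after thresholding/masking", nm)
  spaces[[mesh$space_id]] <- mesh
  rotations <- sample_rotations(n_rotations, seed)
  mats <- lapply(atlases, function(atl) {
    if (!identical(atl$source_space, mesh$space_id)) {
      src <- spaces[[atl$source_space]]
      if (is.null(src))
        stopf("atlas '%s' lives on '%s'; supply that mesh in `spaces` to project it",
              atl$name, atl$source_space)
      atl <- atlas(atl$name, resample_labels(src, atl$label_map, mesh),
                   network_names = atl$network_names,
                   source_space = mesh$space_id)
    }
    spin_test_matrix(data, atl, mesh, alpha = alpha, variant = variant,
                     rotations = rotations)
  })
  n_tests <- sum(vapply(mats, length, integer(1L)))
  alpha_eff <- if (bonferroni) alpha / n_tests else alpha
  tab <- summary_table(mats, alpha = alpha_eff)
  tab$reference_atlas <- NULL
  names(tab)[names(tab) == "reference_network"] <- "data_dimension"
  names(tab)[names(tab) == "other_atlas"] <- "atlas"
  names(tab)[names(tab) == "other_network"] <- "network"
  multi <- length(data) > 1L
  clock <- radar <- NULL
  if (!multi) {
    clock <- tab[, c("atlas", "network", "dice", "p_value", "significant")]
    # font-size rank for clock rendering: larger Dice, larger font
    clock$font_size <- 0.6 + 1.4 * (clock$dice - min(clock$dice)) /
      max(max(clock$dice) - min(clock$dice), .Machine$double.eps)
    radar <- split(clock[, c("network", "dice", "p_value", "significant")],
                   clock$atlas)
  }
  structure(list(clock_rows = clock, radar_groups = radar,
                 heatmaps = if (multi) mats else NULL,
                 matrices = mats, summary_table = tab,
                 data_name = data_name, multi = multi,
                 params = list(n_rotations = n_rotations, seed = seed,
                               alpha = alpha, alpha_effective = alpha_eff,
                               variant = variant, bonferroni = bonferroni)),
            class = "nct_report")
}

#' @export
print.nct_report <- function(x, ...) {
  cat(sprintf("<nct_report> '%s' vs %d atlases (%d networks), %d rotations, alpha %.3g%s\n",
              x$data_name, length(x$matrices), nrow(x$summary_table),
              x$params$n_rotations, x$params$alpha,
              if (x$params$bonferroni) " (Bonferroni)" else ""))
  sig <- x$summary_table[x$summary_table$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat(sprintf("%d significant overlaps; strongest:\n", nrow(sig)))
    print(head(sig[order(-sig$dice),
                   c("atlas", "network", "dice", "p_value")], 8L),
          row.names = FALSE)
  } else cat("no significant overlaps\n")
  invisible(x)
}

#' @export
summary.nct_report <- function(object, ...) object$summary_table

#' @export
plot.nct_report <- function(x, type = c("clock", "radar", "heatmap"),
                            atlas = NULL, ...) {
  type <- match.arg(type)
  switch(type,
         clock = plot_network_clock(x, ...),
         radar = plot_network_radar(x, atlas = atlas, ...),
         heatmap = plot_overlap_heatmap(x, atlas = atlas, ...))
  invisible(x)
}

plot_network_clock <- function(report, main = NULL) {
  rows <- report$clock_rows
  if (is.null(rows)) stopf("clock plot needs unidimensional input data")
  n <- nrow(rows)
  ang <- pi / 2 - 2 * pi * (seq_len(n) - 0.5) / n
  atl <- factor(rows$atlas)
  cols <- hcl.colors(max(3L, nlevels(atl)), "Dark 3")[as.integer(atl)]
  r <- rows$dice / max(max(rows$dice), .Machine$double.eps)
  op <- par(mar = c(1, 1, 3, 1)); on.exit(par(op))
  plot.new(); plot.window(c(-1.7, 1.7), c(-1.7, 1.7), asp = 1)
  title(main %||% sprintf("Network Clock: %s", report$data_name))
  segments(0, 0, r * cos(ang), r * sin(ang), col = cols, lwd = 2)
  points(r * cos(ang), r * sin(ang), pch = 16, col = cols,
         cex = 0.5 + rows$dice * 2)
  sig <- rows$significant
  if (any(sig))
    text(1.12 * cos(ang[sig]), 1.12 * sin(ang[sig]),
         rows$network[sig], col = cols[sig],
         cex = rows$font_size[sig], xpd = NA)
  legend("bottomleft", legend = levels(atl), bty = "n", cex = 0.7,
         text.col = hcl.colors(max(3L, nlevels(atl)), "Dark 3")[seq_len(nlevels(atl))])
  invisible(NULL)
}

plot_network_radar <- function(report, atlas = NULL, main = NULL) {
  if (is.null(report$radar_groups)) stopf("radar plot needs unidimensional input data")
  atlas <- atlas %||% names(report$radar_groups)[[1L]]
  g <- report$radar_groups[[atlas]]
  if (is.null(g)) stopf("no radar group for atlas '%s'", atlas)
  n <- nrow(g)
  ang <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  rmax <- max(g$dice, 0.1)
  op <- par(mar = c(1, 1, 3, 1)); on.exit(par(op))
  plot.new(); plot.window(c(-1.6, 1.6), c(-1.6, 1.6), asp = 1)
  title(main %||% sprintf("Network Radar: %s vs %s", report$data_name, atlas))
  for (f in c(0.25, 0.5, 0.75, 1))
    polygon(f * cos(ang), f * sin(ang), border = "grey80")
  r <- g$dice / rmax
  polygon(r * cos(ang), r * sin(ang), border = "steelblue",
          col = grDevices::adjustcolor("steelblue", 0.3), lwd = 2)
  lab <- paste0(g$network, ifelse(g$significant, " *", ""))
  text(1.25 * cos(ang), 1.25 * sin(ang), lab, cex = 0.65, xpd = NA)
  invisible(NULL)
}

plot_overlap_heatmap <- function(report, atlas = NULL, main = NULL) {
  mats <- report$heatmaps %||% report$matrices
  atl_names <- vapply(mats, attr, character(1L), "other_atlas")
  m <- if (is.null(atlas)) mats[[1L]] else mats[[match(atlas, atl_names)]]
  v <- unclass(m)
  op <- par(mar = c(6, 6, 3, 1)); on.exit(par(op))
  image(seq_len(ncol(v)), seq_len(nrow(v)), t(v)[, rev(seq_len(nrow(v))), drop = FALSE],
        col = hcl.colors(64, "YlOrRd", rev = TRUE), zlim = c(0, 1),
        axes = FALSE, xlab = "", ylab = "",
        main = main %||% sprintf("Overlap Heatmap: %s", attr(m, "other_atlas")))
  axis(1, seq_len(ncol(v)), colnames(v), las = 2, cex.axis = 0.6)
  axis(2, rev(seq_len(nrow(v))), rownames(v), las = 2, cex.axis = 0.6)
  box()
  invisible(NULL)
}

#' Write all report artifacts to a directory
#'
#' Writes the clock figure (unidimensional input), one radar figure per
#' atlas, heatmap figures (multidimensional input), the summary CSV and a
#' machine-readable JSON mirror of all numbers. The CSV and JSON are
#' byte-reproducible for identical inputs and seed; figures are best-effort
#' renderings.
#'
#' @param report an [build_report()] result.
#' @param out_dir output directory (created if needed).
#' @return Character vector of files written (the manifest), invisibly
#'   returned as `manifest.txt` content.
#' @export
render_outputs <- function(report, out_dir) {
  stopifnot(inherits(report, "nct_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stopf("output directory not writable: %s", out_dir)
  unlink(probe)
  manifest <- character(0)
  emit_png <- function(name, expr) {
    path <- file.path(out_dir, name)
    png(path, width = 900, height = 900, res = 120)
    on.exit(dev.off(), add = TRUE)
    force(expr)
    manifest <<- c(manifest, name)
  }
  if (!report$multi) {
    emit_png("network_clock.png", plot_network_clock(report))
    for (anm in names(report$radar_groups))
      emit_png(sprintf("network_radar_%s.png", anm),
               plot_network_radar(report, atlas = anm))
  } else {
    for (m in report$heatmaps)
      emit_png(sprintf("overlap_heatmap_%s.png", attr(m, "other_atlas")),
               plot_overlap_heatmap(report, atlas = attr(m, "other_atlas")))
  }
  csv_path <- file.path(out_dir, "summary_table.csv")
  tab_out <- report$summary_table
  for (j in seq_along(tab_out))  # full 17-digit precision: exact round trips
    if (is.double(tab_out[[j]])) tab_out[[j]] <- formatC(tab_out[[j]], format = "g",
                                                         digits = 17)
  write.csv(tab_out, csv_path, row.names = FALSE, quote = FALSE)
  manifest <- c(manifest, "summary_table.csv")
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(data_name = report$data_name, params = report$params,
         summary = report$summary_table),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- c(manifest, "report.json")
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  manifest <- c(manifest, "manifest.txt")
  manifest
}
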