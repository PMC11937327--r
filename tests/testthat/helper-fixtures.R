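# Shared fixtures, built once per test run.

mesh2 <- build_icosphere(2)                      # 162 vertices
mesh3 <- build_icosphere(3)                      # 642 vertices
mesh4 <- build_icosphere(4)                      # 2562 vertices

# brute-force nearest-vertex oracle: exhaustive distance scan, lowest-index ties
nn_oracle <- function(mesh, q) {
  q <- q / sqrt(sum(q^2))
  d2 <- colSums((t(mesh$vertices) - q)^2)
  which(d2 == min(d2))[1L]
}

# brute-force set-count Dice oracle
dice_oracle <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0L) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# registry of synthetic atlases written to disk, for io/cli tests
write_synth_registry <- function(dir, mesh, n_atlases = 4L, n_networks = 5L,
                                 seed0 = 100L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_len(n_atlases)) {
    nm <- sprintf("synth%02d", i)
    atl <- generate_synthetic_atlas(mesh, n_networks, seed = seed0 + i, name = nm)
    f <- file.path(dir, paste0(nm, ".label.gii"))
    write_gifti_label(atl$label_map, f)
    entries[[nm]] <- list(file = paste0(nm, ".label.gii"),
                          space = mesh$space_id,
                          networks = atl$network_names)
  }
  reg_path <- file.path(dir, "registry.json")
  jsonlite::write_json(list(atlases = entries), reg_path, auto_unbox = TRUE)
  reg_path
}
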