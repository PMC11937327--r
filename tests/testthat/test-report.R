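make_report_fixture <- function(n_rotations = 40, data_masks = NULL,
                                n_atlases = 4, seed = 77) {
  atlases <- lapply(seq_len(n_atlases), function(i)
    generate_synthetic_atlas(mesh3, 3 + i %% 2, seed = 200 + i,
                             name = sprintf("atl%d", i)))
  if (is.null(data_masks))
    data_masks <- list(input = atlases[[1]]$label_map$values == 1L)
  build_report(data_masks, atlases, mesh3, n_rotations = n_rotations,
               seed = seed)
}

test_that("clock rows cover every (atlas, network) pair exactly once", {
  rep <- make_report_fixture()
  expected <- sum(3L + seq_len(4) %% 2L)
  expect_identical(nrow(rep$clock_rows), expected)
  expect_false(anyDuplicated(paste(rep$clock_rows$atlas,
                                   rep$clock_rows$network)) > 0)
  expect_identical(sort(unique(rep$clock_rows$atlas)),
                   sprintf("atl%d", 1:4))
  # font size scales with Dice
  cr <- rep$clock_rows
  expect_identical(order(cr$dice), order(cr$font_size))
})

test_that("significance is strict: p < alpha, never p == alpha", {
  m <- new_matrix <- matrix(c(0.5, 0.4), 1, 2,
                            dimnames = list("input", c("n1", "n2")))
  om <- structure(m, class = c("overlap_matrix", "matrix"),
                  reference_atlas = "input_data", other_atlas = "a",
                  p_values = matrix(c(0.049, 0.05), 1, 2))
  tab <- summary_table(om, alpha = 0.05)
  expect_identical(tab$significant, c(TRUE, FALSE))
})

test_that("multidimensional input produces one heatmap per atlas", {
  src <- generate_synthetic_atlas(mesh3, 3, seed = 300)
  masks <- list(d1 = src$label_map$values == 1L,
                d2 = src$label_map$values == 2L,
                d3 = src$label_map$values == 3L)
  rep <- make_report_fixture(data_masks = masks, n_atlases = 2)
  expect_null(rep$clock_rows)
  expect_length(rep$heatmaps, 2L)
  for (h in rep$heatmaps) expect_identical(nrow(unclass(h)), 3L)
})

test_that("empty data masks are rejected with a clear error", {
  atl <- generate_synthetic_atlas(mesh3, 3, seed = 301)
  expect_error(build_report(list(bad = rep(FALSE, n_locations(mesh3))),
                            list(atl), mesh3, n_rotations = 5),
               "empty after thresholding")
})

test_that("rendered outputs have the contracted manifest and round-trip exactly", {
  rep <- make_report_fixture(n_atlases = 2)
  out <- tempfile()
  manifest <- render_outputs(rep, out)
  expect_identical(sum(manifest == "network_clock.png"), 1L)
  expect_identical(sum(grepl("^network_radar_", manifest)), 2L)
  expect_identical(sum(manifest == "summary_table.csv"), 1L)
  expect_identical(sum(manifest == "report.json"), 1L)
  expect_true(all(file.exists(file.path(out, manifest))))
  back <- read.csv(file.path(out, "summary_table.csv"))
  expect_equal(back$dice, rep$summary_table$dice, tolerance = 1e-15)
  expect_equal(back$p_value, rep$summary_table$p_value, tolerance = 1e-15)
})

test_that("identical seeds give byte-identical CSV and JSON outputs", {
  out1 <- tempfile(); out2 <- tempfile()
  render_outputs(make_report_fixture(), out1)
  render_outputs(make_report_fixture(), out2)
  for (f in c("summary_table.csv", "report.json"))
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
})

test_that("the compare subcommand runs end to end from files", {
  dir <- tempfile()
  reg_path <- write_synth_registry(dir, mesh3, n_atlases = 2L)
  data_atl <- generate_synthetic_atlas(mesh3, 1, seed = 400, name = "net3")
  data_path <- file.path(dir, "net3.label.gii")
  write_gifti_label(data_atl$label_map, data_path)
  cfg_path <- file.path(dir, "hard.json")
  jsonlite::write_json(list(name = "net3", space = mesh3$space_id,
                            type = "Hard"), cfg_path, auto_unbox = TRUE)
  out <- file.path(dir, "out")
  code <- suppressMessages(run_compare(c(
    "compare", "--data", data_path, "--config", cfg_path,
    "--registry", reg_path, "--atlases", "synth01,synth02",
    "--out", out, "--n-rotations", "25", "--seed", "7")))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(out, "summary_table.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
})

test_that("validation failures exit with code 2 and name the problem", {
  dir <- tempfile()
  reg_path <- write_synth_registry(dir, mesh3, n_atlases = 2L)
  cfg_bad <- file.path(dir, "metric_no_thr.json")
  jsonlite::write_json(list(name = "m", space = mesh3$space_id,
                            type = "Metric"), cfg_bad, auto_unbox = TRUE)
  expect_identical(suppressMessages(run_compare(c(
    "compare", "--data", "x.func.gii", "--config", cfg_bad,
    "--registry", reg_path, "--atlases", "synth01", "--out", tempfile()))),
    2L)
  # unknown atlas: exit 2, message lists registered names
  cfg_ok <- file.path(dir, "hard.json")
  jsonlite::write_json(list(name = "m", space = mesh3$space_id,
                            type = "Hard"), cfg_ok, auto_unbox = TRUE)
  data_atl <- generate_synthetic_atlas(mesh3, 1, seed = 401)
  data_path <- file.path(dir, "d.label.gii")
  write_gifti_label(data_atl$label_map, data_path)
  msgs <- character()
  code <- withCallingHandlers(
    run_compare(c("compare", "--data", data_path, "--config", cfg_ok,
                  "--registry", reg_path, "--atlases", "nonexistent",
                  "--out", tempfile())),
    message = function(m) { msgs <<- c(msgs, conditionMessage(m))
                            invokeRestart("muffleMessage") })
  expect_identical(code, 2L)
  expect_true(any(grepl("synth01", msgs)))
})

test_that("the pipeline refuses volumetric spaces with a remediation hint", {
  dir <- tempfile(); dir.create(dir)
  reg_path <- write_synth_registry(dir, mesh3, n_atlases = 1L)
  cfg <- file.path(dir, "vol.json")
  jsonlite::write_json(list(name = "v", space = "MNI152", type = "Hard"),
                       cfg, auto_unbox = TRUE)
  msgs <- character()
  code <- withCallingHandlers(
    run_compare(c("compare", "--data", "v.nii.gz", "--config", cfg,
                  "--registry", reg_path, "--atlases", "synth01",
                  "--out", tempfile())),
    message = function(m) { msgs <<- c(msgs, conditionMessage(m))
                            invokeRestart("muffleMessage") })
  expect_identical(code, 2L)
  expect_true(any(grepl("projected to a surface", msgs)))
})
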