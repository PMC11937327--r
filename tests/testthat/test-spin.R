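test_that("sampled rotations are proper and exactly reproducible", {
  rs <- sample_rotations(20, seed = 5)
  for (i in 1:20) {
    R <- rs$rotations[, , i]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_lt(abs(det(R) - 1), 1e-10)
    M <- rs$mirrored[, , i]
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-10)
    expect_lt(abs(det(M) - 1), 1e-10)
  }
  rs2 <- sample_rotations(20, seed = 5)
  expect_identical(rs$rotations, rs2$rotations)
  expect_error(sample_rotations(0), "positive")
})

test_that("rotations are uniform: the rotated pole has zero mean direction", {
  rs <- sample_rotations(10000, seed = 8)
  z <- c(0, 0, 1)
  pts <- t(apply(rs$rotations, 3, function(R) R %*% z))
  expect_lt(max(abs(colMeans(pts))), 0.05)
})

test_that("rotating by the identity leaves a map unchanged", {
  atl <- generate_synthetic_atlas(mesh3, 5, seed = 13)
  out <- rotate_map(atl$label_map, mesh3, diag(3))
  expect_identical(out$values, atl$label_map$values)
  mask <- atl$label_map$values == 2L
  expect_identical(rotate_map(mask, mesh3, diag(3)), mask)
  expect_error(rotate_map(mask, mesh3, matrix(1, 3, 3)), "not orthogonal")
})

test_that("rotation followed by its inverse recovers almost all labels", {
  # all-cortical sphere: only nearest-neighbour discretization error remains
  dense <- build_icosphere(5, medial_wall_frac = 0)
  atl <- generate_synthetic_atlas(dense, 6, seed = 14)
  R <- sample_rotations(1, seed = 15)$rotations[, , 1]
  fwd <- rotate_map(atl$label_map, dense, R)
  back <- rotate_map(fwd, dense, t(R))
  recovered <- mean(back$values == atl$label_map$values)
  expect_gte(recovered, 0.95)
  # with a medial wall, rotated-off-cortex vertices additionally become
  # unassigned, so recovery drops by about the wall fraction
  walled <- build_icosphere(5)
  atlw <- generate_synthetic_atlas(walled, 6, seed = 14)
  fwdw <- rotate_map(atlw$label_map, walled, R)
  backw <- rotate_map(fwdw, walled, t(R))
  ctx <- walled$cortex_mask
  expect_gte(mean(backw$values[ctx] == atlw$label_map$values[ctx]), 0.85)
})

test_that("nearest-neighbour remapping approximately preserves mask area", {
  allctx <- build_icosphere(4, medial_wall_frac = 0)
  atl <- generate_synthetic_atlas(allctx, 8, seed = 16)
  mask <- atl$label_map$values == 1L
  rs <- sample_rotations(20, seed = 17)
  for (i in 1:20) {
    rot <- rotate_map(mask, allctx, rs$rotations[, , i])
    expect_lt(abs(sum(rot) - sum(mask)) / sum(mask), 0.10)
  }
})

test_that("the spin p-value follows the strict-exceedance formula", {
  expect_equal(spin_pvalue(0.5, c(0.6, 0.4, 0.3, 0.2)), 0.25)
  expect_equal(spin_pvalue(0.9, c(0.1, 0.2, 0.3)), 0)
  expect_equal(spin_pvalue(0.05, c(0.1, 0.2, 0.3)), 1)
  expect_equal(spin_pvalue(0.5, c(0.6, 0.4, 0.3, 0.2), variant = "plus-one"),
               2 / 5)
  # ties count as not larger
  expect_equal(spin_pvalue(0.5, c(0.5, 0.5, 0.7, 0.1)), 0.25)
  # non-increasing in the observed value for a fixed null
  null <- runif(50)
  ps <- vapply(seq(0, 1, 0.05), function(o) spin_pvalue(o, null), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("spin_test returns a complete, reproducible null", {
  atlA <- generate_synthetic_atlas(mesh3, 4, seed = 18)
  atlB <- generate_synthetic_atlas(mesh3, 4, seed = 19)
  rs <- sample_rotations(25, seed = 20)
  res <- spin_test(atlA$label_map$values == 1L, atlB$label_map$values == 2L,
                   mesh3, rs)
  expect_length(res$null_dice, 25L)
  expect_equal(res$p_value, mean(res$null_dice > res$observed_dice))
  res2 <- spin_test(atlA$label_map$values == 1L, atlB$label_map$values == 2L,
                    mesh3, sample_rotations(25, seed = 20))
  expect_identical(res$null_dice, res2$null_dice)
  expect_identical(res$p_value, res2$p_value)
})

test_that("a mask identical to a network has Dice 1 and spin p-value 0", {
  atl <- generate_synthetic_atlas(mesh3, 5, seed = 23)
  mask <- atl$label_map$values == 3L
  sm <- spin_test_matrix(list(input = mask), atl, mesh3, n = 99, seed = 24)
  expect_equal(unclass(sm)[1, 3], 1)
  expect_equal(attr(sm, "p_values")[1, 3], 0)
  expect_identical(dim(unclass(sm)), c(1L, 5L))
})

test_that("spin_test_matrix has the (data x network) shape with p-values in [0,1]", {
  atl <- generate_synthetic_atlas(mesh3, 6, seed = 25)
  other <- generate_synthetic_atlas(mesh3, 3, seed = 26)
  data <- list(a = other$label_map$values == 1L,
               b = other$label_map$values == 2L)
  sm <- spin_test_matrix(data, atl, mesh3, n = 60, seed = 27)
  expect_identical(dim(unclass(sm)), c(2L, 6L))
  pv <- attr(sm, "p_values")
  expect_identical(dim(pv), c(2L, 6L))
  expect_true(all(pv >= 0 & pv <= 1))
  # shared rotation set: matrix cells agree with standalone spin tests
  rs <- sample_rotations(60, seed = 27)
  solo <- spin_test(data$a, atl$label_map$values == 4L, mesh3, rs)
  expect_equal(unclass(sm)[1, 4], solo$observed_dice, tolerance = 1e-12)
  expect_equal(pv[1, 4], solo$p_value, tolerance = 1e-12)
})

test_that("spin p-values are roughly uniform under a rotation-generated null", {
  # smaller version of the full calibration (which runs in the acceptance
  # suite): 60 replicates x 100 rotations on the 642-vertex sphere.  The
  # template parcel must be large enough that zero-overlap rotations (exact
  # Dice ties at 0, which the strict-inequality p-value cannot spread over
  # [0, 1]) are rare.
  atl <- generate_synthetic_atlas(mesh3, 3, seed = 28)
  tmpl <- atl$label_map$values == 1L
  ps <- spin_calibration(mesh3, tmpl, n_rotations = 100, n_replicates = 60,
                         seed = 29)
  expect_gte(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  fpr <- mean(ps < 0.05)
  expect_gte(fpr, 0); expect_lte(fpr, 0.15)
})
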