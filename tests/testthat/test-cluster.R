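ari <- function(a, b) mclust::adjustedRandIndex(a, b)

planted_similarity <- function(sizes, within = 0.9, between = 0.05,
                               seed = 1, noise = 0.02) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  set.seed(seed)
  s <- matrix(between, n, n) + matrix(runif(n * n, 0, noise), n, n)
  s[outer(lab, lab, "==")] <- within
  diag(s) <- 1
  rownames(s) <- colnames(s) <- paste0("atlas", lab, "::net", seq_len(n))
  list(s = pmin(s, 1), labels = lab)
}

test_that("planted block partitions are recovered exactly", {
  p <- planted_similarity(c(5, 6, 7))
  asg <- cluster_networks(p$s, 3)
  expect_equal(ari(asg$cluster_labels, p$labels), 1)
  expect_setequal(unique(asg$cluster_labels), 1:3)
})

test_that("degenerate and invalid clustering inputs behave per contract", {
  p <- planted_similarity(c(4, 4))
  one <- cluster_networks(p$s, 1)
  expect_true(all(one$cluster_labels == 1L))
  expect_error(cluster_networks(p$s - 2, 2), "\\[0, 1\\]")
  expect_error(cluster_networks(p$s, 0), "n_clusters")
  expect_error(cluster_networks(p$s[, 1:3], 2), "square")
})

test_that("clustering is equivariant under simultaneous permutations", {
  p <- planted_similarity(c(4, 5, 3), seed = 2)
  asg <- cluster_networks(p$s, 3)
  set.seed(3)
  perm <- sample(nrow(p$s))
  asg_p <- cluster_networks(p$s[perm, perm], 3)
  expect_equal(ari(asg_p$cluster_labels, asg$cluster_labels[perm]), 1)
})

test_that("jittered atlas families cluster back to their template networks", {
  template_k <- 5
  atlases <- lapply(1:6, function(i)
    generate_synthetic_atlas(mesh3, template_k, seed = 90,
                             jitter = if (i == 1) 0 else 0.04, variant = i,
                             name = sprintf("fam%d", i)))
  spaces <- setNames(list(mesh3), mesh3$space_id)
  mats <- all_pairs_correspondence(atlases, spaces)
  S <- stack_similarity(mats, atlases, spaces)
  asg <- cluster_networks(S, template_k)
  truth <- rep(seq_len(template_k), times = length(atlases))
  expect_gte(ari(asg$cluster_labels, truth), 0.9)
})

test_that("cluster probability maps count each atlas once per vertex", {
  a1 <- generate_synthetic_atlas(mesh3, 4, seed = 95, name = "p1")
  asg1 <- list(network_ids = data.frame(atlas = "p1", network = "p1_net2"),
               cluster_labels = 1L, n_clusters = 1L)
  class(asg1) <- "cluster_assignment"
  pm <- cluster_probability_maps(asg1, list(a1), mesh3)[[1]]
  expect_equal(pm$values, as.numeric(a1$label_map$values == 2L))
  expect_identical(pm$n_contributing_atlases, 1L)

  # two atlases with identical member masks give 1 inside, 0 outside
  a2 <- atlas("p2", a1$label_map, source_space = a1$source_space)
  asg2 <- list(network_ids = data.frame(atlas = c("p1", "p2"),
                                        network = c("p1_net2", "p1_net2")),
               cluster_labels = c(1L, 1L), n_clusters = 1L)
  class(asg2) <- "cluster_assignment"
  pm2 <- cluster_probability_maps(asg2, list(a1, a2), mesh3)[[1]]
  expect_setequal(unique(pm2$values), c(0, 1))
  expect_equal(which(pm2$values == 1), which(a1$label_map$values == 2L))
})

test_that("probability-map values are atlas-count fractions with a boundary band", {
  fams <- lapply(1:4, function(i)
    generate_synthetic_atlas(mesh4, 4, seed = 96,
                             jitter = if (i == 1) 0 else 0.03, variant = i,
                             name = sprintf("q%d", i)))
  # cluster = the best-matching network of each atlas to fams[[1]] network 1
  nets <- vapply(fams, function(a) {
    om <- unclass(overlap_matrix(fams[[1]], a, space = mesh4))
    a$network_names[which.max(om[1, ])]
  }, character(1))
  asg <- list(network_ids = data.frame(atlas = vapply(fams, `[[`, character(1), "name"),
                                       network = nets),
              cluster_labels = rep(1L, 4), n_clusters = 1L)
  class(asg) <- "cluster_assignment"
  pm <- cluster_probability_maps(asg, fams, mesh4)[[1]]
  expect_identical(pm$n_contributing_atlases, 4L)
  expect_true(all(pm$values %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_gt(sum(pm$values == 1), 0)                 # interior plateau
  expect_gt(sum(pm$values %in% c(0.25, 0.5, 0.75)), 0)  # boundary band
  expect_true(all(pm$values[!mesh4$cortex_mask] == 0))
})

test_that("reordering groups the similarity matrix by cluster without losing entries", {
  p <- planted_similarity(c(3, 4, 5), seed = 5)
  set.seed(6)
  perm <- sample(nrow(p$s))
  shuffled <- p$s[perm, perm]
  asg <- cluster_networks(shuffled, 3)
  reord <- reorder_similarity(shuffled, asg)
  expect_equal(sort(as.vector(reord$matrix)), sort(as.vector(p$s)))
  expect_identical(reord$boundaries[3], nrow(p$s))
  # blocks are contiguous: labels in reordered order are non-decreasing runs
  labs <- asg$cluster_labels[reord$order]
  expect_identical(labs, labs[order(labs)])
  # already grouped input stays grouped
  asg0 <- cluster_networks(p$s, 3)
  reord0 <- reorder_similarity(p$s, asg0)
  labs0 <- asg0$cluster_labels[reord0$order]
  expect_identical(labs0, labs0[order(labs0)])
})

test_that("dendrograms export as parseable Newick trees", {
  p <- planted_similarity(c(3, 3))
  asg <- cluster_networks(p$s, 2)
  f <- tempfile(fileext = ".nwk")
  write_dendrogram(asg, f)
  tree <- ape::read.tree(f)
  expect_identical(ape::Ntip(tree), nrow(p$s))
})

test_that("chord edge lists carry cluster annotations", {
  p <- planted_similarity(c(3, 3), seed = 7)
  asg <- cluster_networks(p$s, 2)
  edges <- chord_edges(p$s, asg, min_similarity = 0.5)
  expect_true(all(edges$similarity >= 0.5))
  expect_true(all(edges$from_cluster == edges$to_cluster))
})
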