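gauss_bump <- function(grid, cx, cy, height = 1, width = 2) {
  height * exp(-((grid$col - cx)^2 + (grid$row - cy)^2) / (2 * width^2))
}

test_that("spot detection: single bump, two bumps, size filter", {
  g <- som_grid(20)
  v <- gauss_bump(g, 5, 5)
  sp <- detect_spots(v, g, "over", 0.98)
  expect_length(sp$spots, 1L)
  peak_node <- which.max(v)
  expect_true(peak_node %in% sp$spots[[1]]$nodes)
  expect_identical(sp$spots[[1]]$label, "A")

  # two disjoint bumps, second slightly lower: labels by decreasing peak
  v2 <- gauss_bump(g, 4, 4, 1) + gauss_bump(g, 15, 15, 0.9)
  sp2 <- detect_spots(v2, g, "over", 0.97)
  expect_length(sp2$spots, 2L)
  expect_identical(vapply(sp2$spots, `[[`, "", "label"), c("A", "B"))
  expect_gt(sp2$spots[[1]]$peak_value, sp2$spots[[2]]$peak_value)

  # equal heights: tie broken by seed node index
  v3 <- gauss_bump(g, 4, 4, 1) + gauss_bump(g, 15, 15, 1)
  sp3 <- detect_spots(v3, g, "over", 0.97)
  expect_length(sp3$spots, 2L)
  expect_lt(sp3$spots[[1]]$seed_node, sp3$spots[[2]]$seed_node)

  # min_size suppresses a small satellite component
  v4 <- v
  v4[g$row == 18 & g$col %in% 17:19] <- max(v) * 2   # 3-node satellite
  with_sat <- detect_spots(v4, g, "over", 0.95, min_size = 1)
  without <- detect_spots(v4, g, "over", 0.95, min_size = 5)
  expect_equal(length(with_sat$spots) - 1L, length(without$spots))
})

test_that("degenerate and underexpression cases", {
  g <- som_grid(6)
  expect_warning(sp <- detect_spots(rep(1, g$K), g), "equal")
  expect_length(sp$spots, 0L)

  v <- -gauss_bump(g, 2, 2, 3)
  spu <- detect_spots(v, g, "under", 0.9)
  expect_gte(length(spu$spots), 1L)
  expect_identical(spu$spots[[1]]$label, "a")        # lower-case labels
  expect_true(which.min(v) %in% spu$spots[[1]]$nodes)
})

test_that("detected spots are node-disjoint connected components (graph oracle)", {
  som <- fixture_som()
  for (q in c(0.95, 0.97, 0.99)) {
    gs <- find_global_spots(som, quantile_threshold = q)
    expect_length(gs$over$spots, 4L)   # one spot per planted module
    nodes <- lapply(gs$over$spots, `[[`, "nodes")
    expect_equal(anyDuplicated(unlist(nodes)), 0L)
    for (nn in nodes)
      expect_equal(igraph_components(nn, som$grid, 8L), 1L)
  }
})

test_that("spot expression: singleton, symmetry, ground truth", {
  som <- fixture_som()
  gs <- find_global_spots(som)
  se <- spot_expression(gs$over, som)
  expect_equal(dim(se), c(4L, 24L))

  # singleton spot equals its node's profile
  single <- structure(list(polarity = "over", spots = list(
    list(label = "A", polarity = "over", nodes = 7L, seed_node = 7L,
         peak_value = 0))), class = "spot_set")
  expect_equal(unname(spot_expression(single, som)[1, ]),
               unname(som$codebook[7, ]))

  # two-node spot with profiles p and -p averages to zero
  toy <- structure(list(grid = som_grid(2, 1),
                        codebook = rbind(c(1, -1, 2), c(-1, 1, -2)),
                        assignment = structure(list(n_k = c(1L, 1L)),
                                               class = "som_assignment")),
                   class = "trained_som")
  colnames(toy$codebook) <- c("a", "b", "c")
  pair <- structure(list(polarity = "over", spots = list(
    list(label = "A", polarity = "over", nodes = 1:2, seed_node = 1L,
         peak_value = 1))), class = "spot_set")
  expect_equal(unname(spot_expression(pair, toy)[1, ]), c(0, 0, 0))

  # each module's spot peaks in that module's planted samples
  truth <- fixture_sim()$truth
  for (i in seq_len(nrow(se))) {
    genes <- gs$over$spots[[i]]$genes
    ov <- vapply(truth$module_genes, function(m) length(intersect(genes, m)), 0L)
    j <- which.max(ov)
    active <- truth$module_samples[[j]]
    expect_gt(min(se[i, active]), max(se[i, setdiff(colnames(se), active)]))
  }
})

test_that("specificity entropy: bounds, uniform, dominance, hand case", {
  expect_warning(h_uniform <- cluster_specificity_entropy(c(3, 3)), "uniform")
  expect_equal(h_uniform, 1)

  # H -> 0 with growing single-cluster dominance
  hs <- vapply(c(10, 100, 1e4, 1e6), function(v)
    cluster_specificity_entropy(c(v, 0)), 0)
  expect_true(all(diff(hs) < 0))
  expect_lt(hs[4], 1e-4)

  # C = 4, weights (.5, .5, 0, 0): H = 0.5
  expect_equal(cluster_specificity_entropy(c(1, 1, 0, 0)), 0.5, tolerance = 1e-9)

  # bounds under random inputs
  for (i in 1:25) {
    e <- somatlas:::with_seed(i, stats::rnorm(somatlas:::with_seed(i, sample(2:12, 1))))
    h <- cluster_specificity_entropy(e)
    expect_gte(h, 0); expect_lte(h, 1)
  }
  expect_error(cluster_specificity_entropy(1), "at least 2")
})

test_that("clustering methods compare by the same entropy machinery", {
  sim <- fixture_sim()
  cen <- fixture_centered()
  truth_cl <- sim$truth$module
  truth_cl[truth_cl == 0] <- somatlas:::with_seed(3L,
    sample(5:10, sum(truth_cl == 0), replace = TRUE))  # pad background to C = 10
  random_cl <- somatlas:::with_seed(4L,
    stats::setNames(sample(1:10, length(truth_cl), replace = TRUE), names(truth_cl)))

  res <- compare_cluster_methods(cen, list(truth = truth_cl, truth2 = truth_cl,
                                           random = random_cl))
  # identical clusterings give identical entropy distributions
  expect_equal(res$entropy[res$method == "truth"],
               res$entropy[res$method == "truth2"])
  # module-aware clustering is more specific than a random partition
  expect_lt(stats::median(res$entropy[res$method == "truth"]),
            stats::median(res$entropy[res$method == "random"]))
})
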