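test_that("codebook initialization honors its determinism contracts", {
  em <- random_centered(80, 6, seed = 21L)
  g <- som_grid(5, 4)
  expect_identical(init_codebook(em, g, "pca_plane"),
                   init_codebook(em, g, "pca_plane"))
  expect_identical(init_codebook(em, g, "random", seed = 1L),
                   init_codebook(em, g, "random", seed = 1L))
  expect_false(isTRUE(all.equal(init_codebook(em, g, "random", seed = 1L),
                                init_codebook(em, g, "random", seed = 2L))))
})

test_that("pca_plane spans the two leading principal components", {
  # rank-2 synthetic matrix: profiles live exactly in span(v1, v2)
  m <- 8L
  v1 <- c(1, rep(0, m - 1)); v2 <- c(0, 1, rep(0, m - 2))
  sc <- somatlas:::with_seed(3L, cbind(rnorm(300, sd = 4), rnorm(300, sd = 1)))
  vals <- sc %*% rbind(v1, v2)
  dimnames(vals) <- list(sprintf("g%03d", 1:300), sprintf("s%d", 1:m))
  em <- expr_matrix(vals - rowMeans(vals) * 0, "linear") # uncentered container ok
  g <- som_grid(10)
  cb <- init_codebook(em, g, "pca_plane")
  # corner-to-corner along the grid's x axis ~ PC1, y axis ~ PC2
  along_x <- cb[10, ] - cb[1, ]              # row 0: nodes 1..10
  along_y <- cb[91, ] - cb[1, ]              # col 0: node 91 = row 9
  cosang <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  ev <- svd(scale(vals, scale = FALSE), nu = 0, nv = 2)$v
  expect_gt(cosang(along_x, ev[, 1]), 0.99)
  expect_gt(cosang(along_y, ev[, 2]), 0.99)

  # degenerate covariance falls back to random with a warning
  flat <- expr_matrix(matrix(rep(c(-1, 1), each = 20), 20, 2,
    dimnames = list(sprintf("g%d", 1:20), c("a", "b"))), "linear")
  expect_warning(init_codebook(flat, som_grid(3, 2), "pca_plane"), "rank")
})

test_that("zero-epoch training on a pre-converged codebook is a fixed point", {
  g <- som_grid(4)
  cb0 <- somatlas:::with_seed(13L, matrix(rnorm(16 * 5), 16, 5))
  cb0 <- cb0 - rowMeans(cb0)
  colnames(cb0) <- sprintf("s%d", 1:5)
  vals <- cb0
  dimnames(vals) <- list(sprintf("g%02d", 1:16), colnames(cb0))
  em <- expr_matrix(vals, "centered")
  sched <- som_schedule(g, phases = list(list(epochs = 0L, radius_start = 2,
    radius_end = 1, alpha_start = 0.05, alpha_end = 0.01)))
  som <- train_som(em, g, sched, codebook = cb0)
  expect_identical(unname(som$assignment$bmu), 1:16)
  expect_true(all(som$assignment$n_k == 1L))
  expect_identical(som$codebook, cb0)
})

test_that("assignment equals the brute-force nearest codebook row", {
  em <- random_centered(200, 6, seed = 31L)
  cb <- somatlas:::with_seed(32L, matrix(rnorm(25 * 6), 25, 6))
  colnames(cb) <- sprintf("s%02d", 1:6)
  a <- assign_genes(em, cb)
  brute <- apply(em$values, 1, function(x)
    which.min(colSums((t(cb) - x)^2)))
  expect_identical(unname(a$bmu), unname(brute))
  expect_equal(sum(a$n_k), 200L)                      # conservation
  expect_identical(sort(unlist(a$members)), sort(gene_ids(em)))  # partition
})

test_that("BMU ties break to the lowest node index; exact hits match", {
  cb <- matrix(0, 6, 2, dimnames = list(NULL, c("a", "b")))
  cb[2, ] <- c(1, 0); cb[5, ] <- c(-1, 0)
  cb[1, ] <- c(5, 5); cb[3, ] <- c(5, -5); cb[4, ] <- c(-5, 5); cb[6, ] <- c(-5, -5)
  X <- rbind(g1 = c(0, 0),      # equidistant from nodes 2 and 5
             g2 = c(5, 5))      # exact hit on node 1
  colnames(X) <- c("a", "b")
  a <- assign_genes(X, cb)
  expect_identical(unname(a$bmu), c(2L, 1L))
})

test_that("training is deterministic and reduces quantization error", {
  som1 <- fixture_som()
  som2 <- train_som(fixture_centered(), som_grid(20L), seed = 42L)
  expect_identical(som1$codebook, som2$codebook)
  expect_identical(som1$assignment$bmu, som2$assignment$bmu)

  qe <- som1$meta$quantization_error
  expect_lte(qe[["after"]], qe[["before"]] * 1.01)
  expect_equal(sum(som1$assignment$n_k), 2000L)
})

test_that("planted modules map to four disjoint contiguous node regions", {
  som <- fixture_som()
  truth <- fixture_sim()$truth
  regions <- lapply(truth$module_genes, function(g)
    sort(unique(som$assignment$bmu[g])))
  # pairwise overlap of module regions is empty
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(regions[[i]], regions[[j]]), 0L)
  # each region is one connected component (igraph oracle, 8-connectivity)
  for (r in regions)
    expect_equal(igraph_components(r, som$grid, 8L), 1L)
})

test_that("grid distance anti-correlates with codebook profile correlation", {
  som <- fixture_som()
  pairs <- somatlas:::with_seed(17L, {
    idx <- sample(som$grid$K, 80)
    t(utils::combn(idx, 2))
  })
  gd <- grid_distance(som$grid, pairs[, 1], pairs[, 2])
  pc <- vapply(seq_len(nrow(pairs)), function(i)
    stats::cor(som$codebook[pairs[i, 1], ], som$codebook[pairs[i, 2], ]), 0)
  expect_lt(stats::cor(gd, pc, method = "spearman"), -0.3)
})

test_that("metagene matrix has grid dimensions and tracks member centroids", {
  expect_equal(nrow(metagene_matrix(train_som(random_centered(100, 4, seed = 2L),
    som_grid(6), som_schedule(som_grid(6),
      phases = list(list(epochs = 1L, radius_start = 3, radius_end = 1,
                         alpha_start = 0.05, alpha_end = 0.01)))))), 36L)

  som <- fixture_som()
  mg <- metagene_matrix(som)
  expect_equal(ncol(mg), 24L)
  expect_equal(nrow(mg), 400L)
  cen <- fixture_centered()
  node_r <- function(nodes) vapply(nodes, function(k) {
    centroid <- colMeans(cen$values[som$assignment$members[[k]], , drop = FALSE])
    stats::cor(centroid, som$codebook[k, ])
  }, 0)
  # background miniclusters average a handful of pure-noise genes, so their
  # centroid-codebook correlation is moderate; the co-expressed module
  # miniclusters the metagene concept targets track their centroids closely
  expect_gt(stats::median(node_r(which(som$assignment$n_k >= 1L))), 0.65)
  mod_nodes <- unique(som$assignment$bmu[unlist(fixture_sim()$truth$module_genes)])
  expect_gt(stats::median(node_r(mod_nodes)), 0.9)
})

test_that("training validates its inputs", {
  em_log <- expr_matrix(matrix(1:12 + 0, 3, 4,
    dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4))), "log10")
  expect_error(train_som(em_log, som_grid(3, 2)), "centered")
  expect_warning(som_schedule(som_grid(4)), NA)
  expect_error(som_schedule(som_grid(4),
    phases = list(list(epochs = 1, radius_start = 1, radius_end = 2,
                       alpha_start = 0.1, alpha_end = 0.01))), "radius")
})
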