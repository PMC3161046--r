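# naive UPGMA cophenetic oracle: iteratively merge the closest pair,
# recording the merge height for every cross-cluster pair
naive_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  d <- D
  active <- seq_len(n)
  while (length(active) > 1L) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    h <- d[a, b]
    for (x in clusters[[a]]) for (y in clusters[[b]])
      coph[x, y] <- coph[y, x] <- h
    # UPGMA update: size-weighted average distance
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (o in setdiff(active, c(a, b)))
      d[a, o] <- d[o, a] <- (na * d[a, o] + nb * d[b, o]) / (na + nb)
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active <- setdiff(active, b)
  }
  coph
}

test_that("hierarchical clustering: zero distance, forced topology, cophenetic oracle", {
  mat <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  rownames(mat) <- sprintf("f%d", 1:3)
  hc <- hierarchical_cluster(mat, "samples")$samples
  expect_equal(hc$height[1], 0)                       # identical samples
  first_pair <- sort(-hc$merge[1, ])
  expect_equal(first_pair, c(1, 2))                   # a and b merge first

  pts <- somatlas:::with_seed(30L, matrix(rnorm(40), 4, 10,
    dimnames = list(sprintf("f%d", 1:4), sprintf("s%02d", 1:10))))
  hc2 <- hierarchical_cluster(pts, "samples", linkage = "average")$samples
  coph <- as.matrix(stats::cophenetic(hc2))
  oracle <- naive_upgma_cophenetic(as.matrix(stats::dist(t(pts))))
  dimnames(oracle) <- dimnames(coph)
  expect_equal(coph, oracle, tolerance = 1e-10)

  expect_error(hierarchical_cluster(mat[, 1, drop = FALSE], "samples"), ">= 2")
})

test_that("PCM: diagonal, anticorrelation, intra/inter split", {
  p <- c(1, 2, 3, 4)
  mat <- cbind(s1 = p, s2 = -p, s3 = p + 0.01)
  rownames(mat) <- sprintf("f%d", 1:4)
  ann <- sample_annotation(c("s1", "s2", "s3"), c("x", "y", "x"))
  res <- pcm(mat, ann)
  expect_equal(diag(res$cor), rep(1, 3), ignore_attr = TRUE)
  expect_equal(res$cor["s1", "s2"], -1)
  expect_equal(res$cor, t(res$cor))
  expect_length(res$intra, 1L)   # (s1, s3)
  expect_length(res$inter, 2L)
  expect_gt(min(res$intra), max(res$inter))

  flat <- cbind(s1 = rep(1, 3), s2 = c(1, 2, 3))
  rownames(flat) <- sprintf("f%d", 1:3)
  expect_warning(pz <- pcm(flat), "zero-variance")
  expect_true(is.na(pz$cor["s1", "s2"]))
})

test_that("metagene PCM sharpens intra-category correlation vs single genes", {
  sim <- fixture_sim()
  som <- fixture_som()
  ann <- sim$annotation
  r_gene <- pcm(fixture_centered()$values, ann)
  r_meta <- pcm(metagene_matrix(som), ann)
  expect_gt(stats::median(r_meta$intra), stats::median(r_gene$intra))
  expect_gt(stats::median(r_meta$intra), 0.8)
})

test_that("ICA recovers mixed sources and separates clusters deterministically", {
  # unmixing oracle: two independent uniforms, random 2x2 mixing
  S <- somatlas:::with_seed(40L, cbind(runif(400) - 0.5, runif(400) - 0.5))
  A <- matrix(c(2, 1, 1, 3), 2)
  X <- t(S %*% t(A))                       # 2 features x 400 "samples"
  dimnames(X) <- list(c("f1", "f2"), sprintf("s%03d", 1:400))
  rec <- ica_project(X, 2, seed = 1L)
  cors <- abs(stats::cor(rec, S))
  best <- apply(cors, 1, max)
  expect_true(all(best > 0.95))
  expect_setequal(apply(cors, 1, which.max), c(1, 2))  # up to permutation

  expect_identical(ica_project(X, 2, seed = 1L), rec)     # seed determinism

  # two well-separated isotropic clusters separate along one component
  cl <- somatlas:::with_seed(41L, {
    a <- matrix(rnorm(20 * 5), 5, 20)
    b <- matrix(rnorm(20 * 5), 5, 20) + 10
    cbind(a, b)
  })
  dimnames(cl) <- list(sprintf("f%d", 1:5), sprintf("s%02d", 1:40))
  coords <- ica_project(cl, 2, seed = 2L)
  lab <- rep(c("a", "b"), each = 20)
  # the clusters separate along one component: 1-d silhouette on the
  # component with the largest between-cluster mean gap
  gaps <- abs(colMeans(coords[lab == "a", ]) - colMeans(coords[lab == "b", ]))
  z <- coords[, which.max(gaps)]
  D <- abs(outer(z, z, `-`))
  sil <- vapply(1:40, function(i) {
    same <- setdiff(which(lab == lab[i]), i)
    ai <- mean(D[i, same])
    bi <- mean(D[i, lab != lab[i]])
    (bi - ai) / max(ai, bi)
  }, 0)
  expect_gt(mean(sil), 0.8)

  expect_error(ica_project(cl[, 1:2], 2), "more samples")
})

test_that("F-score: separation, permutation null, scale invariance", {
  clusters <- somatlas:::with_seed(50L, {
    a <- matrix(rnorm(10 * 6, sd = 0.2), 10, 6)
    b <- matrix(rnorm(10 * 6, sd = 0.2), 10, 6) + 4
    cbind(a, b)
  })
  dimnames(clusters) <- list(sprintf("f%d", 1:10), sprintf("s%02d", 1:12))
  lab <- rep(c("x", "y"), each = 6)
  f <- f_score(clusters, lab)
  expect_gt(f, 1)
  expect_equal(f_score(clusters * 7.3, lab), f, tolerance = 1e-9)  # scale invariant

  perm_f <- somatlas:::with_seed(51L, vapply(1:100, function(i)
    f_score(clusters, sample(lab)), 0))
  expect_lt(abs(stats::median(perm_f) - 1), 0.5)   # ~1 under the null

  expect_error(f_score(clusters, c(rep("x", 11), "y")), ">= 2 samples")
})

test_that("IC-variance fraction: self ratio, degenerate and symmetric cases", {
  coords <- somatlas:::with_seed(52L, matrix(rnorm(60), 30, 2,
    dimnames = list(sprintf("s%02d", 1:30), c("IC1", "IC2"))))
  lab <- rep(c("a", "b", "c"), each = 10)
  expect_equal(ic_variance_fraction(coords, rep("one", 30), "one"), 100)

  collapsed <- coords; collapsed[lab == "a", ] <- 0
  expect_equal(ic_variance_fraction(collapsed, lab, "a",
                                    reference_categories = c("a", "b", "c")), 0)

  fr <- vapply(c("a", "b", "c"), function(cc)
    ic_variance_fraction(coords, lab, cc), 0)
  expect_true(all(abs(fr - 33.3) < 25))   # equal-variance symmetry, loose band

  expect_warning(
    expect_true(is.na(ic_variance_fraction(coords, c("solo", lab[-1]), "solo"))),
    "< 2 samples")
})

test_that("cluster-size fraction reads heatmap blocks operationally", {
  # features exclusively overexpressed in one category -> 100% for it
  lab <- rep(c("x", "y"), each = 4)
  pure <- somatlas:::with_seed(53L, matrix(rnorm(160, sd = 0.1), 20, 8))
  pure[, lab == "x"] <- pure[, lab == "x"] + 2
  dimnames(pure) <- list(sprintf("f%02d", 1:20), sprintf("s%d", 1:8))
  expect_equal(cluster_size_fraction(pure, lab, "x", k = 2), 100)

  # fractions across categories sum to <= 100
  mixed <- somatlas:::with_seed(54L, matrix(rnorm(240), 30, 8,
    dimnames = list(sprintf("f%02d", 1:30), sprintf("s%d", 1:8))))
  fr <- vapply(c("x", "y"), function(cc)
    cluster_size_fraction(mixed, lab, cc, k = 2), 0)
  expect_lte(sum(fr), 100 + 1e-9)

  # planted 3-module fixture: each module's share within 10 points of truth
  sim3 <- generate_planted_modules(n_genes = 300L, n_samples = 12L,
                                   n_modules = 3L, genes_per_module = 100L,
                                   samples_per_module = 4L, sigma = 0.1,
                                   seed = 77L)
  cen3 <- preprocess(sim3$expression)
  lab3 <- annotation_categories(sim3$annotation, sample_ids(cen3))
  for (j in 1:3) {
    fr_j <- cluster_size_fraction(cen3$values, lab3, sprintf("module_%d", j), k = 3)
    expect_lt(abs(fr_j - 100 / 3), 10)
  }
})
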