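test_that("feature ranking: dominance, absolute max, independent sort oracle", {
  mat <- rbind(flat = c(0, 0, 0), hit = c(0, 0, 2))
  colnames(mat) <- c("a", "b", "c")
  expect_identical(rank_features(mat, "fc")$id[1], "hit")
  expect_identical(rank_features(mat, "variance")$id[1], "hit")

  expect_equal(rank_features(rbind(x = c(-3, 1)), "fc")$score[1], 3)

  vals <- somatlas:::with_seed(12L, matrix(rnorm(300), 50, 6,
    dimnames = list(sprintf("f%02d", 1:50), sprintf("s%d", 1:6))))
  for (crit in c("fc", "variance")) {
    rk <- rank_features(vals, crit)
    score <- if (crit == "fc") apply(abs(vals), 1, max) else apply(vals, 1, stats::var)
    oracle <- names(sort(-score))  # independent sort
    expect_identical(rk$id, oracle)
    expect_identical(rk$rank, seq_len(50L))
  }
})

test_that("top lists nest and clip", {
  vals <- somatlas:::with_seed(13L, matrix(rnorm(1200), 200, 6,
    dimnames = list(sprintf("f%03d", 1:200), sprintf("s%d", 1:6))))
  rk <- rank_features(vals, "fc")
  expect_identical(top_list(rk, 200)$ids, rk$id)                 # vacuous
  expect_identical(top_list(rk, 1)$ids, rk$id[1])                # forced
  t10 <- top_list(rk, 10); t50 <- top_list(rk, 50); t200 <- top_list(rk, 200)
  expect_true(all(t10$ids %in% t50$ids))                         # nesting
  expect_true(all(t50$ids %in% t200$ids))
  expect_warning(clipped <- top_list(rk, 500), "clipping")
  expect_length(clipped$ids, 200L)
  expect_error(top_list(rk, 0), "positive")
})

test_that("metagene lists imply their gene unions with compression factors", {
  som <- fixture_som()
  mg <- metagene_matrix(som)
  mg <- mg[som$assignment$n_k > 0L, , drop = FALSE]
  rk <- rank_features(mg, "fc")
  fs <- top_list(rk, 50, "metagene", "fc")
  info <- metagene_list_genes(fs, som)
  expect_gte(info$n_genes, length(fs$ids))      # each metagene carries >= 1 gene
  expect_true(all(info$gene_union %in% gene_ids(fixture_centered())))
  expect_length(info$compression, 50L)
  expect_true(all(is.finite(info$compression)))
})

test_that("compression factor arithmetic", {
  expect_equal(compression_factor(10, 40, 400), 1)        # average population
  expect_equal(compression_factor(308, 3600, 22277), 22277 / (308 * 3600))
  expect_equal(compression_factor(308, 3600, 22277), 0.0201, tolerance = 1e-2)
  expect_warning(cf <- compression_factor(c(0, 2), 10, 100), "empty")
  expect_true(is.na(cf[1]) && cf[2] == 5)
})

test_that("shrinkage-t: null rows, planted-signal recovery", {
  # all-zero gene row: t = 0, p = 1, fdr at the pi0 cap
  vals <- somatlas:::with_seed(20L, matrix(rnorm(200 * 8, sd = 0.3), 200, 8))
  dimnames(vals) <- list(sprintf("g%03d", 1:200), sprintf("s%d", 1:8))
  vals[1, ] <- 5                                   # constant row -> centered zero
  em <- center_profiles(expr_matrix(vals, "log10"))
  res <- shrinkage_t_fdr(em)
  expect_equal(res$score[1], 0)
  expect_equal(res$p[1], 1)
  expect_equal(res$fdr[1], max(res$fdr))

  # 90% null + 10% genes with one large spike: fdr < 0.05 list is >= 80% true
  n <- 1000L
  sig <- somatlas:::with_seed(21L, {
    m <- matrix(rnorm(n * 10, sd = 0.2), n, 10)
    spikes <- cbind(1:100, sample(10, 100, replace = TRUE))
    m[spikes] <- m[spikes] + 3
    m
  })
  dimnames(sig) <- list(sprintf("g%04d", 1:n), sprintf("s%02d", 1:10))
  em2 <- center_profiles(expr_matrix(sig, "log10"))
  res2 <- shrinkage_t_fdr(em2)
  hits <- which(res2$fdr < 0.05)
  expect_gt(length(hits), 20L)
  expect_gte(mean(hits <= 100), 0.8)

  expect_error(shrinkage_t_fdr(center_profiles(expr_matrix(
    matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
    "log10"))), "3 samples")
})

test_that("pure-null FDR calibration stays within the 1.5x band", {
  for (a in c(0.005, 0.01, 0.05)) {
    frac <- vapply(1:5, function(s) {
      vals <- somatlas:::with_seed(100L + s,
        matrix(rnorm(500 * 8, sd = 0.2), 500, 8,
               dimnames = list(sprintf("g%03d", 1:500), sprintf("s%d", 1:8))))
      res <- shrinkage_t_fdr(center_profiles(expr_matrix(vals, "log10")))
      mean(res$fdr < a)
    }, 0)
    expect_lte(mean(frac), 1.5 * a)
  }
})

test_that("metagene FDR is the geometric mean of member FDRs", {
  som <- fixture_som()
  gene_fdr <- stats::setNames(rep(0.01, 2000L), gene_ids(fixture_centered()))
  mf <- metagene_fdr(som, gene_fdr)
  pop <- som$assignment$n_k > 0L
  expect_equal(unname(mf[pop]), rep(0.01, sum(pop)), tolerance = 1e-12)
  expect_true(all(is.na(mf[!pop])))

  # {1, 0.0001} -> 0.01; always between member min and max
  expect_equal(10^mean(log10(c(1, 0.0001))), 0.01)
  rnd <- somatlas:::with_seed(23L,
    stats::setNames(runif(2000L, 1e-6, 1), gene_ids(fixture_centered())))
  mf2 <- metagene_fdr(som, rnd)
  for (k in which(pop)[1:50]) {
    f <- rnd[som$assignment$members[[k]]]
    expect_gte(mf2[k], min(f) - 1e-12); expect_lte(mf2[k], max(f) + 1e-12)
  }
})

test_that("FDR filter and Venn counts", {
  tab <- data.frame(id = c("a", "b", "c", "d"),
                    fdr = c(0.001, 0.2, 0.04, 0.5),
                    score = c(5, 1, 3, 0))
  fs <- fdr_filter(tab, 0.05)
  expect_identical(fs$ids, c("a", "c"))
  expect_identical(fs$criterion, "fdr")
  expect_equal(venn_counts(fs, c("c", "d")),
               c(only_a = 1L, shared = 1L, only_b = 1L))
})
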