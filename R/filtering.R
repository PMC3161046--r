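#' Rank features by fold change or variance
#'
#' Works identically on single genes and on metagenes (any features x
#' samples matrix of centered values). The FC score of a feature is the
#' maximum over samples of its absolute logged fold change (one pooled
#' ranking serving all samples); the variance score is the variance of its
#' expression profile. Features are ordered by decreasing score, ties by id.
#'
#' @param mat features x samples numeric matrix (rownames = feature ids).
#' @param criterion `"fc"` or `"variance"`.
#' @param per_sample_union for `"fc"` only: rank instead by concatenating
#'   per-sample top lists (round-robin over samples by |FC|); provided for
#'   robustness studies.
#' @return data.frame (id, score, rank) in rank order.
#' @export
rank_features <- function(mat, criterion = c("fc", "variance"),
                          per_sample_union = FALSE) {
  criterion <- match.arg(criterion)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  ids <- rownames(mat)
  score <- switch(criterion,
                  fc = apply(abs(mat), 1L, max),
                  variance = row_vars(mat))
  if (criterion == "fc" && per_sample_union) {
    # round-robin: best feature of each sample, then second-best, ...
    ord_by_sample <- apply(-abs(mat), 2L, order)
    seen <- character(0)
    for (r in seq_len(nrow(mat))) for (m in seq_len(ncol(mat))) {
      id <- ids[ord_by_sample[r, m]]
      if (!id %in% seen) seen <- c(seen, id)
    }
    ord <- match(seen, ids)
  } else {
    ord <- order(-score, ids)
  }
  data.frame(id = ids[ord], score = unname(score[ord]),
             rank = seq_along(ord), row.names = NULL)
}

#' Top-list feature selection
#'
#' The simplest filter: keep the first `n` features of a ranking (typical
#' lengths 100, 1000, 3600). Longer-than-available requests are clipped with
#' a warning, so `n = Inf` selects everything.
#'
#' @param ranked a [rank_features()] data.frame (or any data.frame with an
#'   `id` column in rank order).
#' @param n list length.
#' @param level `"single_gene"` or `"metagene"` (bookkeeping only).
#' @param criterion criterion label carried along (bookkeeping only).
#' @return an object of class `filtered_set`: `ids` (in rank order),
#'   `scores`, `level`, `criterion`, `n_requested`.
#' @export
top_list <- function(ranked, n, level = c("single_gene", "metagene"),
                     criterion = "fc") {
  level <- match.arg(level)
  if (n < 1) stopf("`n` must be a positive integer")
  if (n > nrow(ranked)) {
    warnf("requested %s features but only %d available; clipping", format(n), nrow(ranked))
    n <- nrow(ranked)
  }
  head_ <- ranked[seq_len(n), ]
  structure(list(ids = head_$id, scores = head_$score, level = level,
                 criterion = criterion, n_requested = n),
            class = "filtered_set")
}

#' @export
print.filtered_set <- function(x, ...) {
  cat(sprintf("<filtered_set> %s/%s, %d features\n", x$level, x$criterion,
              length(x$ids)))
  invisible(x)
}

#' Single-gene union and compression bookkeeping of a metagene list
#'
#' A metagene stands for its minicluster, so a metagene top-list implies the
#' union of the member genes — typically several-fold more genes than list
#' entries. Each selected metagene carries its compression factor
#' F_k = N / (n_k K).
#'
#' @param fs a metagene-level [filtered_set()] whose ids are `mg_<k>` (as
#'   produced by ranking [metagene_matrix()] rows).
#' @param som the [train_som()] result.
#' @return list: `gene_union` (character), `compression` (named per
#'   metagene), `n_metagenes`, `n_genes`.
#' @export
metagene_list_genes <- function(fs, som) {
  stopifnot(inherits(fs, "filtered_set"), inherits(som, "trained_som"))
  k <- as.integer(sub("^mg_", "", fs$ids))
  if (any(is.na(k))) stopf("filtered set ids are not metagene ids (mg_<k>)")
  genes <- sort(unique(unlist(som$assignment$members[k])))
  n_k <- som$assignment$n_k[k]
  Fk <- compression_factor(n_k, som$grid$K, length(som$assignment$bmu))
  names(Fk) <- fs$ids
  list(gene_union = genes, compression = Fk,
       n_metagenes = length(k), n_genes = length(genes))
}

#' Profile-specific compression factor
#'
#' F_k = (n_k K / N)^-1 = N / (n_k K): the reweighting a gene experiences
#' when represented by its metagene. F_k = 1 for an average-population node,
#' < 1 for crowded nodes (their genes are down-weighted), undefined (NA,
#' flagged by a warning) for empty nodes.
#'
#' @param n_k node population(s).
#' @param K total number of metagenes.
#' @param N total number of genes.
#' @return numeric vector of compression factors.
#' @export
compression_factor <- function(n_k, K, N) {
  out <- ifelse(n_k >= 1, N / (n_k * K), NA_real_)
  if (any(n_k < 1)) warnf("compression factor undefined for empty nodes (NA)")
  out
}

#' Shrinkage-t scores and local FDR for single genes
#'
#' Moderated differential-expression test on the centered matrix. Per gene
#' and sample, the noise SD is estimated leave-one-out (the profile SD with
#' the tested sample removed — a single strongly differential sample must
#' not inflate its own noise estimate and mask itself), shrunk toward the
#' median of all leave-one-out variances with an intensity estimated from
#' the variance of the per-gene variance estimates, and stabilized by a
#' fudge s0 = 0.01 * median SD. The gene score is
#' max_m |dE_{g,m} / (s*_{g,m} + s0)|; its two-sided p-value accounts for
#' the maximum over M samples via the order-statistic tail
#' p = 1 - (1 - p_single)^M with p_single from the t distribution on M - 2
#' df (the leave-one-out estimate loses one further df). Local FDR follows
#' the standard two-component mixture: the null proportion pi0 is read off
#' the p > 0.5 half, the marginal density f(p) comes from the Grenander
#' (monotone-decreasing) estimator, and fdr(p) = min(1, pi0 / f(p)).
#'
#' @param em centered [expr_matrix()] with M >= 3 samples.
#' @return data.frame (id, score, p, fdr) in input gene order; attributes
#'   `pi0` and `lambda` (shrinkage intensity).
#' @export
shrinkage_t_fdr <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "centered") stopf("shrinkage_t_fdr expects centered values")
  X <- em$values
  M <- ncol(X)
  if (M < 3L) stopf("need at least 3 samples for the t reference distribution")
  ss <- rowSums(X^2)                       # rows are centered
  v <- ss / (M - 1)
  # leave-one-out variance: remove sample m, re-center the rest
  v_loo <- pmax((ss - X^2 * M / (M - 1)) / (M - 2), 0)
  v_med <- stats::median(v_loo)
  # variance of each per-gene variance estimate drives the shrinkage weight
  W <- X^2
  var_v <- M / (M - 1)^3 * rowSums((W - rowMeans(W))^2)
  denom <- sum((v - stats::median(v))^2)
  lambda <- if (denom > 0) min(1, sum(var_v) / denom) else 1
  s_star <- sqrt(lambda * v_med + (1 - lambda) * v_loo)
  s0 <- 0.01 * stats::median(sqrt(v))
  t_mat <- X / (s_star + s0)
  score <- apply(abs(t_mat), 1L, max)
  p_single <- 2 * stats::pt(-score, df = M - 2)
  p <- 1 - (1 - p_single)^M
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  fdr <- .local_fdr(p)
  out <- data.frame(id = rownames(X), score = unname(score), p = unname(p),
                    fdr = unname(fdr), row.names = NULL)
  attr(out, "pi0") <- attr(fdr, "pi0")
  attr(out, "lambda") <- lambda
  out
}

# local FDR via the Grenander estimator: f(p) is the slope of the least
# concave majorant of the empirical CDF of the p-values (monotone
# non-increasing by construction), pi0 comes from the p > 0.5 half, and
# fdr(p) = min(1, pi0 / f(p)) — automatically non-decreasing in p.
.local_fdr <- function(p) {
  n <- length(p)
  pi0 <- min(1, mean(p > 0.5) * 2)
  ux <- sort(unique(p))
  Fy <- stats::ecdf(p)(ux)
  x <- c(0, ux); y <- c(0, Fy)
  if (x[length(x)] < 1) { x <- c(x, 1); y <- c(y, 1) }
  # least concave majorant = upper hull of the ECDF points
  hull <- c(1L, 2L)
  for (i in seq_len(length(x) - 2L) + 2L) {
    while (length(hull) >= 2L) {
      j <- hull[length(hull)]; k <- hull[length(hull) - 1L]
      cross <- (x[j] - x[k]) * (y[i] - y[k]) - (y[j] - y[k]) * (x[i] - x[k])
      if (cross >= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  hx <- x[hull]; hy <- y[hull]
  slopes <- diff(hy) / diff(hx)
  seg <- pmin(pmax(findInterval(p, hx, left.open = TRUE), 1L), length(slopes))
  out <- pmin(1, pi0 / pmax(slopes[seg], 1e-300))
  attr(out, "pi0") <- pi0
  out
}

#' Metagene local FDR
#'
#' The FDR of a metagene is the log-average (geometric mean) of the single
#' gene FDRs of its minicluster. Empty nodes are undefined (NA).
#'
#' @param som a [train_som()] result.
#' @param gene_fdr named numeric vector of single-gene FDRs (names = gene
#'   ids), e.g. the `fdr` column of [shrinkage_t_fdr()].
#' @return numeric vector of length K, named `mg_<k>`.
#' @export
metagene_fdr <- function(som, gene_fdr) {
  stopifnot(inherits(som, "trained_som"), !is.null(names(gene_fdr)))
  out <- vapply(som$assignment$members, function(g) {
    f <- gene_fdr[g]
    if (!length(f)) NA_real_ else 10^mean(log10(f))
  }, 0)
  names(out) <- paste0("mg_", seq_along(out))
  out
}

#' FDR-threshold filter
#'
#' Keeps the features whose local FDR falls below the threshold (typical
#' choices 0.005, 0.01, 0.05), ranked by increasing FDR then score.
#'
#' @param fdr_table [shrinkage_t_fdr()] output, or a data.frame with `id`,
#'   `fdr` and optionally `score` columns.
#' @param threshold local FDR cutoff.
#' @param level bookkeeping, see [top_list()].
#' @return a `filtered_set` (criterion `"fdr"`).
#' @export
fdr_filter <- function(fdr_table, threshold = 0.01,
                       level = c("single_gene", "metagene")) {
  level <- match.arg(level)
  if (threshold <= 0 || threshold >= 1) stopf("`threshold` must be in (0, 1)")
  keep <- fdr_table$fdr < threshold
  sc <- if ("score" %in% names(fdr_table)) fdr_table$score else -fdr_table$fdr
  ord <- order(fdr_table$fdr[keep], -sc[keep], fdr_table$id[keep])
  structure(list(ids = fdr_table$id[keep][ord],
                 scores = fdr_table$fdr[keep][ord],
                 level = level, criterion = "fdr", n_requested = sum(keep)),
            class = "filtered_set")
}

#' Overlap (Venn) counts between two filtered sets
#' @param a,b `filtered_set`s (or character vectors of ids).
#' @return named integer vector (only_a, shared, only_b).
#' @export
venn_counts <- function(a, b) {
  ia <- if (inherits(a, "filtered_set")) a$ids else a
  ib <- if (inherits(b, "filtered_set")) b$ids else b
  c(only_a = length(setdiff(ia, ib)), shared = length(intersect(ia, ib)),
    only_b = length(setdiff(ib, ia)))
}
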