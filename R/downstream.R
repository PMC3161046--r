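#' Hierarchical clustering of samples and/or features
#'
#' Agglomerative clustering on Euclidean distances (the similarity measure
#' used throughout), default average linkage (UPGMA). `axis = "both"` gives
#' the two-way result whose orderings drive a clustered heatmap.
#'
#' @param mat features x samples numeric matrix.
#' @param axis `"samples"`, `"genes"` (= features) or `"both"`.
#' @param linkage one of `"single"`, `"complete"`, `"average"`, `"ward"`
#'   (mapped to `ward.D2`).
#' @return list with `samples` and/or `genes` `hclust` objects plus the
#'   corresponding leaf `order`s.
#' @export
hierarchical_cluster <- function(mat, axis = c("samples", "genes", "both"),
                                 linkage = c("average", "single", "complete", "ward")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  out <- list()
  if (axis %in% c("samples", "both")) {
    if (ncol(mat) < 2L) stopf("need >= 2 samples to cluster")
    out$samples <- stats::hclust(stats::dist(t(mat)), method = method)
    out$sample_order <- out$samples$order
  }
  if (axis %in% c("genes", "both")) {
    if (nrow(mat) < 2L) stopf("need >= 2 features to cluster")
    out$genes <- stats::hclust(stats::dist(mat), method = method)
    out$gene_order <- out$genes$order
  }
  out
}

#' Export a sample tree as Newick
#' @param hc an `hclust` object.
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stopf("Newick export needs the 'ape' package")
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Pairwise correlation map (PCM)
#'
#' Pearson correlation over the feature dimension for every pair of
#' samples, with the pairings split into intra- and inter-category groups
#' for the contrast histograms: compact tissue categories show intra-
#' category correlations near unity while unrelated categories spread
#' toward zero and below.
#'
#' @param mat features x samples matrix (single genes or metagenes).
#' @param annotation optional [sample_annotation()] used to split pairings.
#' @return an object of class `pcm`: `cor` (M x M, unit diagonal), `intra`,
#'   `inter` (off-diagonal r values by pairing type; `intra`/`inter` empty
#'   without annotation). Zero-variance samples give NA correlations with a
#'   warning.
#' @export
pcm <- function(mat, annotation = NULL) {
  if (ncol(mat) < 2L) stopf("need >= 2 samples")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0))
    warnf("zero-variance sample(s): %s; their correlations are NA",
          paste(colnames(mat)[sds == 0], collapse = ", "))
  C <- suppressWarnings(stats::cor(mat))
  diag(C) <- 1
  intra <- inter <- numeric(0)
  if (!is.null(annotation)) {
    cats <- annotation_categories(annotation, colnames(mat))
    ut <- upper.tri(C)
    same <- outer(cats, cats, `==`) & ut
    diff_ <- (!outer(cats, cats, `==`)) & ut
    intra <- C[same]
    inter <- C[diff_]
  }
  structure(list(cor = C, intra = intra, inter = inter), class = "pcm")
}

#' @export
print.pcm <- function(x, ...) {
  cat(sprintf("<pcm> %d x %d samples; %d intra- / %d inter-category pairings\n",
              nrow(x$cor), ncol(x$cor), length(x$intra), length(x$inter)))
  invisible(x)
}

# symmetric FastICA (tanh nonlinearity) on pre-whitened data; returns the
# k x k rotation. Deterministic given the seeded random init.
.fastica_rotation <- function(Z, k, seed, max_iter = 200L, tol = 1e-7) {
  n <- nrow(Z)
  W <- with_seed(seed, matrix(stats::rnorm(k * k), k, k))
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  for (it in seq_len(max_iter)) {
    S <- Z %*% W
    G <- tanh(S)
    gprime <- colMeans(1 - G^2)
    W1 <- crossprod(Z, G) / n - W %*% diag(gprime, k)
    W1 <- orth(W1)
    delta <- max(abs(abs(colSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Independent component projection of samples
#'
#' Whitens the samples (observations) in feature space via PCA, then
#' rotates to maximize non-Gaussianity (symmetric fixed-point FastICA,
#' tanh contrast). Components are ordered by explained variance of the
#' projected coordinates and sign-fixed (largest-magnitude coordinate
#' positive), but note the intrinsic indeterminacy: ICA plots are invariant
#' under reversing the direction of any coordinate axis, i.e. under mirror
#' and rotational symmetry operations.
#'
#' @param mat features x samples matrix.
#' @param n_components 2 (default) or 3.
#' @param seed integer; fixes the rotation's random initialization, making
#'   the output reproducible.
#' @param max_iter,tol fixed-point iteration controls.
#' @return M x n_components matrix of sample coordinates (rownames =
#'   sample ids, colnames `IC1`, `IC2`, ...).
#' @export
ica_project <- function(mat, n_components = 2L, seed = 42L,
                        max_iter = 200L, tol = 1e-7) {
  k <- as.integer(n_components)
  if (!k %in% c(2L, 3L)) stopf("`n_components` must be 2 or 3")
  M <- ncol(mat)
  if (M <= k) stopf("need more samples (%d) than components (%d)", M, k)
  X <- t(mat)                       # samples x features
  X <- sweep(X, 2L, colMeans(X))
  sv <- svd(X, nu = k, nv = 0L)
  if (sum(sv$d > 1e-10 * sv$d[1L]) < k)
    stopf("data rank < %d; cannot extract %d components", k, k)
  Z <- sv$u[, seq_len(k), drop = FALSE] * sqrt(M)   # whitened, unit covariance
  W <- .fastica_rotation(Z, k, seed, max_iter, tol)
  S <- Z %*% W
  # order by the variance each component explains in the original data
  expl <- (sv$d[seq_len(k)]^2) %*% (W^2)
  ord <- order(-as.numeric(expl))
  S <- S[, ord, drop = FALSE]
  for (j in seq_len(k)) if (S[which.max(abs(S[, j])), j] < 0) S[, j] <- -S[, j]
  dimnames(S) <- list(colnames(mat), paste0("IC", seq_len(k)))
  S
}

#' F-score: inter- to intra-class variance ratio of sample distances
#'
#' Quality measure for a clustering of samples into known categories: the
#' classic one-way analysis-of-variance ratio computed from the pairwise
#' Euclidean distances between samples (the distance-based pseudo-F). With
#' squared pairwise distances d2, total scatter SST = sum of all d2 / n and
#' within-class scatter SSW = per-category sum of d2 / category size; then
#' \deqn{F = \frac{(SST - SSW)/(k-1)}{SSW/(n-k)}.}
#' Compact, well-separated categories give F >> 1; random labels give
#' F ~ 1; the statistic is invariant under global scaling and rigid
#' rotation of the data.
#'
#' @param mat features x samples matrix.
#' @param labels category label per sample (length M); restrict to the
#'   categories of interest before calling, or use `categories`.
#' @param categories optional subset of categories to evaluate.
#' @return a single number; `+Inf` (with a warning) when the within-class
#'   scatter is 0.
#' @export
f_score <- function(mat, labels, categories = NULL) {
  labels <- as.character(labels)
  if (length(labels) != ncol(mat)) stopf("one label per sample required")
  if (!is.null(categories)) {
    keep <- labels %in% categories
    mat <- mat[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (any(table(labels) < 2L)) stopf("every category needs >= 2 samples")
  n <- ncol(mat)
  k <- length(unique(labels))
  if (k < 2L) stopf("need >= 2 categories")
  D2 <- as.matrix(stats::dist(t(mat)))^2
  sst <- sum(D2[upper.tri(D2)]) / n
  ssw <- 0
  for (g in unique(labels)) {
    i <- which(labels == g)
    ssw <- ssw + sum(D2[i, i][upper.tri(D2[i, i, drop = FALSE])]) / length(i)
  }
  if (ssw == 0) {
    warnf("within-class scatter is 0; F = Inf")
    return(Inf)
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

#' Relative IC-coordinate variance of one category
#'
#' (var IC1 + var IC2) within the category, relative to the summed
#' per-category (var IC1 + var IC2) over the reference categories, in
#' percent — the relative size a category's cluster occupies in the ICA
#' plot. The denominator sums each reference category's own within-category
#' variance (so equal-variance categories score equal shares regardless of
#' how far apart their clusters sit).
#'
#' @param coords sample coordinates from [ica_project()] (>= 2 columns; the
#'   first two are used).
#' @param labels category label per sample.
#' @param category the category to evaluate.
#' @param reference_categories categories summed into the denominator
#'   (default: all labels present; must include `category`).
#' @return percent in `[0, 100]`; NA (with a warning) for a single-sample
#'   category.
#' @export
ic_variance_fraction <- function(coords, labels, category,
                                 reference_categories = unique(labels)) {
  labels <- as.character(labels)
  stopifnot(nrow(coords) == length(labels), ncol(coords) >= 2L)
  if (!category %in% labels) stopf("category '%s' not present", category)
  if (!category %in% reference_categories)
    stopf("`reference_categories` must include '%s'", category)
  if (sum(labels == category) < 2L) {
    warnf("category '%s' has < 2 samples; undefined", category)
    return(NA_real_)
  }
  vsum <- function(cat_) {
    i <- labels == cat_
    if (sum(i) < 2L) return(NA_real_)
    sum(apply(coords[i, 1:2, drop = FALSE], 2L, stats::var))
  }
  denom <- sum(vapply(reference_categories, vsum, 0), na.rm = TRUE)
  100 * vsum(category) / denom
}

#' Fraction of features in a category-specific cluster
#'
#' Operational reading of a two-way heatmap block: features are cut into
#' `k` clusters (gene axis, Euclidean/chosen linkage); each cluster is
#' attributed to the category whose samples show its highest mean
#' expression; the statistic is the percentage of all features landing in
#' clusters attributed to `category`.
#'
#' @param mat features x samples matrix (typically already filtered).
#' @param labels category label per sample.
#' @param category the category of interest.
#' @param k number of feature clusters (default: number of distinct
#'   labels).
#' @param linkage see [hierarchical_cluster()].
#' @return percent in `[0, 100]`; 0 with a warning when no cluster is
#'   attributed to the category.
#' @export
cluster_size_fraction <- function(mat, labels, category,
                                  k = length(unique(labels)),
                                  linkage = "average") {
  labels <- as.character(labels)
  stopifnot(ncol(mat) == length(labels))
  if (nrow(mat) < k) stopf("fewer features than requested clusters")
  hc <- hierarchical_cluster(mat, axis = "genes", linkage = linkage)$genes
  cl <- stats::cutree(hc, k = k)
  cats <- unique(labels)
  assigned <- vapply(seq_len(k), function(ci) {
    prof <- colMeans(mat[cl == ci, , drop = FALSE])
    means <- vapply(cats, function(cc) mean(prof[labels == cc]), 0)
    cats[which.max(means)]
  }, "")
  if (!category %in% assigned) {
    warnf("no feature cluster attributed to category '%s'", category)
    return(0)
  }
  100 * sum(cl %in% which(assigned == category)) / nrow(mat)
}
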