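# connected components on the planar lattice; returns integer component id
# per candidate node (0 for non-candidates). BFS with an integer queue.
.lattice_components <- function(cand, grid, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  K <- grid$K; x <- grid$x; y <- grid$y
  comp <- integer(K)
  nb_dc <- if (connectivity == 4L) c(-1L, 1L, 0L, 0L) else c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  nb_dr <- if (connectivity == 4L) c(0L, 0L, -1L, 1L) else c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  cur <- 0L
  queue <- integer(K)
  for (k in seq_len(K)) {
    if (!cand[k] || comp[k] != 0L) next
    cur <- cur + 1L
    comp[k] <- cur
    queue[1L] <- k; head <- 1L; tail <- 1L
    while (head <= tail) {
      node <- queue[head]; head <- head + 1L
      nc <- grid$col[node] + nb_dc
      nr <- grid$row[node] + nb_dr
      ok <- nc >= 0L & nc < x & nr >= 0L & nr < y
      for (nn in (nr[ok] * x + nc[ok] + 1L)) {
        if (cand[nn] && comp[nn] == 0L) {
          comp[nn] <- cur
          tail <- tail + 1L
          queue[tail] <- nn
        }
      }
    }
  }
  comp
}

.spot_labels <- function(n, polarity) {
  base <- if (polarity == "over") LETTERS else letters
  if (n <= 26L) base[seq_len(n)]
  else c(base, paste0(base[1L], seq_len(n - 26L)))[seq_len(n)]
}

#' Segment over-/underexpression spots on the lattice
#'
#' Overexpression: nodes at or above the `quantile_threshold` quantile of
#' the node values are candidates; connected components (default
#' 8-connectivity) of at least `min_size` nodes become spots, labeled A, B,
#' C, ... in decreasing order of their extremal (peak) value. Underexpression
#' is the mirror image: quantile `1 - q`, values at or below it, labels a,
#' b, c, ... in increasing order of their minimum.
#'
#' @param node_values length-K numeric vector (e.g. a logFC portrait or a
#'   summary map).
#' @param grid the [som_grid()].
#' @param polarity `"over"` or `"under"`.
#' @param quantile_threshold candidate quantile q in (0, 1); default 0.98.
#' @param min_size minimum component size in nodes; default 3.
#' @param connectivity 4 or 8 (default) neighborhood on the lattice.
#' @param assignment optional [assign_genes()] result; if given, each spot
#'   also carries the union of its nodes' member gene ids.
#' @return an object of class `spot_set`: `polarity`, and `spots`, a list of
#'   `list(label, polarity, nodes, seed_node, peak_value, genes)` with
#'   1-based node indices. Zero spots (with a warning) when all node values
#'   are equal.
#' @export
detect_spots <- function(node_values, grid, polarity = c("over", "under"),
                         quantile_threshold = 0.98, min_size = 3L,
                         connectivity = 8L, assignment = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(length(node_values) == grid$K)
  q <- quantile_threshold
  if (!is.numeric(q) || q <= 0 || q >= 1)
    stopf("`quantile_threshold` must be in (0, 1)")
  if (diff(range(node_values)) == 0) {
    warnf("all node values are equal; no spots detected")
    return(structure(list(polarity = polarity, spots = list()), class = "spot_set"))
  }
  if (polarity == "over") {
    t_ <- stats::quantile(node_values, q, names = FALSE)
    cand <- node_values >= t_
  } else {
    t_ <- stats::quantile(node_values, 1 - q, names = FALSE)
    cand <- node_values <= t_
  }
  comp <- .lattice_components(cand, grid, connectivity)
  ids <- setdiff(unique(comp), 0L)
  spots <- list()
  for (cid in ids) {
    nodes <- which(comp == cid)
    if (length(nodes) < min_size) next
    ext <- if (polarity == "over") nodes[which.max(node_values[nodes])]
           else nodes[which.min(node_values[nodes])]
    spots[[length(spots) + 1L]] <- list(
      polarity = polarity, nodes = nodes, seed_node = ext,
      peak_value = node_values[ext])
  }
  if (length(spots)) {
    peak <- vapply(spots, `[[`, 0, "peak_value")
    seed <- vapply(spots, `[[`, 0L, "seed_node")
    ord <- if (polarity == "over") order(-peak, seed) else order(peak, seed)
    spots <- spots[ord]
    labels <- .spot_labels(length(spots), polarity)
    for (i in seq_along(spots)) {
      spots[[i]]$label <- labels[i]
      if (!is.null(assignment))
        spots[[i]]$genes <- sort(unique(unlist(assignment$members[spots[[i]]$nodes])))
    }
    spots <- lapply(spots, function(s) s[c("label", "polarity", "nodes",
                                           "seed_node", "peak_value",
                                           if (!is.null(assignment)) "genes")])
  }
  structure(list(polarity = polarity, spots = spots, threshold = t_),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set:%s> %d spot(s)\n", x$polarity, length(x$spots)))
  for (s in x$spots)
    cat(sprintf("  %s: %d nodes, peak %.3f at node %d%s\n", s$label,
                length(s$nodes), s$peak_value, s$seed_node,
                if (!is.null(s$genes)) sprintf(", %d genes", length(s$genes)) else ""))
  invisible(x)
}

#' Global spots of a trained map
#'
#' The pipeline-level segmentation: per-sample spots are collected into the
#' over-/under-summary maps ([summary_maps()]), and global spots are the
#' connected components of each summary map's non-zero support (a node is
#' non-zero exactly when it belonged to at least one per-sample spot, so no
#' second threshold is imposed on the master map). Member genes come from
#' the SOM assignment.
#'
#' @inheritParams summary_maps
#' @return list with `over` and `under` [detect_spots()]-style `spot_set`s
#'   plus the two summary maps under `$maps`.
#' @export
find_global_spots <- function(som, quantile_threshold = 0.98, min_size = 3L,
                              connectivity = 8L) {
  maps <- summary_maps(som, quantile_threshold, min_size, connectivity)
  gather <- function(map, polarity) {
    cand <- map$values != 0
    comp <- .lattice_components(cand, som$grid, connectivity)
    vals <- map$values
    sp <- list()
    for (cid in setdiff(unique(comp), 0L)) {
      nodes <- which(comp == cid)
      if (length(nodes) < min_size) next
      ext <- if (polarity == "over") nodes[which.max(vals[nodes])]
             else nodes[which.min(vals[nodes])]
      sp[[length(sp) + 1L]] <- list(polarity = polarity, nodes = nodes,
                                    seed_node = ext, peak_value = vals[ext])
    }
    if (length(sp)) {
      peak <- vapply(sp, `[[`, 0, "peak_value")
      seed <- vapply(sp, `[[`, 0L, "seed_node")
      ord <- if (polarity == "over") order(-peak, seed) else order(peak, seed)
      sp <- sp[ord]
      labels <- .spot_labels(length(sp), polarity)
      for (i in seq_along(sp)) {
        sp[[i]]$label <- labels[i]
        sp[[i]]$genes <- sort(unique(unlist(som$assignment$members[sp[[i]]$nodes])))
      }
      sp <- lapply(sp, function(s)
        s[c("label", "polarity", "nodes", "seed_node", "peak_value", "genes")])
    }
    structure(list(polarity = polarity, spots = sp), class = "spot_set")
  }
  list(over = gather(maps$over, "over"), under = gather(maps$under, "under"),
       maps = maps)
}

#' Spot x sample expression matrix
#'
#' e_{c,m}: the mean metagene value of spot c's nodes in sample m. The
#' attribute `"max_variant"` holds the value of each spot's extremal
#' metagene instead of the mean (the scale used for heatmap display).
#'
#' @param spots a `spot_set` (from [detect_spots()] or
#'   [find_global_spots()]).
#' @param som the [train_som()] result the spots were segmented on.
#' @return C x M numeric matrix, rownames = spot labels.
#' @export
spot_expression <- function(spots, som) {
  stopifnot(inherits(spots, "spot_set"), inherits(som, "trained_som"))
  C <- length(spots$spots)
  if (C == 0L) return(matrix(numeric(0), 0L, ncol(som$codebook),
                             dimnames = list(NULL, colnames(som$codebook))))
  e <- t(vapply(spots$spots, function(s)
    colMeans(som$codebook[s$nodes, , drop = FALSE]), numeric(ncol(som$codebook))))
  mx <- t(vapply(spots$spots, function(s) som$codebook[s$seed_node, ],
                 numeric(ncol(som$codebook))))
  rownames(e) <- rownames(mx) <- vapply(spots$spots, `[[`, "", "label")
  attr(e, "max_variant") <- mx
  e
}

#' Cluster-specificity entropy of one sample
#'
#' Normalized Shannon entropy of the cluster expression weights
#' \deqn{H_m = -\sum_c p_{c,m} \log_2 p_{c,m} / \log_2 C,}
#' with weights \eqn{w_{c,m} = \max(e_{c,m} - \min_c e_{c,m}, 0) +
#' \varepsilon} and \eqn{p = w / \sum w} (the shift makes the logged
#' expression values nonnegative before normalizing; see the methods
#' vignette). H has units of bits and ranges from 0 — one dominant, highly
#' expressed cluster — to 1 — uniform expression of all C clusters.
#'
#' @param e_m numeric vector of length C: the (logged) expression of the C
#'   clusters in one sample.
#' @param eps stabilizer added to the shifted weights (default 1e-12).
#' @return H_m in `[0, 1]`.
#' @export
cluster_specificity_entropy <- function(e_m, eps = 1e-12) {
  C <- length(e_m)
  if (C < 2L) stopf("entropy needs at least 2 clusters")
  w <- pmax(e_m - min(e_m), 0) + eps
  if (all(e_m == e_m[1L]))
    warnf("all cluster expression values equal; H = 1 (uniform) by convention")
  p <- w / sum(w)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  h <- -sum(plogp) / log2(C)
  min(max(h, 0), 1)
}

#' Per-sample specificity entropy of a spot x sample matrix
#' @param spot_expr C x M matrix from [spot_expression()].
#' @param eps see [cluster_specificity_entropy()].
#' @return named numeric vector of H_m per sample.
#' @export
specificity_entropy <- function(spot_expr, eps = 1e-12) {
  if (nrow(spot_expr) < 2L) stopf("entropy needs at least 2 clusters")
  apply(spot_expr, 2L, cluster_specificity_entropy, eps = eps)
}

#' Compare clusterings by specificity entropy
#'
#' Applies the same entropy machinery to gene clusterings produced by
#' arbitrary methods (the hooks accept externally produced assignments):
#' for every method, cluster expression is the mean expression of its member
#' genes per sample, and H_m is computed for every sample.
#'
#' @param em centered [expr_matrix()] (genes x samples).
#' @param cluster_assignments named list; each element a named vector
#'   mapping gene id to cluster label (C clusters, default expectation 10).
#' @return long data.frame (method, sample, entropy), boxplot-ready. Empty
#'   clusters are excluded with a warning.
#' @export
compare_cluster_methods <- function(em, cluster_assignments) {
  stopifnot(inherits(em, "expr_matrix"))
  X <- em$values
  out <- list()
  for (method in names(cluster_assignments)) {
    cl <- cluster_assignments[[method]]
    cl <- cl[names(cl) %in% rownames(X)]
    if (!length(cl)) {
      warnf("method '%s': no genes overlap the matrix; skipped", method)
      next
    }
    labs <- sort(unique(cl))
    ce <- t(vapply(labs, function(l) {
      g <- names(cl)[cl == l]
      colMeans(X[g, , drop = FALSE])
    }, numeric(ncol(X))))
    keep <- rowSums(is.na(ce)) == 0L
    if (!all(keep)) warnf("method '%s': excluding %d empty cluster(s)", method, sum(!keep))
    ce <- ce[keep, , drop = FALSE]
    h <- specificity_entropy(ce)
    out[[method]] <- data.frame(method = method, sample = names(h),
                                entropy = unname(h), row.names = NULL)
  }
  do.call(rbind, out)
}
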