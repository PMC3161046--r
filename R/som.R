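#' Planar rectangular SOM grid
#'
#' Nodes (tiles) are laid out row-major: node k (1-based internally) sits at
#' 0-based coordinates `(col, row)` with `k = row * x + col + 1`. The grid is
#' planar — no wraparound — so corner spots are meaningful landmarks.
#'
#' @param x,y number of tiles per dimension (positive integers).
#' @return an object of class `som_grid` with fields `x`, `y`, `K`, `col`,
#'   `row` (the latter two 0-based, length K).
#' @export
som_grid <- function(x, y = x) {
  x <- as.integer(x); y <- as.integer(y)
  if (is.na(x) || is.na(y) || x < 1L || y < 1L)
    stopf("grid dimensions must be positive integers")
  K <- x * y
  k <- 0:(K - 1L)
  structure(list(x = x, y = y, K = K, col = k %% x, row = k %/% x),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %d x %d = %d tiles (planar rectangular)\n", x$x, x$y, x$K))
  invisible(x)
}

#' Two-phase Kohonen training schedule
#'
#' The conventional two-phase recipe: an ordering phase with a wide
#' neighborhood that untangles the map, then a fine-tuning phase with a
#' narrow neighborhood. Radius (the Gaussian neighborhood's sigma, in grid
#' units) and learning rate alpha decay linearly per epoch within each
#' phase; one epoch presents every gene once in a seeded random order.
#'
#' @param grid a [som_grid()]; sets the default starting radius `x / 2`
#'   (floored at 3 so tiny grids keep a valid schedule).
#' @param phases list of phases, each a list with `epochs`, `radius_start`,
#'   `radius_end`, `alpha_start`, `alpha_end`.
#' @return an object of class `som_schedule`.
#' @export
som_schedule <- function(grid,
                         phases = list(
                           list(epochs = 2L, radius_start = max(grid$x / 2, 3), radius_end = 3,
                                alpha_start = 0.05, alpha_end = 0.02),
                           list(epochs = 2L, radius_start = 3, radius_end = 1,
                                alpha_start = 0.02, alpha_end = 0.01))) {
  for (ph in phases) {
    need <- c("epochs", "radius_start", "radius_end", "alpha_start", "alpha_end")
    if (!all(need %in% names(ph))) stopf("schedule phase missing fields")
    if (ph$epochs < 0) stopf("epochs must be >= 0")
    if (ph$radius_start <= 0 || ph$radius_end <= 0 || ph$alpha_start <= 0 || ph$alpha_end <= 0)
      stopf("schedule radii and learning rates must be positive")
    if (ph$radius_start < ph$radius_end)
      stopf("radius_start must be >= radius_end within a phase")
  }
  structure(list(phases = phases), class = "som_schedule")
}

#' Initialize a metagene codebook
#'
#' `pca_plane` (the deterministic default) spans the plane of the two
#' leading principal components of the gene profiles, linearly interpolated
#' over the grid so the untrained map already reflects the dominant
#' covariance structure. `random` draws each codebook entry uniformly from
#' the per-sample value range under the given seed.
#'
#' @param em centered [expr_matrix()] (genes x samples).
#' @param grid a [som_grid()].
#' @param method `"pca_plane"` or `"random"`.
#' @param seed integer; used by `"random"` (and by the fallback when the
#'   profile covariance is degenerate).
#' @return K x M numeric codebook matrix (columns named by sample).
#' @export
init_codebook <- function(em, grid, method = c("pca_plane", "random"), seed = 42L) {
  method <- match.arg(method)
  X <- if (inherits(em, "expr_matrix")) em$values else em
  M <- ncol(X)
  if (M < 2L) stopf("need at least 2 samples")
  if (grid$K < 4L) stopf("need a grid of at least 4 tiles")
  if (method == "pca_plane") {
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    sv <- svd(Xc, nu = 0L, nv = 2L)
    if (length(sv$d) < 2L || sv$d[2L] <= 1e-12 * max(sv$d[1L], 1e-300)) {
      warnf("profile covariance has rank < 2; falling back to random initialization")
      method <- "random"
    } else {
      # fix the SVD sign ambiguity so initialization is platform-stable
      v <- sv$v
      for (j in 1:2) if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
      sdv <- sv$d[1:2] / sqrt(nrow(X) - 1L)
      ux <- if (grid$x > 1L) seq(-1, 1, length.out = grid$x) else 0
      uy <- if (grid$y > 1L) seq(-1, 1, length.out = grid$y) else 0
      cb <- matrix(mu, grid$K, M, byrow = TRUE) +
        outer(2 * sdv[1L] * ux[grid$col + 1L], v[, 1L]) +
        outer(2 * sdv[2L] * uy[grid$row + 1L], v[, 2L])
      colnames(cb) <- colnames(X)
      return(cb)
    }
  }
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  cb <- with_seed(seed, {
    vapply(seq_len(M), function(m) stats::runif(grid$K, lo[m], hi[m]),
           numeric(grid$K))
  })
  colnames(cb) <- colnames(X)
  cb
}

# one sequential Kohonen pass; X items x dims, cb K x dims (modified copy
# returned). Neighborhood is Gaussian on Euclidean grid distance, truncated
# at 3 sigma for speed (h < 0.012 there).
.kohonen_epochs <- function(X, cb, grid, phases) {
  n <- nrow(X); K <- grid$K; M <- ncol(X)
  gc_ <- grid$col; gr_ <- grid$row
  for (ph in phases) {
    E <- ph$epochs
    if (E == 0L) next
    for (e in seq_len(E)) {
      frac <- (e - 1) / max(E - 1, 1)
      sigma <- ph$radius_start + (ph$radius_end - ph$radius_start) * frac
      alpha <- ph$alpha_start + (ph$alpha_end - ph$alpha_start) * frac
      cut2 <- (3 * sigma)^2
      ord <- sample.int(n)
      for (g in ord) {
        xg <- X[g, ]
        d2 <- .rowSums((cb - rep(xg, each = K))^2, K, M)
        bmu <- which.min(d2)
        gd2 <- (gc_ - gc_[bmu])^2 + (gr_ - gr_[bmu])^2
        idx <- which(gd2 <= cut2)
        w <- alpha * exp(-gd2[idx] / (2 * sigma^2))
        cb[idx, ] <- cb[idx, ] + w * (rep(xg, each = length(idx)) - cb[idx, ])
      }
    }
  }
  cb
}

#' Train a self-organizing map on gene expression profiles
#'
#' Sequential Kohonen training: each presented gene pulls its best-matching
#' unit (BMU, minimal Euclidean distance) and the BMU's Gaussian grid
#' neighborhood toward the gene's profile. After training, every gene is
#' assigned to its BMU, so each node becomes a *metagene*: the
#' representative profile of a minicluster of n_k real genes. Neighboring
#' metagenes end up with similar profiles, which is what makes the
#' per-sample mosaics smooth and comparable.
#'
#' @param em centered [expr_matrix()] (genes x samples).
#' @param grid a [som_grid()]; the default 60 x 60 suits genome-scale input
#'   (the tissue-specific spot count converges for x = y > 50); use a
#'   smaller grid for small data sets.
#' @param schedule a [som_schedule()].
#' @param seed integer; fixes initialization (if random) and the per-epoch
#'   gene presentation order. Identical inputs + seed give a bit-identical
#'   map.
#' @param init codebook initialization, see [init_codebook()].
#' @param codebook optional explicit K x M starting codebook (overrides
#'   `init`); useful for warm restarts and for testing fixed points.
#' @return an object of class `trained_som`: `grid`, `codebook` (K x M),
#'   `assignment` (see [assign_genes()]) and `meta` (seed, schedule, init,
#'   quantization error before/after each phase).
#' @export
train_som <- function(em, grid = som_grid(60L), schedule = som_schedule(grid),
                      seed = 42L, init = c("pca_plane", "random"),
                      codebook = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "centered")
    stopf("train_som expects centered differential expression; run preprocess()/center_profiles() first")
  init <- match.arg(init)
  X <- em$values
  if (nrow(X) < grid$K)
    warnf("fewer genes (%d) than tiles (%d); many nodes will stay empty",
          nrow(X), grid$K)
  cb <- if (is.null(codebook)) init_codebook(em, grid, init, seed) else {
    stopifnot(is.matrix(codebook), nrow(codebook) == grid$K, ncol(codebook) == ncol(X))
    init <- "explicit"
    codebook
  }
  qe <- c(before = .quantization_error(X, cb))
  cb <- with_seed(seed, .kohonen_epochs(X, cb, grid, schedule$phases))
  qe <- c(qe, after = .quantization_error(X, cb))
  assignment <- assign_genes(em, cb)
  structure(list(grid = grid, codebook = cb, assignment = assignment,
                 meta = list(seed = as.integer(seed), schedule = schedule,
                             init = init, quantization_error = qe)),
            class = "trained_som")
}

#' @export
print.trained_som <- function(x, ...) {
  cat(sprintf("<trained_som> %d x %d grid, %d genes, %d samples, %d empty tiles\n",
              x$grid$x, x$grid$y, length(x$assignment$bmu),
              ncol(x$codebook), sum(x$assignment$n_k == 0L)))
  invisible(x)
}

.quantization_error <- function(X, cb) {
  bmu <- .bmu_index(X, cb)
  mean(sqrt(rowSums((X - cb[bmu, , drop = FALSE])^2)))
}

# tie-tolerant vectorized argmin over codebook rows; ties (within 1e-9
# absolute on squared distance) break to the lowest node index
.bmu_index <- function(X, cb) {
  N <- nrow(X)
  bmu <- integer(N)
  cbn <- rowSums(cb^2)
  chunk <- max(1L, floor(4e6 / nrow(cb)))
  for (start in seq(1L, N, by = chunk)) {
    i <- start:min(start + chunk - 1L, N)
    D <- matrix(cbn, length(i), nrow(cb), byrow = TRUE) - 2 * X[i, , drop = FALSE] %*% t(cb)
    dmin <- D[cbind(seq_along(i), max.col(-D, ties.method = "first"))]
    bmu[i] <- max.col(D <= dmin + 1e-9, ties.method = "first")
  }
  bmu
}

#' Assign genes to their best-matching metagenes
#'
#' Each gene goes to the codebook row of minimal Euclidean distance; exact
#' ties break to the lowest node index. Populations n_k and per-node member
#' lists are derived from the assignment; empty nodes (n_k = 0) are allowed.
#'
#' @param em centered [expr_matrix()] or plain numeric matrix (genes x
#'   samples).
#' @param codebook K x M codebook matrix with matching sample count.
#' @return an object of class `som_assignment`: `bmu` (named integer vector,
#'   1-based node index per gene), `n_k` (integer vector of length K),
#'   `members` (list of gene-id vectors per node).
#' @export
assign_genes <- function(em, codebook) {
  X <- if (inherits(em, "expr_matrix")) em$values else em
  if (ncol(X) != ncol(codebook))
    stopf("gene profiles have %d samples but codebook has %d", ncol(X), ncol(codebook))
  K <- nrow(codebook)
  bmu <- .bmu_index(X, codebook)
  names(bmu) <- rownames(X)
  n_k <- tabulate(bmu, nbins = K)
  members <- split(rownames(X) %||% as.character(seq_len(nrow(X))), factor(bmu, levels = seq_len(K)))
  structure(list(bmu = bmu, n_k = n_k, members = unname(members)),
            class = "som_assignment")
}

#' Extract the metagene expression matrix
#'
#' The K x M codebook is the compressed data set every downstream step
#' (portraits, spots, filtering, clustering, second-level SOM) works from.
#'
#' @param som a [train_som()] result.
#' @return K x M numeric matrix, rownames `mg_<k>` (1-based node index),
#'   colnames the sample ids.
#' @export
metagene_matrix <- function(som) {
  stopifnot(inherits(som, "trained_som"))
  out <- som$codebook
  rownames(out) <- paste0("mg_", seq_len(nrow(out)))
  out
}

#' Grid distance between two nodes (Euclidean, in tile units)
#' @param grid a [som_grid()].
#' @param i,j 1-based node indices (vectorized).
#' @return numeric vector of distances.
#' @export
grid_distance <- function(grid, i, j) {
  sqrt((grid$col[i] - grid$col[j])^2 + (grid$row[i] - grid$row[j])^2)
}
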