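#' Per-sample metagene portrait
#'
#' Color-codes every tile of the map with its metagene's differential
#' expression in one sample. Three contrast scales serve different dynamic
#' ranges:
#' \describe{
#'   \item{logFC}{the codebook column itself — strong-to-moderate
#'     differential expression (the default, and the only contrast used by
#'     downstream statistics).}
#'   \item{WAD}{weighted average difference: each node value is multiplied
#'     by its min-max position within the sample, accentuating very strong
#'     overexpression.}
#'   \item{loglogFC}{sign-preserving `log10(1 + |v| / s)` with s the
#'     sample's median absolute node value — compresses large values,
#'     expands weak-to-moderate differential expression.}
#' }
#' Alternate contrasts affect rendering only, never downstream statistics.
#'
#' @param som a [train_som()] result.
#' @param sample_id one of the trained sample ids.
#' @param contrast `"logFC"`, `"WAD"` or `"loglogFC"`.
#' @return an object of class `som_portrait`: `sample_id`, `values`
#'   (length K), `contrast`.
#' @export
sample_portrait <- function(som, sample_id, contrast = c("logFC", "WAD", "loglogFC")) {
  stopifnot(inherits(som, "trained_som"))
  contrast <- match.arg(contrast)
  if (!sample_id %in% colnames(som$codebook))
    stopf("sample '%s' is not on this map", sample_id)
  v <- som$codebook[, sample_id]
  values <- switch(contrast,
    logFC = v,
    WAD = {
      rng <- range(v)
      if (diff(rng) == 0) {
        warnf("flat portrait for sample '%s': WAD contrast degenerates to zeros", sample_id)
        rep(0, length(v))
      } else v * (v - rng[1L]) / diff(rng)
    },
    loglogFC = {
      s <- stats::median(abs(v))
      if (s == 0) s <- 1
      sign(v) * log10(1 + abs(v) / s)
    })
  structure(list(sample_id = sample_id, values = unname(values), contrast = contrast),
            class = "som_portrait")
}

#' Population map
#'
#' log10 of the number of real genes per metagene. Empty nodes (n_k = 0) are
#' flagged via the `empty` field and carry `NA`, not `-Inf`: "no genes" is a
#' different statement than "one gene".
#'
#' @param assignment a [assign_genes()] result (or a `trained_som`).
#' @return an object of class `support_map` with `kind = "population"`,
#'   `values` (log10 n_k, length K) and `empty` (logical length K).
#' @export
population_map <- function(assignment) {
  if (inherits(assignment, "trained_som")) assignment <- assignment$assignment
  stopifnot(inherits(assignment, "som_assignment"))
  n_k <- assignment$n_k
  values <- ifelse(n_k >= 1L, log10(n_k), NA_real_)
  structure(list(kind = "population", values = values, empty = n_k == 0L),
            class = "support_map")
}

#' Variance map
#'
#' Per-node variability of the metagene profile over the samples,
#' \deqn{v_k = \frac{1}{M-1}\sum_m (\Delta e^{meta}_{k,m} - \langle\Delta
#' e^{meta}_k\rangle)^2.}
#' Near-zero nodes mark invariant metagenes, which together with empty
#' nodes carry no classification information.
#'
#' @param som a [train_som()] result.
#' @return a `support_map` with `kind = "variance"`.
#' @export
variance_map <- function(som) {
  stopifnot(inherits(som, "trained_som"))
  if (ncol(som$codebook) < 2L) stopf("variance map needs at least 2 samples")
  structure(list(kind = "variance", values = unname(row_vars(som$codebook)),
                 empty = som$assignment$n_k == 0L),
            class = "support_map")
}

#' Coarse-grained metagene profiling map
#'
#' Overview of the courses of the metagene profiles on a coarse (default
#' 8 x 8) mosaic: each coarse cell holds the population-weighted mean
#' profile of its fine nodes plus the summed member-gene count. If the
#' coarse dimensions do not divide the fine ones, the nearest integer
#' partition is used with a warning.
#'
#' @param som a [train_som()] result.
#' @param coarse_x,coarse_y coarse mosaic dimensions (each must not exceed
#'   the fine dimension).
#' @return an object of class `profiling_map`: `coarse_x`, `coarse_y`,
#'   `profiles` (C x M matrix, C = coarse_x * coarse_y, row-major cells),
#'   `counts` (integer, summing to N).
#' @export
profiling_map <- function(som, coarse_x = 8L, coarse_y = 8L) {
  stopifnot(inherits(som, "trained_som"))
  g <- som$grid
  coarse_x <- as.integer(coarse_x); coarse_y <- as.integer(coarse_y)
  if (coarse_x > g$x || coarse_y > g$y)
    stopf("coarse dimensions (%d x %d) exceed the grid (%d x %d)",
          coarse_x, coarse_y, g$x, g$y)
  if (g$x %% coarse_x != 0L || g$y %% coarse_y != 0L)
    warnf("coarse dims do not divide the grid; using the nearest integer partition")
  cell_col <- (g$col * coarse_x) %/% g$x
  cell_row <- (g$row * coarse_y) %/% g$y
  cell <- cell_row * coarse_x + cell_col + 1L
  C <- coarse_x * coarse_y
  n_k <- som$assignment$n_k
  M <- ncol(som$codebook)
  profiles <- matrix(0, C, M, dimnames = list(NULL, colnames(som$codebook)))
  counts <- integer(C)
  for (cc in seq_len(C)) {
    idx <- which(cell == cc)
    w <- n_k[idx]
    counts[cc] <- sum(w)
    profiles[cc, ] <- if (sum(w) > 0)
      colSums(som$codebook[idx, , drop = FALSE] * w) / sum(w)
    else colMeans(som$codebook[idx, , drop = FALSE])
  }
  structure(list(coarse_x = coarse_x, coarse_y = coarse_y,
                 profiles = profiles, counts = counts),
            class = "profiling_map")
}

#' Integral over-/underexpression summary maps
#'
#' Collects the over- (under-) expression spots of all individual sample
#' portraits into one master map: a node that belongs to at least one
#' per-sample overexpression spot carries the maximum of its metagene value
#' over those samples; all other nodes are 0. The under-summary is the
#' symmetric construction with minima on underexpression spots.
#'
#' @param som a [train_som()] result.
#' @param quantile_threshold,min_size,connectivity spot segmentation
#'   parameters, see [detect_spots()].
#' @return list with `over` and `under` `support_map`s (kinds
#'   `"over_summary"` / `"under_summary"`); each carries the per-sample spot
#'   node mask as attribute `"spot_nodes"` (K x M logical).
#' @export
summary_maps <- function(som, quantile_threshold = 0.98, min_size = 3L,
                         connectivity = 8L) {
  stopifnot(inherits(som, "trained_som"))
  K <- som$grid$K
  samples <- colnames(som$codebook)
  over_mask <- matrix(FALSE, K, length(samples), dimnames = list(NULL, samples))
  under_mask <- over_mask
  for (m in samples) {
    v <- som$codebook[, m]
    for (pol in c("over", "under")) {
      sp <- suppressWarnings(detect_spots(v, som$grid, polarity = pol,
                                          quantile_threshold = quantile_threshold,
                                          min_size = min_size,
                                          connectivity = connectivity))
      nodes <- unlist(lapply(sp$spots, `[[`, "nodes"))
      if (pol == "over") over_mask[nodes, m] <- TRUE else under_mask[nodes, m] <- TRUE
    }
  }
  over_vals <- under_vals <- numeric(K)
  for (k in seq_len(K)) {
    if (any(over_mask[k, ])) over_vals[k] <- max(som$codebook[k, over_mask[k, ]])
    if (any(under_mask[k, ])) under_vals[k] <- min(som$codebook[k, under_mask[k, ]])
  }
  empty <- som$assignment$n_k == 0L
  over <- structure(list(kind = "over_summary", values = over_vals, empty = empty),
                    class = "support_map")
  under <- structure(list(kind = "under_summary", values = under_vals, empty = empty),
                     class = "support_map")
  attr(over, "spot_nodes") <- over_mask
  attr(under, "spot_nodes") <- under_mask
  list(over = over, under = under)
}

#' @export
print.support_map <- function(x, ...) {
  cat(sprintf("<support_map:%s> %d tiles (%d empty)\n",
              x$kind, length(x$values), sum(x$empty)))
  invisible(x)
}

# blue -> green -> yellow -> red -> maroon, symmetric around 0
.som_palette <- function(n = 255L)
  grDevices::colorRampPalette(c("#00008B", "#0000FF", "#00A000", "#FFFF00",
                                "#FF0000", "#800000"))(n)

#' Draw a portrait or support map on the current graphics device
#'
#' Tiles are drawn as squares; the color scale is symmetric around 0 for
#' signed values (negating all node values mirrors the colors). Empty nodes
#' are grey.
#'
#' @param values length-K numeric node values (or a `som_portrait` /
#'   `support_map`).
#' @param grid the [som_grid()] the values live on.
#' @param main plot title.
#' @param symmetric center the color scale on 0 (default for signed maps).
#' @param empty optional logical mask of empty nodes, drawn grey.
#' @return invisibly, the matrix handed to [graphics::image()].
#' @export
plot_som_map <- function(values, grid, main = "", symmetric = TRUE, empty = NULL) {
  if (inherits(values, "som_portrait")) {
    if (main == "") main <- paste(values$sample_id, values$contrast)
    values <- values$values
  } else if (inherits(values, "support_map")) {
    if (main == "") main <- values$kind
    empty <- empty %||% values$empty
    symmetric <- !values$kind %in% c("population", "variance")
    values <- values$values
  }
  stopifnot(length(values) == grid$K)
  z <- matrix(values, grid$x, grid$y)[, , drop = FALSE]  # col-major: [col+1, row+1]
  lim <- if (symmetric) c(-1, 1) * max(abs(values), na.rm = TRUE)
         else range(values, na.rm = TRUE)
  if (!all(is.finite(lim)) || lim[1L] == lim[2L]) lim <- lim[1L] + c(-1, 1)
  graphics::image(seq_len(grid$x), seq_len(grid$y), z, zlim = lim,
                  col = .som_palette(), axes = FALSE, xlab = "", ylab = "",
                  main = main, useRaster = FALSE)
  grey_mask <- is.na(values) | (empty %||% rep(FALSE, grid$K))
  if (any(grey_mask)) {
    idx <- which(grey_mask)
    graphics::rect(grid$col[idx] + 0.5, grid$row[idx] + 0.5,
                   grid$col[idx] + 1.5, grid$row[idx] + 1.5,
                   col = "grey70", border = NA)
  }
  invisible(z)
}
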