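#' Hypergeometric overrepresentation p-value
#'
#' Upper-tail probability of drawing at least `x` members of a gene set of
#' size `N_set` when sampling a list of `n` genes without replacement from a
#' universe of `N_univ` genes:
#' \deqn{p = \sum_{i=x}^{\min(n, N_{set})}
#'   \binom{N_{set}}{i}\binom{N_{univ}-N_{set}}{n-i} / \binom{N_{univ}}{n}.}
#' Computed in log space via the hypergeometric CDF, so it is safe for
#' genome-scale arguments. All arguments are vectorized.
#'
#' @param x overlap between list and set.
#' @param n list size.
#' @param N_set set size.
#' @param N_univ universe size.
#' @param log10_p return log10(p) instead of p.
#' @return p in (0, 1] (or its log10); `x = 0` gives exactly 1.
#' @export
hypergeom_pvalue <- function(x, n, N_set, N_univ, log10_p = FALSE) {
  if (any(x < 0) || any(x > n) || any(x > N_set))
    stopf("need 0 <= x <= min(n, N_set)")
  if (any(n > N_univ) || any(N_set > N_univ))
    stopf("need n <= N_univ and N_set <= N_univ")
  if (log10_p) {
    lp <- stats::phyper(x - 1, N_set, N_univ - N_set, n,
                        lower.tail = FALSE, log.p = TRUE) / log(10)
    pmax(lp, -300)  # render floor, avoids -Inf downstream
  } else {
    stats::phyper(x - 1, N_set, N_univ - N_set, n, lower.tail = FALSE)
  }
}

#' Node-resolved overrepresentation map for one gene set
#'
#' For every tile k the member genes of its minicluster form the list
#' (n = n_k) and the overlap with the gene set gives the hypergeometric
#' p-value; the map is reported in units of log10(p). The universe is the
#' set of genes mapped onto the SOM (the draw is from mapped genes). Tiles
#' whose minicluster contains no gene of the set are flagged `absent`
#' (rendered white), empty tiles are flagged `empty`.
#'
#' @param assignment a [assign_genes()] result (or `trained_som`).
#' @param gene_set character vector of member gene ids.
#' @param universe character vector of universe gene ids; defaults to all
#'   genes in the assignment.
#' @return an object of class `overrep_map`: `log10_p` (length K), `x`
#'   (overlap per node), `absent`, `empty`, `set_size` (size after
#'   restriction to the universe).
#' @export
overrepresentation_map <- function(assignment, gene_set, universe = NULL) {
  if (inherits(assignment, "trained_som")) assignment <- assignment$assignment
  stopifnot(inherits(assignment, "som_assignment"))
  universe <- universe %||% names(assignment$bmu)
  set_in <- unique(gene_set[gene_set %in% universe])
  if (!length(set_in))
    warnf("gene set is disjoint from the universe; all tiles absent")
  N_univ <- length(universe)
  N_set <- length(set_in)
  K <- length(assignment$n_k)
  x <- vapply(assignment$members, function(g) sum(g %in% set_in), 0L)
  n <- assignment$n_k
  log10_p <- rep(0, K)
  pop <- n > 0L
  if (N_set > 0L && any(pop))
    log10_p[pop] <- hypergeom_pvalue(x[pop], n[pop], N_set, N_univ, log10_p = TRUE)
  structure(list(log10_p = log10_p, x = x, n = n,
                 absent = x == 0L, empty = n == 0L, set_size = N_set,
                 universe_size = N_univ),
            class = "overrep_map")
}

#' @export
print.overrep_map <- function(x, ...) {
  cat(sprintf("<overrep_map> %d tiles, set size %d / universe %d, min log10(p) = %.2f\n",
              length(x$log10_p), x$set_size, x$universe_size, min(x$log10_p)))
  invisible(x)
}

#' Ranked gene-set overrepresentation per spot
#'
#' For every spot, its member genes form the list and each set of the
#' collection is scored by the hypergeometric upper tail; sets are ranked by
#' increasing p (ties by name) and the `top_n` best are returned — the
#' guilt-by-association reading of a spot's biology. Raw p-values are
#' reported, plus a Benjamini-Hochberg column (`p_bh`, an extension — the
#' primary ranking is raw p).
#'
#' @param spots a `spot_set` whose spots carry member genes.
#' @param assignment the [assign_genes()] result (defines the universe).
#' @param collection a [gene_set_collection()].
#' @param top_n list length per spot (default 20).
#' @return named list (by spot label) of data.frames with columns
#'   (rank, set, category, x, n, N_set, p, log10_p, p_bh).
#' @export
spot_enrichment <- function(spots, assignment, collection, top_n = 20L) {
  if (inherits(assignment, "trained_som")) assignment <- assignment$assignment
  stopifnot(inherits(spots, "spot_set"), inherits(assignment, "som_assignment"),
            inherits(collection, "gene_set_collection"))
  universe <- names(assignment$bmu)
  N_univ <- length(universe)
  sets <- lapply(collection$sets, function(s) s[s %in% universe])
  out <- list()
  for (s in spots$spots) {
    genes <- s$genes
    if (is.null(genes) || !length(genes)) {
      warnf("spot '%s' has no member genes; empty result", s$label %||% "?")
      out[[s$label %||% "?"]] <- data.frame()
      next
    }
    n <- length(genes)
    x <- vapply(sets, function(m) sum(genes %in% m), 0L)
    N_set <- lengths(sets)
    ok <- N_set > 0L
    p <- rep(1, length(sets))
    p[ok] <- hypergeom_pvalue(x[ok], n, N_set[ok], N_univ)
    df <- data.frame(set = names(collection$sets),
                     category = unname(collection$category),
                     x = x, n = n, N_set = N_set, p = p,
                     log10_p = pmax(log10(pmax(p, 1e-300)), -300),
                     row.names = NULL)
    df$p_bh <- stats::p.adjust(df$p, method = "BH")
    df <- df[order(df$p, df$set), ]
    df <- utils::head(df, top_n)
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    out[[s$label]] <- df[, c("rank", "set", "category", "x", "n", "N_set",
                             "p", "log10_p", "p_bh")]
  }
  out
}
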