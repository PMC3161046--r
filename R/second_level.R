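#' Second-level SOM: map samples onto a metasample grid
#'
#' Uses the K metagene expression profiles of the M samples as input and
#' clusters the samples, not the genes: each sample is a K-vector, each
#' tile a representative *metasample*. The grid is deliberately larger than
#' the sample count (K_2SOM > M), so a considerable fraction of tiles stay
#' empty and similar samples land on nearby nodes.
#'
#' @param metagene_mat K x M matrix from [metagene_matrix()].
#' @param grid a [som_grid()]; default the smallest square with
#'   >= 2 tiles per sample (side `ceiling(sqrt(2 M))`).
#' @param schedule a [som_schedule()] (same Kohonen kernel as
#'   [train_som()]).
#' @param seed integer seed.
#' @param init see [init_codebook()].
#' @return an object of class `second_level_som`: `grid`, `codebook`
#'   (K_2SOM x K), `positions` (data.frame sample_id, node, col, row —
#'   col/row 0-based), `empty` (logical per tile).
#' @export
train_second_level <- function(metagene_mat, grid = NULL,
                               schedule = NULL, seed = 42L,
                               init = c("pca_plane", "random")) {
  init <- match.arg(init)
  M <- ncol(metagene_mat)
  if (M < 2L) stopf("need at least 2 samples")
  if (is.null(grid)) {
    side <- ceiling(sqrt(2 * M))
    grid <- som_grid(side)
  }
  if (grid$K <= M)
    stopf("second-level grid (%d tiles) must exceed the sample count (%d)",
          grid$K, M)
  if (is.null(schedule)) schedule <- som_schedule(grid)
  X <- t(metagene_mat)                      # samples x K
  cb <- init_codebook(X, grid, init, seed)
  cb <- with_seed(seed, .kohonen_epochs(X, cb, grid, schedule$phases))
  bmu <- .bmu_index(X, cb)
  positions <- data.frame(sample_id = colnames(metagene_mat), node = bmu,
                          col = grid$col[bmu], row = grid$row[bmu],
                          row.names = NULL)
  occupied <- tabulate(bmu, nbins = grid$K) > 0L
  structure(list(grid = grid, codebook = cb, positions = positions,
                 empty = !occupied,
                 meta = list(seed = as.integer(seed), schedule = schedule, init = init)),
            class = "second_level_som")
}

#' @export
print.second_level_som <- function(x, ...) {
  cat(sprintf("<second_level_som> %d x %d grid, %d samples, %d empty tiles\n",
              x$grid$x, x$grid$y, nrow(x$positions), sum(x$empty)))
  invisible(x)
}

#' Zoom in: re-run the pipeline on a sample subset
#'
#' Trains a new map on a reduced set of samples so the metagene profiles
#' adapt to the subset's narrower bandwidth of expression values and finer
#' structure becomes resolvable. Preprocessing restarts from the log-scale
#' matrix: differential expression is re-centered within the subset,
#' because centering depends on the sample ensemble.
#'
#' @param e_log [expr_matrix()] on the log10 (or linear) scale — the state
#'   *before* centering.
#' @param samples character vector of >= 2 sample ids to keep.
#' @param config pipeline configuration, see [pipeline_config()]; the
#'   subset run uses the same grid, schedule, spot and seed settings.
#' @param output_dir optional directory; when given, outputs are written
#'   under `<output_dir>/` mirroring [run_pipeline()]'s layout.
#' @return the [run_pipeline()] result list for the subset.
#' @export
zoom_in <- function(e_log, samples, config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(e_log, "expr_matrix"))
  if (e_log$scale == "centered")
    stopf("zoom_in needs the uncentered (log10 or linear) matrix")
  samples <- unique(as.character(samples))
  bad <- setdiff(samples, sample_ids(e_log))
  if (length(bad)) stopf("unknown sample id(s): %s", paste(bad, collapse = ", "))
  if (length(samples) < 2L) stopf("zoom-in needs at least 2 samples")
  sub <- expr_matrix(e_log$values[, samples, drop = FALSE], e_log$scale)
  run_pipeline_core(sub, config, output_dir = output_dir)
}
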