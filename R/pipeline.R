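#' Pipeline configuration
#'
#' All knobs of [run_pipeline()] in one validated list; serialized as YAML
#' alongside the results so a run can be reproduced from its output
#' directory alone.
#'
#' @param grid_x,grid_y map dimensions (default 20 x 20 — raise to 60 x 60
#'   for genome-scale input).
#' @param seed master seed; every source of randomness in the run derives
#'   from it.
#' @param scale declared scale of the input matrix.
#' @param normalize quantile-normalize before centering?
#' @param present_fraction_threshold,level_threshold low-expression mask,
#'   see [filter_low_expression()].
#' @param spot_quantile,spot_min_size,spot_connectivity spot segmentation,
#'   see [detect_spots()].
#' @param top_lengths FC/variance top-list lengths.
#' @param fdr_thresholds local-FDR cutoffs offered.
#' @param enrich_top_n ranked list length per spot.
#' @param coarse_x,coarse_y profiling-map granularity.
#' @param second_level train the sample-level map?
#' @param render write PNG rasters (requires a working png device)?
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_x = 20L, grid_y = grid_x, seed = 42L,
                            scale = "log10", normalize = FALSE,
                            present_fraction_threshold = 0,
                            level_threshold = -Inf,
                            spot_quantile = 0.98, spot_min_size = 3L,
                            spot_connectivity = 8L,
                            top_lengths = c(100L, 1000L, 3600L),
                            fdr_thresholds = c(0.005, 0.01, 0.05),
                            enrich_top_n = 20L,
                            coarse_x = 8L, coarse_y = 8L,
                            second_level = TRUE, render = FALSE) {
  cfg <- list(grid_x = as.integer(grid_x), grid_y = as.integer(grid_y),
              seed = as.integer(seed), scale = scale, normalize = normalize,
              present_fraction_threshold = present_fraction_threshold,
              level_threshold = level_threshold,
              spot_quantile = spot_quantile,
              spot_min_size = as.integer(spot_min_size),
              spot_connectivity = as.integer(spot_connectivity),
              top_lengths = as.integer(top_lengths),
              fdr_thresholds = fdr_thresholds,
              enrich_top_n = as.integer(enrich_top_n),
              coarse_x = as.integer(coarse_x), coarse_y = as.integer(coarse_y),
              second_level = isTRUE(second_level), render = isTRUE(render))
  if (cfg$grid_x < 2L || cfg$grid_y < 2L) stopf("grid must be at least 2 x 2")
  if (cfg$spot_quantile <= 0 || cfg$spot_quantile >= 1)
    stopf("`spot_quantile` must be in (0, 1)")
  if (!cfg$spot_connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  if (!cfg$scale %in% c("linear", "log10", "centered")) stopf("unknown scale")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[names(raw) %in% names(formals(pipeline_config))])
}

#' @param config a [pipeline_config()].
#' @rdname pipeline_config_io
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.stage <- function(name, log_con, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  if (!is.null(log_con))
    writeLines(sprintf("[%s] stage %-12s done in %.2fs",
                       format(Sys.time(), "%H:%M:%S"), name,
                       as.numeric(difftime(Sys.time(), t0, units = "secs"))),
               log_con)
  res
}

.write_csv <- function(df, path) utils::write.csv(df, path, row.names = FALSE)

#' Run the full expression-cartography pipeline
#'
#' preprocess -> SOM -> portraits & supporting maps -> spots & entropy ->
#' enrichment -> filtering -> downstream clustering/ICA -> second-level
#' SOM. Every stage is logged with its timing; two runs with identical
#' inputs, config and seed produce identical outputs.
#'
#' @param em input [expr_matrix()] (scale per `config$scale` if read from
#'   file; an in-memory matrix keeps its own scale).
#' @param config a [pipeline_config()].
#' @param annotation optional [sample_annotation()].
#' @param collection optional [gene_set_collection()] for enrichment.
#' @param output_dir optional directory; when given, the stage
#'   subdirectories (`portraits/`, `maps/`, `spots/`, `enrichment/`,
#'   `filtering/`, `downstream/`, `second_level/`), `config.yaml` and
#'   `log.txt` are written there. Without it the run is purely in-memory.
#' @return invisibly, a list with all stage results (`centered`, `som`,
#'   `portraits`, `maps`, `spots`, `spot_expression`, `entropy`,
#'   `enrichment`, `filtering`, `downstream`, `second_level`).
#' @export
run_pipeline_core <- function(em, config = pipeline_config(),
                              annotation = NULL, collection = NULL,
                              output_dir = NULL) {
  stopifnot(inherits(em, "expr_matrix"), inherits(config, "pipeline_config"))
  log_con <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (d in c("portraits", "maps", "spots", "enrichment", "filtering",
                "downstream", "second_level"))
      dir.create(file.path(output_dir, d), showWarnings = FALSE)
    write_pipeline_config(config, file.path(output_dir, "config.yaml"))
    log_con <- file(file.path(output_dir, "log.txt"), "w")
    on.exit(close(log_con))
  }
  grid <- som_grid(config$grid_x, config$grid_y)

  centered <- .stage("preprocess", log_con,
    preprocess(em, normalize = config$normalize,
               present_fraction_threshold = config$present_fraction_threshold,
               level_threshold = config$level_threshold))

  som <- .stage("som", log_con,
    train_som(centered, grid, som_schedule(grid), seed = config$seed))

  portraits <- .stage("portraits", log_con,
    lapply(stats::setNames(nm = sample_ids(centered)), function(s)
      sample_portrait(som, s, "logFC")))

  maps <- .stage("maps", log_con, {
    list(population = population_map(som),
         variance = variance_map(som),
         profiling = profiling_map(som, min(config$coarse_x, grid$x),
                                   min(config$coarse_y, grid$y)))
  })

  spots <- .stage("spots", log_con,
    find_global_spots(som, config$spot_quantile, config$spot_min_size,
                      config$spot_connectivity))
  maps$over_summary <- spots$maps$over
  maps$under_summary <- spots$maps$under
  se <- if (length(spots$over$spots) > 0L) spot_expression(spots$over, som) else NULL
  entropy <- if (!is.null(se) && nrow(se) >= 2L) specificity_entropy(se) else NULL

  enrich <- NULL
  if (!is.null(collection) && length(spots$over$spots) > 0L)
    enrich <- .stage("enrichment", log_con,
      spot_enrichment(spots$over, som$assignment, collection,
                      top_n = config$enrich_top_n))

  filtering <- .stage("filtering", log_con, {
    mg <- metagene_matrix(som)
    mg <- mg[som$assignment$n_k > 0L, , drop = FALSE]  # empty metagenes excluded
    gene_rank <- rank_features(centered$values, "fc")
    mg_rank <- rank_features(mg, "fc")
    lens <- config$top_lengths
    gene_lists <- lapply(lens, function(n)
      suppressWarnings(top_list(gene_rank, min(n, nrow(gene_rank)), "single_gene", "fc")))
    mg_lists <- lapply(lens, function(n)
      suppressWarnings(top_list(mg_rank, min(n, nrow(mg_rank)), "metagene", "fc")))
    names(gene_lists) <- names(mg_lists) <- paste0("FC-", lens)
    fdr_tab <- if (ncol(centered$values) >= 3L) shrinkage_t_fdr(centered) else NULL
    list(gene_rank = gene_rank, metagene_rank = mg_rank,
         gene_lists = gene_lists, metagene_lists = mg_lists, fdr = fdr_tab)
  })

  downstream <- .stage("downstream", log_con, {
    mg <- metagene_matrix(som)
    res <- list(
      sample_tree = hierarchical_cluster(mg, axis = "samples")$samples,
      pcm = pcm(mg, annotation))
    if (ncol(mg) > 2L)
      res$ica <- ica_project(mg, 2L, seed = config$seed)
    res
  })

  second <- NULL
  if (config$second_level)
    second <- .stage("second_level", log_con,
      train_second_level(metagene_matrix(som), seed = config$seed))

  if (!is.null(output_dir))
    .stage("write", log_con,
      .write_outputs(output_dir, config, centered, som, portraits, maps,
                     spots, se, entropy, enrich, filtering, downstream, second))

  invisible(list(centered = centered, som = som, portraits = portraits,
                 maps = maps, spots = spots, spot_expression = se,
                 entropy = entropy, enrichment = enrich,
                 filtering = filtering, downstream = downstream,
                 second_level = second, config = config))
}

.write_outputs <- function(dir, config, centered, som, portraits, maps, spots,
                           se, entropy, enrich, filtering, downstream, second) {
  grid <- som$grid
  # SOM serialization: codebook, assignment (0-based node index), metadata
  cb <- as.data.frame(som$codebook)
  .write_csv(cbind(node_index = seq_len(grid$K) - 1L, cb),
             file.path(dir, "maps", "codebook.csv"))
  bmu <- som$assignment$bmu
  .write_csv(data.frame(gene_id = names(bmu), node_index = unname(bmu) - 1L,
                        node_col = grid$col[bmu], node_row = grid$row[bmu]),
             file.path(dir, "maps", "assignment.csv"))
  yaml::write_yaml(list(grid = list(x = grid$x, y = grid$y),
                        seed = som$meta$seed, init = som$meta$init,
                        quantization_error = as.list(som$meta$quantization_error)),
                   file.path(dir, "maps", "som_metadata.yaml"))
  for (kind in c("population", "variance", "over_summary", "under_summary"))
    .write_csv(data.frame(node_index = seq_len(grid$K) - 1L,
                          value = maps[[kind]]$values,
                          empty = maps[[kind]]$empty),
               file.path(dir, "maps", paste0(kind, ".csv")))
  port_df <- data.frame(node_index = seq_len(grid$K) - 1L,
                        vapply(portraits, `[[`, numeric(grid$K), "values"))
  .write_csv(port_df, file.path(dir, "portraits", "portraits_logFC.csv"))
  sp_rows <- lapply(c(spots$over$spots, spots$under$spots), function(s)
    data.frame(label = s$label, polarity = s$polarity,
               n_nodes = length(s$nodes),
               nodes = paste(s$nodes - 1L, collapse = ";"),
               seed_node = s$seed_node - 1L, peak_value = s$peak_value,
               n_genes = length(s$genes),
               genes = paste(s$genes, collapse = ";")))
  .write_csv(if (length(sp_rows)) do.call(rbind, sp_rows) else
               data.frame(label = character(0)),
             file.path(dir, "spots", "spots.csv"))
  if (!is.null(se))
    .write_csv(cbind(spot = rownames(se), as.data.frame(se)),
               file.path(dir, "spots", "spot_expression.csv"))
  if (!is.null(entropy))
    .write_csv(data.frame(sample = names(entropy), entropy = unname(entropy)),
               file.path(dir, "spots", "entropy.csv"))
  if (!is.null(enrich))
    for (lab in names(enrich))
      .write_csv(enrich[[lab]],
                 file.path(dir, "enrichment", paste0("spot_", lab, ".csv")))
  for (nm in names(filtering$gene_lists)) {
    fs <- filtering$gene_lists[[nm]]
    .write_csv(data.frame(rank = seq_along(fs$ids), id = fs$ids,
                          score = fs$scores, level = fs$level,
                          criterion = fs$criterion),
               file.path(dir, "filtering", paste0("genes_", nm, ".csv")))
  }
  for (nm in names(filtering$metagene_lists)) {
    fs <- filtering$metagene_lists[[nm]]
    .write_csv(data.frame(rank = seq_along(fs$ids), id = fs$ids,
                          score = fs$scores, level = fs$level,
                          criterion = fs$criterion),
               file.path(dir, "filtering", paste0("metagenes_", nm, ".csv")))
  }
  if (!is.null(filtering$fdr))
    .write_csv(filtering$fdr, file.path(dir, "filtering", "gene_fdr.csv"))
  .write_csv(cbind(sample = colnames(downstream$pcm$cor),
                   as.data.frame(downstream$pcm$cor)),
             file.path(dir, "downstream", "pcm.csv"))
  if (!is.null(downstream$ica))
    .write_csv(cbind(sample = rownames(downstream$ica),
                     as.data.frame(downstream$ica)),
               file.path(dir, "downstream", "ica_coordinates.csv"))
  if (requireNamespace("ape", quietly = TRUE))
    write_newick(downstream$sample_tree,
                 file.path(dir, "downstream", "sample_tree.nwk"))
  if (!is.null(second))
    .write_csv(second$positions, file.path(dir, "second_level", "positions.csv"))
  if (config$render) .render_pngs(dir, som, portraits, maps)
  invisible(dir)
}

.render_pngs <- function(dir, som, portraits, maps) {
  grid <- som$grid
  px <- max(4L, 240L %/% grid$x)
  draw <- function(path, expr) {
    ok <- tryCatch({
      grDevices::png(path, width = grid$x * px, height = grid$y * px)
      on.exit(grDevices::dev.off())
      expr
      TRUE
    }, error = function(e) FALSE)
    if (!ok) warnf("could not render '%s' (no png device?)", path)
  }
  for (s in names(portraits))
    draw(file.path(dir, "portraits", paste0(s, ".png")),
         plot_som_map(portraits[[s]], grid))
  for (kind in c("population", "variance", "over_summary", "under_summary"))
    draw(file.path(dir, "maps", paste0(kind, ".png")),
         plot_som_map(maps[[kind]], grid))
}

#' Run the pipeline from files on disk
#'
#' File-level front end of [run_pipeline_core()]: reads the expression
#' matrix (TSV/GCT), optional annotation TSV and optional GMT collection
#' named in `paths`, then delegates.
#'
#' @param matrix_path expression matrix file.
#' @param config a [pipeline_config()] (its `scale` declares the matrix
#'   scale).
#' @param annotation_path,gmt_path optional companion files.
#' @param output_dir where to write the result tree (required here).
#' @return the [run_pipeline_core()] result list, invisibly.
#' @export
run_pipeline <- function(matrix_path, config = pipeline_config(),
                         annotation_path = NULL, gmt_path = NULL,
                         output_dir) {
  em <- read_expression_matrix(matrix_path, config$scale)
  ann <- if (!is.null(annotation_path))
    read_sample_annotation(annotation_path, sample_ids(em)) else NULL
  gsc <- if (!is.null(gmt_path)) read_gmt(gmt_path) else NULL
  run_pipeline_core(em, config, annotation = ann, collection = gsc,
                    output_dir = output_dir)
}
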