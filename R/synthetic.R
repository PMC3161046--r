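#' Generate a planted-module expression matrix
#'
#' Emulates tissue-specific co-expression modules: background cells are
#' drawn from Normal(b, sigma^2) on the log10 scale; the genes of module j
#' get an additive effect +delta in that module's active samples (additive
#' on the log scale, i.e. in logged-fold-change units), and optionally
#' -delta/2 in all other samples to mimic the anti-correlation of
#' tissue-specific genes across the remaining categories. Samples are
#' annotated by their active module.
#'
#' The defaults (2,000 genes x 24 samples, 4 disjoint modules of 100 genes
#' active in 6 samples each, delta = 1, sigma = 0.2) train a 20 x 20 map in
#' seconds and are the fixture every stage of the package is tested on.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param n_modules number of planted modules.
#' @param genes_per_module module size; `n_modules * genes_per_module`
#'   must not exceed `n_genes` (modules are disjoint).
#' @param samples_per_module size of each module's active sample block
#'   (blocks are disjoint and consecutive).
#' @param delta effect size in log10 units (> 0).
#' @param sigma noise SD (>= 0).
#' @param background_mean baseline b of the logged expression.
#' @param anti also plant -delta/2 outside the active block?
#' @param seed integer; generation is a pure function of parameters + seed.
#' @return list with `expression` ([expr_matrix()], scale log10), `truth`
#'   (class `synthetic_truth`: `module` integer per gene with 0 =
#'   background, `module_genes`, `module_samples`, `delta`, `sigma`,
#'   `seed`), and `annotation` ([sample_annotation()]).
#' @export
generate_planted_modules <- function(n_genes = 2000L, n_samples = 24L,
                                     n_modules = 4L, genes_per_module = 100L,
                                     samples_per_module = n_samples %/% n_modules,
                                     delta = 1, sigma = 0.2,
                                     background_mean = 2, anti = FALSE,
                                     seed = 42L) {
  if (n_modules * genes_per_module > n_genes)
    stopf("modules would overlap: %d x %d > %d genes",
          n_modules, genes_per_module, n_genes)
  if (n_modules * samples_per_module > n_samples)
    stopf("module sample blocks would overlap: %d x %d > %d samples",
          n_modules, samples_per_module, n_samples)
  if (delta <= 0) stopf("`delta` must be > 0")
  if (sigma < 0) stopf("`sigma` must be >= 0")
  gene_names <- sprintf("g%04d", seq_len(n_genes))
  sample_names <- sprintf("s%02d", seq_len(n_samples))
  vals <- with_seed(seed, matrix(stats::rnorm(n_genes * n_samples,
                                              background_mean, sigma),
                                 n_genes, n_samples,
                                 dimnames = list(gene_names, sample_names)))
  module <- integer(n_genes)
  module_genes <- module_samples <- vector("list", n_modules)
  for (j in seq_len(n_modules)) {
    gi <- ((j - 1L) * genes_per_module + 1L):(j * genes_per_module)
    si <- ((j - 1L) * samples_per_module + 1L):(j * samples_per_module)
    module[gi] <- j
    module_genes[[j]] <- gene_names[gi]
    module_samples[[j]] <- sample_names[si]
    vals[gi, si] <- vals[gi, si] + delta
    if (anti) vals[gi, -si] <- vals[gi, -si] - delta / 2
  }
  cat_ <- rep("unassigned", n_samples)
  for (j in seq_len(n_modules))
    cat_[match(module_samples[[j]], sample_names)] <- sprintf("module_%d", j)
  truth <- structure(list(module = stats::setNames(module, gene_names),
                          module_genes = module_genes,
                          module_samples = module_samples,
                          delta = delta, sigma = sigma, seed = as.integer(seed)),
                     class = "synthetic_truth")
  list(expression = expr_matrix(vals, "log10"), truth = truth,
       annotation = sample_annotation(sample_names, cat_))
}

#' Build a matched gene-set collection from planted truth
#'
#' One set per planted module (its exact genes) plus `n_decoy_sets` decoys
#' sampled uniformly from all genes — so enrichment recovery and null
#' calibration can be tested against known truth. The result is
#' GMT-writable via [write_gmt()].
#'
#' @param truth a `synthetic_truth` from [generate_planted_modules()].
#' @param n_decoy_sets number of decoy sets.
#' @param decoy_size genes per decoy set (<= total gene count).
#' @param seed integer seed for the decoy draws.
#' @return a [gene_set_collection()] (categories: `custom`).
#' @export
generate_gene_sets_from_truth <- function(truth, n_decoy_sets = 20L,
                                          decoy_size = 50L, seed = 42L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  all_genes <- names(truth$module)
  if (decoy_size > length(all_genes))
    stopf("`decoy_size` (%d) exceeds the gene count (%d)",
          decoy_size, length(all_genes))
  sets <- stats::setNames(truth$module_genes,
                          sprintf("module_set_%d", seq_along(truth$module_genes)))
  if (n_decoy_sets > 0L) {
    decoys <- with_seed(seed, lapply(seq_len(n_decoy_sets), function(i)
      sample(all_genes, decoy_size)))
    names(decoys) <- sprintf("decoy_set_%02d", seq_len(n_decoy_sets))
    sets <- c(sets, decoys)
  }
  gene_set_collection(sets)
}
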