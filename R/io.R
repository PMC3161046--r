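#' Expression matrix container
#'
#' A genes x samples matrix of expression values together with its scale
#' state. Three scales are tracked through the pipeline: `"linear"` (raw
#' intensities E), `"log10"` (e = log10 E) and `"centered"` (differential
#' expression, each gene row centered on its mean across samples).
#'
#' @param values numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids).
#' @param scale one of `"linear"`, `"log10"`, `"centered"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale = c("linear", "log10", "centered")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (nrow(values) < 1L) stopf("need at least one gene")
  if (ncol(values) < 2L) stopf("need at least two samples")
  if (any(!is.finite(values)))
    stopf("non-finite values in expression matrix")
  if (scale == "centered") {
    s <- rowSums(values)
    if (any(abs(s) > 1e-9 * ncol(values)))
      stopf("scale 'centered' requires zero-mean gene rows")
  }
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(em) rownames(em$values)
sample_ids <- function(em) colnames(em$values)

#' Read a genes x samples expression matrix
#'
#' Reads plain TSV (header row of sample ids, first column gene ids) or
#' GCT 1.2 (detected by its `#1.2` preamble; the two preamble lines and the
#' `Description` column are skipped). Duplicate ids, missing cells and
#' non-numeric cells are rejected; missing values are never imputed.
#'
#' @param path path to a TSV or GCT file.
#' @param scale_declared the scale the values are on (the file format does
#'   not record it); see [expr_matrix()].
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   scale_declared = c("linear", "log10", "centered")) {
  scale_declared <- match.arg(scale_declared)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("'%s': expected a header line and at least one data row", path)
  id_cols <- 1L
  if (startsWith(lines[[1L]], "#1.2")) {       # GCT 1.2 preamble
    if (length(lines) < 4L) stopf("'%s': truncated GCT file", path)
    lines <- lines[-(1:2)]
    id_cols <- 2L
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < id_cols + 1L)
    stopf("'%s': malformed header (need gene-id column plus >= 1 sample)", path)
  samples <- trimws(header[-seq_len(id_cols)])
  n_fields <- length(header)
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad))
    stopf("'%s': row %d has %d fields, header declares %d",
          path, bad[[1L]], lengths(parts)[bad[[1L]]], n_fields)
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  if (anyDuplicated(ids))
    stopf("'%s': duplicate gene ids: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- vapply(parts, function(p) p[-seq_len(id_cols)], character(length(samples)))
  raw <- if (is.null(dim(raw))) matrix(raw, nrow = 1L) else t(raw)
  suppressWarnings(num <- array(as.numeric(raw), dim = dim(raw)))
  if (any(is.na(num))) {
    ij <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stopf("'%s': non-numeric or missing cell '%s' at data row %d, sample '%s'",
          path, raw[ij[1L], ij[2L]], ij[1L], samples[ij[2L]])
  }
  dimnames(num) <- list(ids, samples)
  expr_matrix(num, scale_declared)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; full double precision is kept so
#' the round trip is lossless to ~1e-15 relative error.
#'
#' @param em an [expr_matrix()].
#' @param path output path.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", sample_ids(em)), collapse = "\t"), con)
  body <- apply(format(em$values, digits = 17, trim = TRUE, scientific = NA),
                1L, paste, collapse = "\t")
  writeLines(paste(gene_ids(em), body, sep = "\t"), con)
  invisible(path)
}

#' Gene-set collection
#'
#' @param sets named list of character vectors (member gene ids).
#' @param category character vector parallel to `sets`: one of
#'   `"biological_process"`, `"molecular_function"`, `"cellular_component"`,
#'   `"custom"`.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, category = rep("custom", length(sets))) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("gene set names must be unique and non-empty")
  if (any(lengths(sets) == 0L)) stopf("empty gene sets are not allowed")
  ok <- c("biological_process", "molecular_function", "cellular_component", "custom")
  if (!all(category %in% ok)) stopf("unknown gene-set category")
  sets <- lapply(sets, function(s) unique(trimws(s)))
  structure(list(sets = sets, category = stats::setNames(category, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d..%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

.gmt_category <- function(desc) {
  d <- tolower(trimws(desc))
  if (d %in% c("biological_process", "bp", "go:bp", "gobp")) return("biological_process")
  if (d %in% c("molecular_function", "mf", "go:mf", "gomf")) return("molecular_function")
  if (d %in% c("cellular_component", "cc", "go:cc", "gocc")) return("cellular_component")
  "custom"
}

#' Read a GMT gene-set file
#'
#' Standard GSEA interchange format: one set per line,
#' `name TAB description TAB member TAB member ...`. Duplicate members within
#' a line are stored once; lines whose member list is empty are dropped with
#' a warning. The description field is mapped to a GO-style category
#' (`biological_process` / `molecular_function` / `cellular_component`,
#' including the common `BP`/`MF`/`CC` abbreviations); anything else becomes
#' `custom`.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stopf("'%s': line %d has fewer than 3 fields", path, short[[1L]])
  nm <- vapply(parts, `[[`, "", 1L)
  cat_ <- vapply(parts, function(p) .gmt_category(p[[2L]]), "")
  members <- lapply(parts, function(p) {
    m <- unique(trimws(p[-(1:2)]))
    m[nzchar(m)]
  })
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warnf("'%s': dropping %d set(s) with no members", path, sum(empty))
    nm <- nm[!empty]; cat_ <- cat_[!empty]; members <- members[!empty]
  }
  gene_set_collection(stats::setNames(members, nm), cat_)
}

#' Write a gene-set collection as GMT
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, unname(gsc$category[nm]), gsc$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Sample annotation
#'
#' Maps every sample id to a category label; samples without an entry get
#' `"unassigned"`. A display color is attached per category.
#'
#' @param sample_id character vector of sample ids.
#' @param category character vector of category labels, recycled checkwise.
#' @return an object of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, category) {
  if (length(sample_id) != length(category))
    stopf("sample_id and category must have equal length")
  if (anyDuplicated(sample_id)) stopf("duplicate sample ids in annotation")
  category <- as.character(category)
  if (any(!nzchar(category))) stopf("empty category labels are not allowed")
  cats <- unique(category)
  cols <- grDevices::hcl.colors(max(length(cats), 2L), "Dark 3")[seq_along(cats)]
  structure(list(sample_id = as.character(sample_id),
                 category = category,
                 categories = cats,
                 colors = stats::setNames(cols, cats)),
            class = "sample_annotation")
}

#' @export
print.sample_annotation <- function(x, ...) {
  cat(sprintf("<sample_annotation> %d samples, %d categories\n",
              length(x$sample_id), length(x$categories)))
  invisible(x)
}

#' Look up category labels for a set of samples
#'
#' @param ann a [sample_annotation()] (or `NULL`: all `"unassigned"`).
#' @param ids sample ids to look up.
#' @return character vector of categories, `"unassigned"` where unknown.
#' @export
annotation_categories <- function(ann, ids) {
  if (is.null(ann)) return(rep("unassigned", length(ids)))
  idx <- match(ids, ann$sample_id)
  out <- ann$category[idx]
  out[is.na(idx)] <- "unassigned"
  out
}

#' Read a two-column sample annotation TSV
#'
#' Columns are `sample_id TAB category`; an optional header line
#' (`sample_id<TAB>category`) is skipped. An empty file yields every sample
#' `"unassigned"`. Entries for samples absent from `sample_ids` (when given)
#' are dropped with a warning.
#'
#' @param path path to the TSV.
#' @param sample_ids optional character vector of the matrix's sample ids;
#'   used to complete and validate the annotation.
#' @return a [sample_annotation()].
#' @export
read_sample_annotation <- function(path, sample_ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^sample_id\t", lines[[1L]], ignore.case = TRUE))
    lines <- lines[-1L]
  if (!length(lines)) {
    if (is.null(sample_ids)) stopf("'%s' is empty and no sample_ids were supplied", path)
    return(sample_annotation(sample_ids, rep("unassigned", length(sample_ids))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stopf("'%s': line %d has fewer than 2 columns", path, bad[[1L]])
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  cat_ <- trimws(vapply(parts, `[[`, "", 2L))
  if (anyDuplicated(ids))
    stopf("'%s': duplicate sample_id rows: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(sample_ids)) {
    unknown <- setdiff(ids, sample_ids)
    if (length(unknown)) {
      warnf("'%s': ignoring %d annotation row(s) for unknown sample(s): %s",
            path, length(unknown), paste(unknown, collapse = ", "))
      keep <- ids %in% sample_ids
      ids <- ids[keep]; cat_ <- cat_[keep]
    }
    missing <- setdiff(sample_ids, ids)
    ids <- c(ids, missing)
    cat_ <- c(cat_, rep("unassigned", length(missing)))
    ord <- match(sample_ids, ids)
    ids <- ids[ord]; cat_ <- cat_[ord]
  }
  sample_annotation(ids, cat_)
}

#' Write a sample annotation as two-column TSV
#' @param ann a [sample_annotation()].
#' @param path output path.
#' @export
write_sample_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "sample_annotation"))
  writeLines(c("sample_id\tcategory",
               paste(ann$sample_id, ann$category, sep = "\t")), path)
  invisible(path)
}
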