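#' Log-transform a linear-scale expression matrix
#'
#' e = log10(max(E, floor)). The floor guards against zeros and negative
#' background-corrected intensities; the default (1e-10) is a no-op for
#' typical summarized microarray or count-derived data.
#'
#' @param em an [expr_matrix()] on the linear scale.
#' @param floor positive value below which intensities are clipped before
#'   taking logs.
#' @return an [expr_matrix()] on the log10 scale.
#' @export
log_transform <- function(em, floor = 1e-10) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "linear") stopf("log_transform expects scale 'linear', got '%s'", em$scale)
  if (!is.numeric(floor) || floor <= 0) stopf("`floor` must be > 0")
  expr_matrix(log10(pmax(em$values, floor)), "log10")
}

#' Center gene profiles to differential expression
#'
#' Transforms logged expression into differential expression relative to the
#' gene's mean over the sample series:
#' \deqn{\Delta e_{g,m} = e_{g,m} - \langle e_{g}\rangle_m}
#' so values are in units of the logged fold change relative to the mean
#' state. Every row of the result sums to zero.
#'
#' @param em an [expr_matrix()] on the log10 scale.
#' @return an [expr_matrix()] with scale `"centered"`.
#' @export
center_profiles <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (!em$scale %in% c("log10", "centered"))
    stopf("center_profiles expects scale 'log10', got '%s'", em$scale)
  if (ncol(em$values) < 2L) stopf("centering needs at least 2 samples")
  expr_matrix(em$values - rowMeans(em$values), "centered")
}

#' Mask genes with low expression
#'
#' Detection-call surrogate: a gene is kept when its logged expression
#' exceeds `level_threshold` in at least `present_fraction_threshold` of the
#' samples. With the default threshold 0 every gene is kept.
#'
#' @param em an [expr_matrix()] on the log10 scale.
#' @param present_fraction_threshold fraction of samples, in `[0, 1]`.
#' @param level_threshold log10 expression level a "present" call must exceed.
#' @return logical vector of length N (TRUE = keep), named by gene id.
#' @export
filter_low_expression <- function(em, present_fraction_threshold = 0,
                                  level_threshold = -Inf) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "log10") stopf("filter_low_expression expects scale 'log10'")
  f <- present_fraction_threshold
  if (!is.numeric(f) || f < 0 || f > 1)
    stopf("`present_fraction_threshold` must be in [0, 1]")
  if (f == 0) return(stats::setNames(rep(TRUE, nrow(em$values)), gene_ids(em)))
  frac_present <- rowMeans(em$values > level_threshold)
  stats::setNames(frac_present >= f, gene_ids(em))
}

#' Quantile-normalize samples
#'
#' Forces every sample column onto the common reference distribution given
#' by the mean of the column-sorted values; within-column rank order is
#' preserved, ties receive the average of the reference values at the tied
#' ranks.
#'
#' @param em an [expr_matrix()] on the log10 scale.
#' @return an [expr_matrix()] on the log10 scale with identical per-sample
#'   distributions.
#' @export
normalize_quantiles <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "log10") stopf("normalize_quantiles expects scale 'log10'")
  x <- em$values
  n <- nrow(x)
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_len(n), ref, xout = r)$y
  })
  dimnames(out) <- dimnames(x)
  expr_matrix(out, "log10")
}

#' One-call preprocessing to the differential-expression scale
#'
#' Convenience wrapper: optional log transform (if the input is linear),
#' optional quantile normalization, optional low-expression masking, then
#' mean-centering per gene. Returns the centered matrix with a
#' `preprocess_report` attribute recording what was done.
#'
#' @param em an [expr_matrix()] on any scale.
#' @param normalize quantile-normalize samples first?
#' @param present_fraction_threshold,level_threshold see
#'   [filter_low_expression()].
#' @param floor see [log_transform()].
#' @return a centered [expr_matrix()]; `attr(, "report")` holds the
#'   bookkeeping (genes in/kept, normalization flag, per-sample medians
#'   before/after).
#' @export
preprocess <- function(em, normalize = FALSE,
                       present_fraction_threshold = 0, level_threshold = -Inf,
                       floor = 1e-10) {
  stopifnot(inherits(em, "expr_matrix"))
  n_in <- nrow(em$values)
  med_before <- apply(em$values, 2L, stats::median)
  if (em$scale == "linear") em <- log_transform(em, floor)
  if (em$scale == "log10") {
    if (normalize) em <- normalize_quantiles(em)
    keep <- filter_low_expression(em, present_fraction_threshold, level_threshold)
    if (!all(keep)) {
      if (sum(keep) < 1L) stopf("low-expression filter removed every gene")
      em <- expr_matrix(em$values[keep, , drop = FALSE], "log10")
    }
    em <- center_profiles(em)
  }
  report <- list(n_genes_in = n_in, n_genes_kept = nrow(em$values),
                 normalization_applied = isTRUE(normalize), floor_value = floor,
                 median_before = med_before,
                 median_after = apply(em$values, 2L, stats::median))
  attr(em, "report") <- report
  em
}
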