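#' Construct a raw count matrix
#'
#' Light container for a genes x samples matrix of raw RNA-seq counts with
#' per-sample library sizes. Library sizes default to column sums and are
#' deliberately carried along unchanged when genes are filtered, so that
#' CPM values keep referring to the original sequencing depth.
#'
#' @param values Non-negative numeric matrix, genes in rows, samples in
#'   columns; must carry unique rownames (gene ids) and colnames (sample
#'   ids).
#' @param libsize Optional per-sample library sizes; defaults to
#'   `colSums(values)`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, libsize = NULL) {
  if (!is.matrix(values)) stopf("values must be a matrix")
  if (any(values < 0) || any(!is.finite(values))) {
    stopf("counts must be finite and non-negative")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stopf("gene ids (rownames) must be present and unique")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stopf("sample ids (colnames) must be present and unique")
  }
  libsize <- libsize %||% colSums(values)
  if (length(libsize) != ncol(values)) {
    stopf("libsize must have one entry per sample")
  }
  if (any(libsize <= 0)) stopf("every sample must have library size > 0")
  names(libsize) <- colnames(values)
  structure(
    list(values = values, gene_ids = rownames(values),
         sample_ids = colnames(values), libsize = libsize),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (median libsize %.0f)\n",
              nrow(x$values), ncol(x$values), stats::median(x$libsize)))
  invisible(x)
}

#' Counts-per-million
#'
#' @param counts A [count_matrix()].
#' @return Matrix of CPM values on the stored library sizes.
#' @export
cpm <- function(counts) {
  sweep(counts$values, 2, counts$libsize, "/") * 1e6
}

#' Remove lowly expressed genes
#'
#' Keeps gene g when its CPM is at least `min_cpm` in at least
#' `ceiling(min_fraction * n_samples)` samples. Library sizes are the ones
#' stored on the input and are not recomputed afterwards, so downstream
#' log-CPM values are unaffected by the filtering itself.
#'
#' @param counts A [count_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_fraction Minimum fraction of samples that must pass
#'   (default 0.2).
#' @return A filtered [count_matrix()] with the original library sizes.
#' @export
expression_filter <- function(counts, min_cpm = 1.0, min_fraction = 0.2) {
  stopifnot(inherits(counts, "count_matrix"))
  n <- ncol(counts$values)
  need <- ceiling(min_fraction * n)
  keep <- rowSums(cpm(counts) >= min_cpm) >= need
  if (!any(keep)) {
    stopf("expression filter removed all genes (min_cpm = %g in >= %d of %d samples)",
          min_cpm, need, n)
  }
  count_matrix(counts$values[keep, , drop = FALSE], libsize = counts$libsize)
}

#' Variance-stabilizing log-CPM normalization with precision weights
#'
#' Computes `log2((count + 0.5) / (libsize + 1) * 1e6)` per observation,
#' optionally quantile-normalizes the columns (each column's sorted values
#' replaced by the across-column mean of the order statistics), then fits a
#' lowess mean-variance trend of `sqrt(residual SD)` against average log2
#' count (intercept-only residuals) and converts the trend into
#' per-observation inverse-variance weights
#' `predicted_sqrt_sd(fitted log2 count)^(-4)`. Outside the fitted range the
#' trend is extended flat so extreme genes get bounded weights.
#'
#' @param counts An expression-filtered [count_matrix()].
#' @param quantile Quantile-normalize columns before trend fitting
#'   (default `FALSE`).
#' @param span Lowess span for the mean-variance trend (default 0.5).
#' @param iterations Lowess robustness iterations (default 2).
#' @return An object of class `normalized_matrix` with elements `logexpr`
#'   (genes x samples), `weights` (same shape, strictly positive),
#'   `kept_genes`, `trend` (lookup table `x`, `y`) and `libsize`.
#' @export
normalize_counts <- function(counts, quantile = FALSE, span = 0.5,
                             iterations = 2L) {
  stopifnot(inherits(counts, "count_matrix"))
  n <- ncol(counts$values)
  if (n < 2L) stopf("normalization needs at least 2 samples (no residual df)")
  lib <- counts$libsize
  E <- log2(sweep(counts$values + 0.5, 2, lib + 1, "/") * 1e6)
  dimnames(E) <- dimnames(counts$values)
  if (isTRUE(quantile)) E <- quantile_normalize(E)

  gene_mean <- rowMeans(E)
  gene_sd <- sqrt(rowSums((E - gene_mean)^2) / (n - 1))
  ## trend is fitted on the average log2-count scale (log-CPM shifted back
  ## by the mean log library size), as in standard voom-type weighting
  x_gene <- gene_mean + mean(log2(lib + 1)) - log2(1e6)
  lo <- stats::lowess(x_gene, sqrt(gene_sd), f = span, iter = iterations)
  trend <- list(x = lo$x, y = pmax(lo$y, 1e-6))

  fitted_logcount <- outer(gene_mean, log2((lib + 1) / 1e6), "+")
  pred <- stats::approx(trend$x, trend$y, xout = as.vector(fitted_logcount),
                        rule = 2, ties = mean)$y
  W <- matrix(pred^(-4), nrow = nrow(E), dimnames = dimnames(E))
  if (any(!is.finite(W)) || any(W <= 0)) stopf("non-finite or non-positive weights")

  structure(
    list(logexpr = E, weights = W, kept_genes = rownames(E),
         trend = trend, libsize = lib),
    class = "normalized_matrix"
  )
}

#' @export
dim.normalized_matrix <- function(x) dim(x$logexpr)

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples\n",
              nrow(x$logexpr), ncol(x$logexpr)))
  invisible(x)
}

## Every column's sorted values are replaced by the across-column mean of
## the order statistics; all columns end up with the same multiset.
quantile_normalize <- function(E) {
  ranks <- apply(E, 2, function(col) sort.list(col, method = "radix"))
  sorted <- apply(E, 2, sort, method = "radix")
  target <- rowMeans(sorted)
  out <- E
  for (j in seq_len(ncol(E))) out[ranks[, j], j] <- target
  out
}

#' Keep the most variable genes by median absolute deviation
#'
#' Per-gene variability is the raw (unscaled) median absolute deviation of
#' the normalized log-expression across samples. The
#' `ceiling(keep_fraction * n_genes)` genes of highest MAD are retained;
#' exact MAD ties at the cut are broken by lexicographic gene id so the
#' result is deterministic.
#'
#' @param norm A [normalize_counts()] result.
#' @param keep_fraction Fraction of genes to keep, in (0, 1]
#'   (default 0.55).
#' @return A `normalized_matrix` restricted to the retained genes.
#' @export
mad_filter <- function(norm, keep_fraction = 0.55) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (!(keep_fraction > 0 && keep_fraction <= 1)) {
    stopf("keep_fraction must be in (0, 1]")
  }
  E <- norm$logexpr
  med <- apply(E, 1, stats::median)
  mad_g <- apply(abs(E - med), 1, stats::median)
  n_keep <- ceiling(keep_fraction * nrow(E))
  ord <- order(-mad_g, rownames(E), method = "radix")
  keep <- sort(ord[seq_len(n_keep)])
  structure(
    list(logexpr = E[keep, , drop = FALSE],
         weights = norm$weights[keep, , drop = FALSE],
         kept_genes = rownames(E)[keep],
         trend = norm$trend, libsize = norm$libsize),
    class = "normalized_matrix"
  )
}
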