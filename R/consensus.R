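#' Resampled consensus clustering of samples
#'
#' For each of `n_resamples` perturbed datasets, a random subset of
#' `floor(item_fraction * n)` samples is drawn without replacement and
#' clustered by average-linkage hierarchical clustering on the distance
#' `1 - Pearson(sample, sample)` over the retained genes; the tree is cut
#' at every k in `k_range`. The consensus matrix M_k records, per sample
#' pair, the fraction of resamples in which the pair co-clustered among
#' those in which both were drawn. Pairs never co-drawn get consensus 0 and
#' are flagged via the co-sampling count matrix `I`.
#'
#' @param norm A [normalize_counts()] / [mad_filter()] result.
#' @param k_range Integer vector of cluster numbers (default 2:8).
#' @param n_resamples Number of resamples (default 1000).
#' @param item_fraction Fraction of samples drawn per resample
#'   (default 0.8).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Object of class `consensus_result` with per-k consensus
#'   matrices `M`, the co-sampling count matrix `I`, and the call
#'   parameters. CDF areas, the selected k and final labels are added by
#'   [discover_subtypes()].
#' @export
consensus_cluster <- function(norm, k_range = 2:8, n_resamples = 1000L,
                              item_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(norm, "normalized_matrix"))
  E <- norm$logexpr
  n <- ncol(E)
  k_range <- sort(unique(as.integer(k_range)))
  if (n < max(k_range) + 1L) {
    stopf("need at least max(k_range) + 1 = %d samples, got %d",
          max(k_range) + 1L, n)
  }
  n_draw <- floor(item_fraction * n)
  if (n_draw < max(k_range)) stopf("item_fraction too small for max(k_range)")
  csd <- apply(E, 2, stats::sd)
  if (any(csd == 0)) {
    stopf("sample(s) with constant expression, correlation undefined: %s",
          paste(colnames(E)[csd == 0], collapse = ", "))
  }
  ## 1 - Pearson between samples is pairwise, so it can be computed once
  ## and subset per resample
  D <- 1 - stats::cor(E)

  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  I <- matrix(0, n, n, dimnames = list(colnames(E), colnames(E)))
  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, n_draw))
      hc <- stats::hclust(stats::as.dist(D[idx, idx]), method = "average")
      cl_all <- stats::cutree(hc, k = k_range)
      if (is.null(dim(cl_all))) cl_all <- matrix(cl_all, ncol = 1L)
      I[idx, idx] <- I[idx, idx] + 1
      for (j in seq_along(k_range)) {
        cl <- cl_all[, j]
        conn[[j]][idx, idx] <- conn[[j]][idx, idx] +
          (outer(cl, cl, "==") * 1)
      }
    }
  })
  M <- lapply(conn, function(cm) {
    out <- ifelse(I > 0, cm / pmax(I, 1), 0)
    dimnames(out) <- dimnames(I)
    out
  })
  structure(
    list(k_range = k_range, M = M, I = I, n_resamples = n_resamples,
         item_fraction = item_fraction, seed = seed,
         never_cosampled = sum(I[upper.tri(I)] == 0)),
    class = "consensus_result"
  )
}

#' Area under the empirical CDF of consensus values
#'
#' Integrates the empirical CDF of the off-diagonal upper-triangle entries
#' of a consensus matrix over \[0, 1\]. A perfectly stable clustering
#' (entries all 0 or 1) maximizes the area for the true k; the area curve
#' A(k) plateaus past the true cluster number.
#'
#' @param M A consensus matrix.
#' @return A single number in \[0, 1\].
#' @export
cdf_area <- function(M) {
  x <- M[upper.tri(M)]
  knots <- sort(unique(pmin(pmax(x, 0), 1)))
  cdf <- stats::ecdf(x)
  upper <- c(knots[-1L], 1)
  sum((upper - knots) * cdf(knots))
}

#' Elbow selection of the number of clusters
#'
#' With `A(1) := 0` and marginal gain `m(k) = A(k) - A(k-1)`, selects the
#' interior k (excluding the endpoints of the k range) where the marginal
#' gain collapses: the argmax of the fold drop `m(k) / m(k+1)`; ties
#' resolve to the smallest k. Below the true cluster number the gains decay
#' smoothly (each split still separates real structure), while at the true
#' k the next gain falls by an order of magnitude, so the fold drop -- not
#' the absolute difference, which is dominated by the smooth decay -- marks
#' the elbow. The endpoints are not candidates: the smallest k has no
#' within-range gain reference and the largest no follow-up gain.
#'
#' @param A Named numeric vector of CDF areas over a contiguous k range of
#'   length >= 3 (names are the k values).
#' @return The selected k (integer).
#' @export
select_k_elbow <- function(A) {
  ks <- as.integer(names(A))
  if (length(ks) < 3L) stopf("k range must have length >= 3")
  if (any(diff(ks) != 1L)) stopf("k range must be contiguous")
  gain <- function(k) {
    prev <- if (k - 1L == 1L && !((k - 1L) %in% ks)) 0 else
      unname(A[as.character(k - 1L)])
    unname(A[as.character(k)]) - prev
  }
  candidates <- ks[ks > min(ks) & ks < max(ks)]
  eps <- 1e-12  # guards flat/zero gains without changing real ratios
  drops <- vapply(candidates, function(k) {
    (max(gain(k), 0) + eps) / (max(gain(k + 1L), 0) + eps)
  }, numeric(1))
  drops <- signif(drops, 10)  # make float near-ties exact ties
  candidates[which.max(drops)]  # which.max takes the first (smallest k) on ties
}

#' Proportion of ambiguous clustering (alternative k selector)
#'
#' Fraction of off-diagonal consensus entries in the ambiguous band
#' `(lower, upper)`; the k minimizing PAC is selected.
#'
#' @param M_list Named list of consensus matrices (names are k values).
#' @param lower,upper Ambiguity band (defaults 0.1 and 0.9).
#' @return The k with minimal PAC (ties: smallest k).
#' @export
select_k_pac <- function(M_list, lower = 0.1, upper = 0.9) {
  pac <- vapply(M_list, function(M) {
    x <- M[upper.tri(M)]
    mean(x > lower & x < upper)
  }, numeric(1))
  as.integer(names(M_list))[which.min(pac)]
}

#' Final cluster labels from a consensus matrix
#'
#' Average-linkage hierarchical clustering on `1 - M`, cut at k. Cluster
#' indices are renumbered 1..k by decreasing cluster size, ties broken by
#' the smallest member sample id, so labels do not depend on internal
#' ordering.
#'
#' @param M Consensus matrix at the selected k.
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels (1..k).
#' @export
final_labels <- function(M, k) {
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  cl <- stats::cutree(hc, k = k)
  names(cl) <- rownames(M)
  sizes <- table(cl)
  first_member <- vapply(names(sizes), function(g) {
    min(names(cl)[cl == as.integer(g)])
  }, character(1))
  new_order <- order(-as.integer(sizes), first_member, method = "radix")
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[new_order]] <- seq_along(sizes)
  out <- relabel[cl]
  names(out) <- names(cl)
  out
}

#' Consensus clustering with k selection and final labels
#'
#' Runs [consensus_cluster()], computes the CDF-area curve, selects k with
#' the elbow rule (or PAC) and derives final labels from the consensus
#' matrix at the selected k.
#'
#' @inheritParams consensus_cluster
#' @param selector `"elbow"` (default) or `"pac"`.
#' @return A `consensus_result` augmented with `A` (named CDF areas),
#'   `k_star` and `labels`.
#' @export
discover_subtypes <- function(norm, k_range = 2:8, n_resamples = 1000L,
                              item_fraction = 0.8, seed = 1L,
                              selector = c("elbow", "pac")) {
  selector <- match.arg(selector)
  res <- consensus_cluster(norm, k_range = k_range, n_resamples = n_resamples,
                           item_fraction = item_fraction, seed = seed)
  res$A <- vapply(res$M, cdf_area, numeric(1))
  res$k_star <- if (selector == "elbow") {
    select_k_elbow(res$A)
  } else {
    select_k_pac(res$M)
  }
  res$labels <- final_labels(res$M[[as.character(res$k_star)]], res$k_star)
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k in {%s}, %d resamples\n",
              paste(x$k_range, collapse = ","), x$n_resamples))
  if (!is.null(x$k_star)) {
    cat(sprintf("  selected k* = %d (cluster sizes: %s)\n", x$k_star,
                paste(table(x$labels), collapse = ", ")))
  }
  invisible(x)
}

#' Plot the consensus CDF-area curve
#'
#' @param x A [discover_subtypes()] result.
#' @param ... Passed to [plot()].
#' @export
plot_consensus_cdf <- function(x, ...) {
  stopifnot(!is.null(x$A))
  plot(as.integer(names(x$A)), x$A, type = "b", xlab = "k",
       ylab = "consensus CDF area", ...)
  if (!is.null(x$k_star)) graphics::abline(v = x$k_star, lty = 2)
  invisible(x)
}
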