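#' Moderated-t differential expression between two clusters
#'
#' Fits, per gene, a weighted least-squares group-means model across all
#' cluster labels (observation weights from the normalization step), takes
#' the contrast `a - b` on the log2 scale, and moderates the residual
#' variances by empirical-Bayes shrinkage toward a pooled prior: the
#' hyperparameters (d0, s0^2) are estimated by moment matching on
#' log residual variances via the digamma/trigamma system (Newton
#' iteration), and the posterior variance is
#' `(d0 * s0^2 + dg * sg^2) / (d0 + dg)`. The moderated t has `d0 + dg`
#' degrees of freedom.
#'
#' @param norm A `normalized_matrix` (log-expression plus weights).
#' @param labels Cluster label per sample (vector aligned with the sample
#'   columns, or named by sample id).
#' @param contrast Length-2 vector `(a, b)`: the comparison is a minus b.
#' @param prior_df,prior_var Optional injected hyperparameters overriding
#'   the empirical-Bayes estimates (used mainly for testing limits).
#' @return Object of class `de_result`: data.frame with columns `gene`,
#'   `logFC`, `sigma2`, `df`, `t_mod`, `p`, `q`; attributes `contrast` and
#'   `hyper` (list `d0`, `s02`).
#' @export
fit_moderated_de <- function(norm, labels, contrast,
                             prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  E <- norm$logexpr
  W <- norm$weights
  labels <- align_labels(labels, colnames(E))
  a <- as.character(contrast[[1]])
  b <- as.character(contrast[[2]])
  lev <- sort(unique(as.character(labels)))
  if (!all(c(a, b) %in% lev)) stopf("contrast clusters not present in labels")
  sizes <- table(labels)
  if (any(sizes[c(a, b)] < 2L)) {
    stopf("each contrasted cluster needs >= 2 samples")
  }
  n <- ncol(E)
  df_resid <- n - length(lev)
  if (df_resid <= 0L) stopf("zero residual degrees of freedom")

  ## weighted group means and their precisions, per gene
  Wsum <- vapply(lev, function(g) rowSums(W[, labels == g, drop = FALSE]),
                 numeric(nrow(E)))
  means <- vapply(lev, function(g) {
    sel <- labels == g
    rowSums(W[, sel, drop = FALSE] * E[, sel, drop = FALSE]) /
      rowSums(W[, sel, drop = FALSE])
  }, numeric(nrow(E)))
  if (!is.matrix(Wsum)) {
    Wsum <- matrix(Wsum, nrow = 1L, dimnames = list(NULL, lev))
    means <- matrix(means, nrow = 1L, dimnames = list(NULL, lev))
  }
  fitted <- means[, match(labels, lev), drop = FALSE]
  s2 <- rowSums(W * (E - fitted)^2) / df_resid
  logFC <- means[, a] - means[, b]
  v <- 1 / Wsum[, a] + 1 / Wsum[, b]

  if (is.null(prior_df) || is.null(prior_var)) {
    hyper <- fit_fdist_moments(s2, df_resid)
  } else {
    hyper <- list(d0 = prior_df, s02 = prior_var)
  }
  d0 <- hyper$d0
  s02 <- hyper$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  }
  t_mod <- logFC / sqrt(s2_post * v)
  df_total <- d0 + df_resid
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- data.frame(
    gene = rownames(E), logFC = logFC, sigma2 = s2, df = df_resid,
    t_mod = t_mod, p = p, q = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, contrast = c(a, b), hyper = hyper, class = c("de_result", "data.frame"))
}

align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing)) {
      stopf("labels missing for sample(s): %s", paste(missing, collapse = ", "))
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stopf("labels must be named by sample id or aligned with the samples")
  }
  as.character(labels)
}

## moment-matching estimate of the scaled-F prior for gene variances:
## solves E[log s^2] and Var[log s^2] identities via digamma/trigamma
fit_fdist_moments <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!all(ok)) {
    warnf("%d gene(s) with zero/non-finite residual variance excluded from prior estimation",
          sum(!ok))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    warnf("under-dispersed variances; falling back to prior df = 10")
    d0 <- 10
  } else {
    d0 <- 2 * trigamma_inverse(evar)
  }
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

## Newton solve of trigamma(x) = y for x > 0
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) (m * p_(j) / j)` clipped at
#' 1, mapped back to input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' All pairwise differential-expression contrasts between clusters
#'
#' @inheritParams fit_moderated_de
#' @param ... Passed to [fit_moderated_de()].
#' @return Named list of `de_result` objects, one per unordered cluster
#'   pair, named `"a_vs_b"` with a < b in sorted label order.
#' @export
all_pairwise_de <- function(norm, labels, ...) {
  labels <- align_labels(labels, colnames(norm$logexpr))
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stopf("need at least 2 clusters")
  out <- list()
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (i < j) {
        out[[sprintf("%s_vs_%s", lev[i], lev[j])]] <-
          fit_moderated_de(norm, labels, c(lev[i], lev[j]), ...)
      }
    }
  }
  out
}

#' Derive per-cluster over/under gene signatures
#'
#' A gene joins `C<c>_over` when, in every contrast of cluster c against
#' each other cluster, it is significant (`q < q_threshold`) with
#' `logFC > lfc_threshold` in the c-minus-other orientation; `C<c>_under`
#' analogously with `logFC < -lfc_threshold`. Contrast orientation is
#' flipped automatically when the stored contrast is (other, c).
#'
#' @param de_list Result of [all_pairwise_de()] covering every unordered
#'   cluster pair.
#' @param q_threshold BH-FDR significance cut (default 0.05).
#' @param lfc_threshold Minimum absolute log2 fold change (default 0; the
#'   membership rule then only constrains the direction).
#' @return Object of class `signature_set`: list with `sets` (named list
#'   `C<c>_over` / `C<c>_under` of gene-id vectors) and `provenance`
#'   (data.frame of qualifying contrasts and q-values per member gene).
#' @export
derive_signatures <- function(de_list, q_threshold = 0.05, lfc_threshold = 0) {
  contrasts <- lapply(de_list, attr, "contrast")
  clusters <- sort(unique(unlist(contrasts)))
  find_contrast <- function(a, b) {
    for (i in seq_along(contrasts)) {
      ct <- contrasts[[i]]
      if (ct[1] == a && ct[2] == b) return(list(de = de_list[[i]], sign = 1))
      if (ct[1] == b && ct[2] == a) return(list(de = de_list[[i]], sign = -1))
    }
    stopf("missing contrast between clusters %s and %s", a, b)
  }
  genes <- de_list[[1]]$gene
  sets <- list()
  prov <- list()
  for (cl in clusters) {
    over_ok <- rep(TRUE, length(genes))
    under_ok <- rep(TRUE, length(genes))
    rows <- list()
    for (other in setdiff(clusters, cl)) {
      fc <- find_contrast(cl, other)
      lfc <- fc$sign * fc$de$logFC
      sig <- fc$de$q < q_threshold
      over_ok <- over_ok & sig & (lfc > lfc_threshold)
      under_ok <- under_ok & sig & (lfc < -lfc_threshold)
      rows[[other]] <- data.frame(gene = genes, cluster = cl, other = other,
                                  logFC = lfc, q = fc$de$q,
                                  stringsAsFactors = FALSE)
    }
    evidence <- do.call(rbind, rows)
    for (dir in c("over", "under")) {
      member <- if (dir == "over") over_ok else under_ok
      nm <- sprintf("C%s_%s", cl, dir)
      sets[[nm]] <- genes[member]
      if (any(member)) {
        pr <- evidence[evidence$gene %in% genes[member], , drop = FALSE]
        pr$set <- nm
        prov[[nm]] <- pr
      }
    }
  }
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(gene = character(), cluster = character(), other = character(),
               logFC = numeric(), q = numeric(), set = character())
  rownames(provenance) <- NULL
  structure(
    list(sets = sets, provenance = provenance,
         q_threshold = q_threshold, lfc_threshold = lfc_threshold),
    class = "signature_set"
  )
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %s: %d genes\n", nm, length(x$sets[[nm]])))
  }
  invisible(x)
}
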