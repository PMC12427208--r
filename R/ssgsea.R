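#' Single-sample enrichment score of one gene set
#'
#' Genes are ranked by descending expression (ties broken by gene id).
#' With N genes, rank positions r (1 = highest) get the rank weight
#' `u = N - r + 1` so the top of the ranking carries the largest weight.
#' The enrichment score is the summed difference of the weighted hit CDF
#' and the uniform miss CDF along the ranking:
#' `ES = sum_i P_hit(i) - P_miss(i)` with
#' `P_hit(i) = sum(u_j^alpha, j in S, r_j <= i) / sum(u^alpha over S)` and
#' `P_miss(i) = #(non-set genes with r_j <= i) / (N - m)`. Positive ES
#' means the set concentrates at the top of the sample's ranking.
#'
#' @param expr Named numeric vector: one sample's expression per gene.
#' @param gene_set Character vector of gene ids.
#' @param alpha Rank-weight exponent (default 0.25; 0 gives the unweighted
#'   rank statistic).
#' @return A single enrichment score.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  if (is.null(names(expr))) stopf("expr must be named by gene id")
  N <- length(expr)
  hit <- names(expr) %in% gene_set
  m <- sum(hit)
  if (m < 1L) stopf("gene set is empty after intersecting with the genes")
  if (m >= N) stopf("gene set must not cover all genes")
  ord <- order(-expr, names(expr), method = "radix")
  pos <- which(names(expr)[ord] %in% gene_set)
  es_from_positions(pos, N, m, alpha)
}

## closed form of the running-sum ES given the set's rank positions:
## a gene at position p contributes to all N - p + 1 running-sum terms
es_from_positions <- function(pos, N, m, alpha) {
  u <- N - pos + 1
  w <- u^alpha
  hit_sum <- sum(w * u) / sum(w)
  miss_sum <- (N * (N + 1) / 2 - sum(u)) / (N - m)
  hit_sum - miss_sum
}

## permutation null: ES of random same-size gene sets (positions uniform
## without replacement); depends only on (N, m, alpha)
ssgsea_null <- function(N, m, alpha, n_perm) {
  vapply(seq_len(n_perm), function(i) {
    es_from_positions(sample.int(N, m), N, m, alpha)
  }, numeric(1))
}

#' Single-sample enrichment of a cohort against gene sets
#'
#' Scores every (sample, gene set) pair with [ssgsea_score()] and
#' standardizes each score against a gene-permutation null: NES is the
#' z-score of ES against `n_perm` random same-size sets, and the p-value
#' is the two-sided normal tail `2 * (1 - Phi(|NES|))`. The null is
#' computed once per (sample, set size) stratum and reused across sets of
#' identical size within a sample. Genes absent from the expression matrix
#' are dropped from each set; sets smaller than `min_set_size` after the
#' intersection are skipped with a warning.
#'
#' By default each gene is standardized (centered and scaled) across the
#' cohort before ranking, so a sample's ranking reflects each gene's
#' expression *relative to its cohort average*. This is what over/under
#' signatures describe; on raw abundance ranks a fold change cannot move a
#' gene across the abundance spectrum and enrichment of DE-derived sets is
#' invisible. Set `standardize = FALSE` to rank raw values.
#'
#' @param expr Genes x samples numeric matrix (e.g. normalized
#'   log-expression), or a `normalized_matrix`.
#' @param sets Named list of gene-id vectors.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param n_perm Number of gene-label permutations (default 1000,
#'   minimum 100).
#' @param seed Integer seed for the permutation null.
#' @param min_set_size Minimum post-intersection set size (default 5).
#' @param standardize Center and scale each gene across samples before
#'   ranking (default `TRUE`).
#' @return Object of class `enrichment_table`: data.frame with columns
#'   `sample_id`, `set`, `size`, `ES`, `NES`, `p`.
#' @export
ssgsea_enrich <- function(expr, sets, alpha = 0.25, n_perm = 1000L,
                          seed = 1L, min_set_size = 5L, standardize = TRUE) {
  if (inherits(expr, "normalized_matrix")) expr <- expr$logexpr
  stopifnot(is.matrix(expr))
  if (n_perm < 100L) stopf("n_perm must be >= 100")
  if (isTRUE(standardize)) {
    if (ncol(expr) < 3L) stopf("standardize requires >= 3 samples")
    mu <- rowMeans(expr)
    sdv <- sqrt(rowSums((expr - mu)^2) / (ncol(expr) - 1))
    if (any(sdv == 0)) {
      warnf("dropping %d constant gene(s) before standardization", sum(sdv == 0))
      expr <- expr[sdv > 0, , drop = FALSE]
      mu <- mu[sdv > 0]; sdv <- sdv[sdv > 0]
    }
    expr <- (expr - mu) / sdv
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stopf("sets must be uniquely named")
  }
  genes <- rownames(expr)
  N <- length(genes)
  kept_sets <- lapply(sets, function(s) intersect(unique(s), genes))
  sizes <- lengths(kept_sets)
  drop <- sizes < min_set_size | sizes >= N
  if (any(drop)) {
    warnf("skipping %d set(s) below %d genes (or covering all genes) after intersection: %s",
          sum(drop), min_set_size, paste(names(sets)[drop], collapse = ", "))
    kept_sets <- kept_sets[!drop]
    sizes <- sizes[!drop]
  }
  if (!length(kept_sets)) stopf("no usable gene sets")

  rows <- vector("list", ncol(expr))
  with_seed(seed, {
    for (j in seq_len(ncol(expr))) {
      col <- expr[, j]
      if (stats::sd(col) == 0) {
        stopf("degenerate (constant) expression column: %s", colnames(expr)[j])
      }
      ord <- order(-col, genes, method = "radix")
      ranked <- genes[ord]
      rank_of <- integer(N)
      rank_of[ord] <- seq_len(N)
      null_cache <- list()
      es <- nes <- pv <- numeric(length(kept_sets))
      for (s in seq_along(kept_sets)) {
        m <- sizes[[s]]
        pos <- rank_of[match(kept_sets[[s]], genes)]
        es[s] <- es_from_positions(pos, N, m, alpha)
        key <- as.character(m)
        if (is.null(null_cache[[key]])) {
          null_cache[[key]] <- ssgsea_null(N, m, alpha, n_perm)
        }
        nd <- null_cache[[key]]
        sd_null <- stats::sd(nd)
        if (sd_null == 0) stopf("degenerate permutation null (sd = 0)")
        nes[s] <- (es[s] - mean(nd)) / sd_null
        pv[s] <- 2 * stats::pnorm(-abs(nes[s]))
      }
      rows[[j]] <- data.frame(
        sample_id = colnames(expr)[j], set = names(kept_sets),
        size = as.integer(sizes), ES = es, NES = nes, p = pv,
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
  })
  structure(do.call(rbind, rows),
            class = c("enrichment_table", "data.frame"))
}

## parse "C<k>_over"/"C<k>_under" signature names into cluster/direction
parse_signature_name <- function(x) {
  mt <- regmatches(x, regexec("^C([0-9]+)_(over|under)$", x))
  t(vapply(mt, function(m) {
    if (length(m) != 3L) c(NA_character_, NA_character_) else m[2:3]
  }, character(2)))
}

#' Classify samples by their most significant signature enrichment
#'
#' Per sample, p-values are BH-adjusted across all scored sets (signature
#' sets plus any context sets, e.g. pathway collections); context sets are
#' then discarded and the sample is assigned the cluster of the signature
#' set with the smallest adjusted p-value, provided it is below
#' `threshold`; otherwise the sample is left unassigned. Ties resolve to
#' the first set name in ascending order. With
#' `require_sign_concordance = TRUE` a signature set only qualifies when
#' the sign of its NES matches its direction (negative for `_under`,
#' positive for `_over`).
#'
#' @param enrich An [ssgsea_enrich()] result covering the signature sets
#'   (and any context sets).
#' @param signature_sets Character vector of signature set names
#'   (`C<k>_over` / `C<k>_under`); defaults to all parseable names in
#'   `enrich`.
#' @param threshold Adjusted-p significance cut (default 0.05).
#' @param require_sign_concordance Require NES sign to match the set
#'   direction (default `FALSE`).
#' @return Data.frame with one row per sample: `sample_id`,
#'   `assigned_cluster` (integer or `NA` for unassigned), `winning_set`,
#'   `winning_q`, `sign_concordant`.
#' @export
classify_samples <- function(enrich, signature_sets = NULL, threshold = 0.05,
                             require_sign_concordance = FALSE) {
  stopifnot(inherits(enrich, "enrichment_table") || is.data.frame(enrich))
  all_sets <- unique(enrich$set)
  if (is.null(signature_sets)) {
    parsed_all <- parse_signature_name(all_sets)
    signature_sets <- all_sets[!is.na(parsed_all[, 1])]
  }
  if (!length(signature_sets)) stopf("no signature sets supplied")
  parsed <- parse_signature_name(signature_sets)
  if (any(is.na(parsed[, 1]))) {
    stopf("signature set name(s) not of the form C<k>_over/C<k>_under: %s",
          paste(signature_sets[is.na(parsed[, 1])], collapse = ", "))
  }
  cluster_of <- as.integer(parsed[, 1])
  direction_of <- parsed[, 2]
  names(cluster_of) <- names(direction_of) <- signature_sets

  out <- lapply(split(enrich, enrich$sample_id), function(d) {
    d$q <- bh_adjust(d$p)           # across ALL sets scored for this sample
    d <- d[d$set %in% signature_sets, , drop = FALSE]
    if (!nrow(d)) stopf("sample %s has no scored signature sets", d$sample_id[1])
    d <- d[order(d$q, d$set, method = "radix"), , drop = FALSE]
    concord <- ifelse(direction_of[d$set] == "under", d$NES < 0, d$NES > 0)
    eligible <- d$q < threshold
    if (require_sign_concordance) eligible <- eligible & concord
    if (any(eligible)) {
      i <- which(eligible)[1]
      data.frame(sample_id = d$sample_id[1],
                 assigned_cluster = cluster_of[[d$set[i]]],
                 winning_set = d$set[i], winning_q = d$q[i],
                 sign_concordant = concord[i],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = d$sample_id[1],
                 assigned_cluster = NA_integer_,
                 winning_set = NA_character_, winning_q = d$q[1],
                 sign_concordant = NA,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  ## restore the input sample order (split() sorts by factor level)
  res[match(unique(enrich$sample_id), res$sample_id), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}
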