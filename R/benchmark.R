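#' Compare prognostic models by Harrell's C-index
#'
#' Fits a Cox model per specification on the full data and evaluates the
#' apparent concordance (train = evaluate) of its fitted linear predictor,
#' matching single-cohort model comparisons. An optional k-fold
#' cross-validated C is available via [cv_concordance()].
#'
#' @param data Data frame with survival columns and all referenced
#'   covariates.
#' @param specs Named list of covariate vectors, one per model.
#' @param time,event Survival column names.
#' @param ties Tie handling for the Cox fits.
#' @return Data.frame (class `benchmark_c_table`), one row per model with
#'   `c_index`, `n_events`, `n_pairs` and the model log-likelihood, sorted
#'   by decreasing C.
#' @export
compare_models <- function(data, specs, time = "os_months",
                           event = "os_event", ties = "efron") {
  if (is.null(names(specs)) || any(names(specs) == "") ||
      anyDuplicated(names(specs))) {
    stopf("model specs must have unique non-empty names")
  }
  rows <- lapply(names(specs), function(nm) {
    fit <- tryCatch(
      cox_fit(data, time, event, specs[[nm]], ties = ties),
      error = function(e) stopf("model '%s' failed: %s", nm, conditionMessage(e))
    )
    ci <- concordance_index(data[[time]], data[[event]], fit$linear_predictor)
    data.frame(model = nm, c_index = ci$c_index, n_events = fit$n_events,
               n_pairs = ci$n_pairs, loglik = fit$loglik[["final"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$c_index, out$model), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("benchmark_c_table", "data.frame")
  out
}

#' Cross-validated concordance of a Cox model
#'
#' K-fold cross-validation: the model is fit on k-1 folds and the held-out
#' linear predictors are pooled before a single concordance computation.
#' An honest alternative to the apparent C reported by [compare_models()].
#'
#' @inheritParams compare_models
#' @param covariates Covariate vector for the model.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List as returned by [concordance_index()].
#' @export
cv_concordance <- function(data, covariates, time = "os_months",
                           event = "os_event", k = 5L, seed = 1L) {
  n <- nrow(data)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  lp <- numeric(n)
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    fit <- cox_fit(train, time, event, covariates)
    X_test <- build_design(data[folds == f, , drop = FALSE], covariates)
    ## apply the training centering so train/test predictors share a scale
    X_test <- sweep(X_test, 2, colMeans(build_design(train, covariates)))
    lp[folds == f] <- drop(X_test %*% fit$coefficients)
  }
  concordance_index(data[[time]], data[[event]], lp)
}

#' Sub-stratification by a predicted 5-year OS threshold
#'
#' Splits the cohort at the external risk score (favorable: score >
#' threshold; unfavorable: score <= threshold, so the boundary value falls
#' in the unfavorable stratum) and, within each stratum, compares survival
#' across cluster groups with Kaplan-Meier curves and a log-rank test.
#'
#' @param data Data frame with survival columns, the risk score and the
#'   cluster labels.
#' @param risk,cluster Column names of the risk score (in \[0, 1\]) and
#'   the cluster label.
#' @param threshold Risk-score cut (default 0.60).
#' @param grouping `"all-clusters"` (default) or `"C1-vs-rest"` (first
#'   sorted cluster against the rest).
#' @param time,event Survival column names.
#' @return Named list (`favorable`, `unfavorable`) of per-stratum results:
#'   `n`, `groups`, `km` (list of [km_curve()] per group) and `logrank`
#'   (`NULL` when fewer than 2 non-empty groups remain, with a warning).
#' @export
substratify_by_risk <- function(data, risk = "risk_score_5yOS",
                                cluster = "cluster", threshold = 0.60,
                                grouping = c("all-clusters", "C1-vs-rest"),
                                time = "os_months", event = "os_event") {
  grouping <- match.arg(grouping)
  score <- data[[risk]]
  if (any(score < 0 | score > 1)) stopf("risk score must lie in [0, 1]")
  cl <- as.character(data[[cluster]])
  grp <- if (grouping == "all-clusters") cl else {
    ref <- sort(unique(cl))[1]
    ifelse(cl == ref, paste0("C", ref), "rest")
  }
  stratum <- ifelse(score > threshold, "favorable", "unfavorable")
  present <- unique(stratum)
  if (length(present) == 1L && length(unique(grp)) < 2L) {
    stopf("all samples fall in one stratum and the grouping is degenerate")
  }
  out <- list()
  for (s in c("favorable", "unfavorable")) {
    sel <- stratum == s
    if (!any(sel)) {
      warnf("stratum '%s' is empty", s)
      next
    }
    gs <- grp[sel]
    empty <- setdiff(unique(grp), unique(gs))
    if (length(empty)) {
      warnf("stratum '%s': dropping empty group(s) %s", s,
            paste(empty, collapse = ", "))
    }
    km <- lapply(split(seq_len(sum(sel)), gs), function(idx) {
      km_curve(data[[time]][sel][idx], data[[event]][sel][idx])
    })
    lr <- if (length(unique(gs)) >= 2L && sum(data[[event]][sel]) >= 1) {
      logrank_test(data[[time]][sel], data[[event]][sel], gs)
    } else {
      warnf("stratum '%s': log-rank not computable", s)
      NULL
    }
    out[[s]] <- list(n = sum(sel), groups = sort(unique(gs)),
                     km = km, logrank = lr)
  }
  out
}

#' Overlap between two gene sets
#'
#' Percentage overlap uses the first set (the comparator list) as the
#' denominator: `100 * |A inter B| / |A|`; the Jaccard index is reported
#' alongside.
#'
#' @param set_a,set_b Non-empty character vectors of gene ids.
#' @param universe Optional gene universe both sets must belong to.
#' @return List with `pct_overlap`, `jaccard`, `n_common`.
#' @export
signature_overlap <- function(set_a, set_b, universe = NULL) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b)) stopf("gene sets must be non-empty")
  if (!is.null(universe)) {
    out <- setdiff(c(set_a, set_b), universe)
    if (length(out)) {
      stopf("gene(s) outside the universe: %s",
            paste(utils::head(out, 5), collapse = ", "))
    }
  }
  common <- length(intersect(set_a, set_b))
  list(pct_overlap = 100 * common / length(set_a),
       jaccard = common / length(union(set_a, set_b)),
       n_common = common)
}

#' Spearman correlation of per-sample enrichment between two gene sets
#'
#' Rank-correlates the per-sample NES vectors of two scored gene sets
#' (average ranks on ties, p-value via the t approximation).
#'
#' @param enrich An [ssgsea_enrich()] table containing both sets.
#' @param set_a,set_b Set names.
#' @return List with `rho` and `p`.
#' @export
nes_correlation <- function(enrich, set_a, set_b) {
  a <- enrich[enrich$set == set_a, c("sample_id", "NES")]
  b <- enrich[enrich$set == set_b, c("sample_id", "NES")]
  mg <- merge(a, b, by = "sample_id")
  if (nrow(mg) < 3L) stopf("need NES for both sets on >= 3 shared samples")
  if (stats::sd(mg$NES.x) == 0 || stats::sd(mg$NES.y) == 0) {
    stopf("constant NES vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(mg$NES.x, mg$NES.y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}
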