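pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    discovery = list(counts = NULL, clinical = NULL, synthetic_seed = 7L),
    validation = list(counts = NULL, clinical = NULL, synthetic_seed = 13L),
    cohort = list(),  # overrides forwarded to cohort_config() for synthesis
    preprocess = list(min_cpm = 1.0, min_fraction = 0.2,
                      quantile_discovery = FALSE, quantile_validation = TRUE,
                      keep_fraction = 0.55),
    discover = list(kmin = 2L, kmax = 8L, n_resamples = 1000L,
                    item_fraction = 0.8, selector = "elbow"),
    signatures = list(q_threshold = 0.05, lfc_threshold = 0),
    classify = list(alpha = 0.25, n_perm = 1000L, threshold = 0.05,
                    concordant = FALSE, context_gmt = NULL,
                    min_set_size = 5L),
    survival = list(time = "os_months", event = "os_event",
                    covariates = c("cluster", "age_years")),
    benchmark = list(risk_col = "risk_score_5yOS", threshold = 0.60)
  )
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the package defaults, one namespace per
#' stage. Unknown keys are rejected rather than ignored, so typos cannot
#' silently fall back to defaults.
#'
#' @param ... Named stage settings (e.g.
#'   `discover = list(n_resamples = 250)`), plus top-level `seed` and
#'   `outdir`.
#' @return Object of class `pipeline_config` (nested list).
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && nm != "cohort") {
      bad <- setdiff(names(user[[nm]]), names(defaults[[nm]]))
      if (length(bad)) {
        stopf("unknown config key(s) in %s: %s", nm, paste(bad, collapse = ", "))
      }
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (cfg$discover$kmax < cfg$discover$kmin) {
    stopf("discover: kmax (%d) < kmin (%d)", cfg$discover$kmax, cfg$discover$kmin)
  }
  structure(cfg, class = "pipeline_config")
}

load_pipeline_cohort <- function(spec, cohort_overrides, role) {
  if (!is.null(spec$counts)) {
    counts <- read_counts_tsv(spec$counts)
    clinical <- read_clinical_csv(spec$clinical)
    check_sample_match(counts$sample_ids, clinical$sample_id, role)
    list(counts = counts, clinical = clinical, truth = NULL)
  } else {
    cfg <- do.call(cohort_config, c(cohort_overrides,
                                    list(seed = spec$synthetic_seed)))
    cohort <- gen_cohort(cfg)
    list(counts = cohort$counts, clinical = cohort$clinical,
         truth = cohort$truth)
  }
}

#' Run the full subtype discovery and prognostic evaluation pipeline
#'
#' Discovery cohort: expression filter, variance-stabilizing
#' normalization, MAD filter, consensus clustering with elbow k-selection,
#' pairwise moderated-t differential expression and signature derivation.
#' Validation cohort: filter, quantile-normalized log-expression,
#' single-sample enrichment against the derived signatures, per-sample
#' classification, Cox survival modeling on the assigned clusters and a
#' C-index benchmark of model combinations. All artifacts, the resolved
#' configuration and the seed are written to `outdir`; numeric output is
#' fixed at 10 significant digits so identical configurations reproduce
#' identical files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main stage results (`discovery`,
#'   `signatures`, `calls`, `survival`, `benchmark`) and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$outdir)) stopf("config$outdir must be set")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(outdir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", nm, conditionMessage(e))
    })
  }

  ## ---- discovery cohort ----
  disc <- stage("load-discovery",
                load_pipeline_cohort(config$discovery, config$cohort, "discovery"))
  message(sprintf("discovery cohort: %d genes x %d samples",
                  nrow(disc$counts$values), ncol(disc$counts$values)))
  pp <- config$preprocess
  filt <- stage("preprocess", expression_filter(disc$counts, pp$min_cpm, pp$min_fraction))
  norm <- stage("preprocess", normalize_counts(filt, quantile = pp$quantile_discovery))
  kept <- stage("preprocess", mad_filter(norm, pp$keep_fraction))
  message(sprintf("preprocess: %d genes pass expression filter, %d kept by MAD",
                  nrow(filt$values), nrow(kept$logexpr)))
  write_matrix_tsv(kept$logexpr, file.path(outdir, "normalized.tsv"))
  write_matrix_tsv(kept$weights, file.path(outdir, "weights.tsv"))

  dv <- config$discover
  res <- stage("discover", discover_subtypes(
    kept, k_range = dv$kmin:dv$kmax, n_resamples = dv$n_resamples,
    item_fraction = dv$item_fraction, seed = config$seed,
    selector = dv$selector
  ))
  message(sprintf("discover: k* = %d (A(k): %s)", res$k_star,
                  paste(sprintf("%d=%.3f", as.integer(names(res$A)), res$A),
                        collapse = " ")))
  write_table_csv(data.frame(k = as.integer(names(res$A)), cdf_area = res$A),
                  file.path(outdir, "cdf_area.csv"))
  write_table_csv(data.frame(sample_id = names(res$labels), cluster = res$labels),
                  file.path(outdir, "labels.csv"))
  write_matrix_tsv(res$M[[as.character(res$k_star)]],
                   file.path(outdir, "consensus_kstar.tsv"))

  sg <- config$signatures
  de <- stage("signatures", all_pairwise_de(kept, res$labels))
  sigs <- stage("signatures", derive_signatures(de, sg$q_threshold, sg$lfc_threshold))
  for (nm in names(de)) {
    write_table_csv(as.data.frame(de[[nm]]),
                    file.path(outdir, sprintf("de_%s.csv", nm)))
  }
  nonempty <- sigs$sets[lengths(sigs$sets) > 0]
  write_gmt(nonempty, file.path(outdir, "signatures.gmt"))
  message(sprintf("signatures: %s",
                  paste(sprintf("%s=%d", names(sigs$sets), lengths(sigs$sets)),
                        collapse = " ")))

  ## ---- validation cohort ----
  val <- stage("load-validation",
               load_pipeline_cohort(config$validation, config$cohort, "validation"))
  vfilt <- stage("classify", expression_filter(val$counts, pp$min_cpm, pp$min_fraction))
  vnorm <- stage("classify", normalize_counts(vfilt, quantile = pp$quantile_validation))
  cl <- config$classify
  sets <- nonempty
  if (!is.null(cl$context_gmt)) sets <- c(sets, read_gmt(cl$context_gmt))
  enrich <- stage("classify", ssgsea_enrich(
    vnorm$logexpr, sets, alpha = cl$alpha, n_perm = cl$n_perm,
    seed = config$seed + 1L, min_set_size = cl$min_set_size
  ))
  calls <- stage("classify", classify_samples(
    enrich, signature_sets = intersect(names(nonempty), unique(enrich$set)),
    threshold = cl$threshold,
    require_sign_concordance = cl$concordant
  ))
  write_table_csv(as.data.frame(enrich), file.path(outdir, "enrichment.csv"))
  write_table_csv(calls, file.path(outdir, "calls.csv"))
  message(sprintf("classify: %d/%d samples assigned",
                  sum(!is.na(calls$assigned_cluster)), nrow(calls)))

  ## ---- survival & benchmark on assigned validation samples ----
  sv <- config$survival
  clin <- merge(val$clinical, data.frame(sample_id = calls$sample_id,
                                         cluster = calls$assigned_cluster),
                by = "sample_id")
  assigned <- clin[!is.na(clin$cluster), , drop = FALSE]
  assigned$cluster <- factor(assigned$cluster)
  surv_res <- NULL
  bench <- NULL
  if (nrow(assigned) >= 10 && nlevels(assigned$cluster) >= 2) {
    surv_res <- stage("survival", {
      fit <- cox_fit(assigned, sv$time, sv$event, sv$covariates)
      lr <- logrank_test(assigned[[sv$time]], assigned[[sv$event]],
                         assigned$cluster)
      ph <- schoenfeld_ph_test(fit)
      list(cox = fit, logrank = lr, ph = ph)
    })
    write_table_csv(
      data.frame(term = names(surv_res$cox$coefficients),
                 coef = surv_res$cox$coefficients, hr = surv_res$cox$hr,
                 lower95 = surv_res$cox$ci_lower, upper95 = surv_res$cox$ci_upper,
                 p = surv_res$cox$p),
      file.path(outdir, "cox_os.csv"))
    write_table_csv(surv_res$ph, file.path(outdir, "schoenfeld.csv"))
    bench <- stage("benchmark", {
      specs <- list(cluster = "cluster",
                    risk_score = config$benchmark$risk_col,
                    cluster_age = c("cluster", "age_years"),
                    risk_cluster = c(config$benchmark$risk_col, "cluster"))
      specs <- Filter(function(cv) all(cv %in% colnames(assigned)), specs)
      tab <- compare_models(assigned, specs, time = sv$time, event = sv$event)
      strat <- substratify_by_risk(assigned, risk = config$benchmark$risk_col,
                                   cluster = "cluster",
                                   threshold = config$benchmark$threshold,
                                   time = sv$time, event = sv$event)
      list(c_table = tab, strata = strat)
    })
    write_table_csv(as.data.frame(bench$c_table),
                    file.path(outdir, "benchmark_cindex.csv"))
  } else {
    message("survival/benchmark skipped: too few assigned samples or clusters")
  }

  invisible(list(
    discovery = res, signatures = sigs, enrichment = enrich, calls = calls,
    survival = surv_res, benchmark = bench,
    truth = list(discovery = disc$truth, validation = val$truth),
    outdir = outdir
  ))
}
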