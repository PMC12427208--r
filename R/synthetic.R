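#' Configuration for a synthetic sarcoma-like expression cohort
#'
#' Defines the generative conditions for [gen_cohort()]: a negative-binomial
#' count matrix with disjoint per-subtype over/under marker blocks,
#' subtype-dependent exponential survival with administrative and dropout
#' censoring, simple clinical covariates, and a noisy external 5-year-OS
#' risk score on the probability scale.
#'
#' @param n_samples Number of samples (default 120).
#' @param n_subtypes Number of planted subtypes (default 4).
#' @param subtype_proportions Simplex vector of subtype frequencies;
#'   defaults to equal proportions. Must sum to 1 (tolerance 1e-8).
#' @param n_genes Number of genes (default 1500).
#' @param markers_per_subtype_per_direction Size of each planted marker
#'   block (default 40); blocks are disjoint across (subtype, direction).
#' @param log2_effect Multiplicative shift (log2 scale) applied to marker
#'   gene means in their subtype: over-markers x `2^log2_effect`,
#'   under-markers x `2^-log2_effect` (default 2).
#' @param nb_dispersion Negative-binomial dispersion; variance is
#'   `mu + nb_dispersion * mu^2` (default 0.1).
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size
#'   parameters (defaults `log(2e5)` and 0.3).
#' @param hazards_per_month Exponential death hazard per subtype, per month
#'   (default `c(0.010, 0.030, 0.028, 0.035)`).
#' @param admin_censor_months Administrative censoring time (default 120).
#' @param dropout_rate_per_month Exponential dropout-censoring hazard
#'   (default 0.005; 0 disables dropout).
#' @param risk_score_noise_sd Gaussian noise added to the external risk
#'   score before clipping to \[0, 1\] (default 0.05).
#' @param seed Integer seed for everything sample-level (subtype draw,
#'   counts, survival, covariates, noise).
#' @param gene_seed Integer seed for the gene universe (baseline
#'   abundances and marker-block positions). Cohorts sharing `gene_seed`
#'   share the same planted generative truth, so signatures discovered on
#'   one transfer to the other; the default is a fixed constant.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 120L,
                          n_subtypes = 4L,
                          subtype_proportions = NULL,
                          n_genes = 1500L,
                          markers_per_subtype_per_direction = 40L,
                          log2_effect = 2.0,
                          nb_dispersion = 0.1,
                          libsize_log_mean = log(2e5),
                          libsize_log_sd = 0.3,
                          hazards_per_month = c(0.010, 0.030, 0.028, 0.035),
                          admin_censor_months = 120,
                          dropout_rate_per_month = 0.005,
                          risk_score_noise_sd = 0.05,
                          seed = 1L,
                          gene_seed = 101L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_subtypes = as.integer(n_subtypes),
    subtype_proportions = subtype_proportions %||% rep(1 / n_subtypes, n_subtypes),
    n_genes = as.integer(n_genes),
    markers_per_subtype_per_direction = as.integer(markers_per_subtype_per_direction),
    log2_effect = log2_effect,
    nb_dispersion = nb_dispersion,
    libsize_log_mean = libsize_log_mean,
    libsize_log_sd = libsize_log_sd,
    hazards_per_month = hazards_per_month,
    admin_censor_months = admin_censor_months,
    dropout_rate_per_month = dropout_rate_per_month,
    risk_score_noise_sd = risk_score_noise_sd,
    seed = as.integer(seed),
    gene_seed = as.integer(gene_seed)
  )
  with(cfg, {
    if (n_samples < 1L || n_subtypes < 1L || n_genes < 1L) {
      stopf("n_samples, n_subtypes and n_genes must all be >= 1")
    }
    if (length(subtype_proportions) != n_subtypes) {
      stopf("subtype_proportions must have length n_subtypes")
    }
    if (abs(sum(subtype_proportions) - 1) > 1e-8) {
      stopf("subtype_proportions must sum to 1 (got %.10f)",
            sum(subtype_proportions))
    }
    if (length(hazards_per_month) != n_subtypes) {
      stopf("hazards_per_month must have one hazard per subtype (%d != %d)",
            length(hazards_per_month), n_subtypes)
    }
    if (any(hazards_per_month <= 0)) stopf("hazards must be > 0")
    if (nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
    if (log2_effect < 0) stopf("log2_effect must be >= 0")
    if (markers_per_subtype_per_direction < 0) {
      stopf("markers_per_subtype_per_direction must be >= 0")
    }
    if (2L * n_subtypes * markers_per_subtype_per_direction > n_genes) {
      stopf("marker blocks (%d genes) exceed n_genes (%d)",
            2L * n_subtypes * markers_per_subtype_per_direction, n_genes)
    }
    if (dropout_rate_per_month < 0 || risk_score_noise_sd < 0) {
      stopf("dropout rate and risk-score noise must be >= 0")
    }
  })
  structure(cfg, class = "cohort_config")
}

## ratio of recurrence hazard to death hazard used for the DFS endpoint;
## makes DFS events more frequent than OS events, as in real cohorts
RECURRENCE_HAZARD_FACTOR <- 1.6

#' Generate a synthetic cohort with planted subtypes
#'
#' Counts are negative-binomial with mean
#' `libsize_s * baseline_g * fold(g, subtype_s)` where the fold change is
#' `2^(+/- log2_effect)` on a subtype's marker genes and 1 elsewhere.
#' Death times are exponential with the subtype hazard; observed survival
#' is censored by the minimum of the administrative horizon and an
#' exponential dropout time. DFS uses an event time
#' `min(recurrence, death)` with recurrence hazard 1.6x the death hazard,
#' so `dfs_months <= os_months` always. The external risk score is
#' `exp(-60 * hazard_subtype)` (a 5-year OS probability) plus Gaussian
#' noise, clipped to \[0, 1\]. The same seed reproduces the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: list with `counts`
#'   (a [count_matrix()]), `clinical` (data.frame), `truth` (named integer
#'   subtype per sample) and `planted_markers` (named list of gene-id sets,
#'   names `C<k>_over` / `C<k>_under`).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  G <- config$n_genes
  k <- config$n_subtypes
  gene_ids <- sprintf("g%05d", seq_len(G))
  sample_ids <- sprintf("s%04d", seq_len(n))

  ## the gene universe -- baseline abundances and marker-block positions --
  ## is drawn from gene_seed so that cohorts with different sample seeds
  ## share the same planted generative truth
  universe <- with_seed(config$gene_seed, {
    m <- config$markers_per_subtype_per_direction
    planted <- list()
    marker_pool <- sample.int(G, 2L * k * m)
    idx <- 0L
    for (cl in seq_len(k)) {
      for (dir in c("over", "under")) {
        planted[[sprintf("C%d_%s", cl, dir)]] <-
          gene_ids[marker_pool[idx + seq_len(m)]]
        idx <- idx + m
      }
    }
    baseline <- exp(stats::rnorm(G, mean = 0, sd = 1.2))
    list(planted = planted, baseline = baseline / sum(baseline))
  })
  planted <- universe$planted
  baseline <- universe$baseline

  with_seed(config$seed, {
    ## deterministic subtype sizes: floor + largest remainders
    raw <- config$subtype_proportions * n
    sizes <- floor(raw)
    rem <- n - sum(sizes)
    if (rem > 0) {
      extra <- order(-(raw - sizes), seq_len(k))[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    truth <- sample(rep.int(seq_len(k), sizes))
    names(truth) <- sample_ids

    fold <- matrix(1, nrow = G, ncol = k)
    for (cl in seq_len(k)) {
      fold[match(planted[[sprintf("C%d_over", cl)]], gene_ids), cl] <-
        2^config$log2_effect
      fold[match(planted[[sprintf("C%d_under", cl)]], gene_ids), cl] <-
        2^(-config$log2_effect)
    }

    lib <- exp(stats::rnorm(n, config$libsize_log_mean, config$libsize_log_sd))
    mu <- sweep(baseline * fold[, truth, drop = FALSE], 2, lib, "*")
    counts <- matrix(
      stats::rnbinom(G * n, mu = mu, size = 1 / config$nb_dispersion),
      nrow = G, dimnames = list(gene_ids, sample_ids)
    )

    lam <- config$hazards_per_month[truth]
    t_death <- stats::rexp(n, rate = lam)
    t_rec <- stats::rexp(n, rate = RECURRENCE_HAZARD_FACTOR * lam)
    t_drop <- if (config$dropout_rate_per_month > 0) {
      stats::rexp(n, rate = config$dropout_rate_per_month)
    } else rep(Inf, n)
    censor <- pmin(config$admin_censor_months, t_drop)
    os_months <- pmin(t_death, censor)
    os_event <- as.integer(t_death <= censor)
    t_dfs <- pmin(t_rec, t_death)
    dfs_months <- pmin(t_dfs, censor)
    dfs_event <- as.integer(t_dfs <= censor)

    risk <- exp(-60 * config$hazards_per_month)[truth] +
      stats::rnorm(n, 0, config$risk_score_noise_sd)
    risk <- pmin(1, pmax(0, risk))

    clinical <- data.frame(
      sample_id = sample_ids,
      os_months = os_months, os_event = os_event,
      dfs_months = dfs_months, dfs_event = dfs_event,
      age_years = pmin(95, pmax(18, round(stats::rnorm(n, 65, 12)))),
      histotype = sample(c("DDLPS", "LMS", "UPS"), n, replace = TRUE,
                         prob = c(0.22, 0.20, 0.58)),
      grade = sample(c("G2", "G3"), n, replace = TRUE, prob = c(0.35, 0.65)),
      adjuvant_rt = stats::rbinom(n, 1, 0.6),
      risk_score_5yOS = risk,
      stringsAsFactors = FALSE
    )

    structure(
      list(counts = count_matrix(counts), clinical = clinical,
           truth = truth, planted_markers = planted, config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples, %d planted subtypes\n",
              nrow(x$counts$values), ncol(x$counts$values),
              x$config$n_subtypes))
  invisible(x)
}

#' Build an external comparator gene list with controlled overlap
#'
#' Emulates a published prognostic gene list (e.g. a 67-gene signature)
#' whose overlap with one planted marker set is fixed by construction:
#' `round(overlap_fraction * size)` genes are drawn from the targeted
#' planted set and the remainder from genes belonging to no planted set.
#'
#' @param cohort A [gen_cohort()] result.
#' @param size Number of genes in the list.
#' @param overlap_fraction Fraction of the list drawn from the target
#'   marker set, in \[0, 1\].
#' @param target Length-2 vector `(subtype, direction)`, e.g.
#'   `c(1, "under")`.
#' @param seed Integer seed.
#' @return Character vector of `size` gene ids.
#' @export
gen_comparator_gene_list <- function(cohort, size, overlap_fraction,
                                     target = c(1, "under"), seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stopf("overlap_fraction must be in [0, 1]")
  }
  set_name <- sprintf("C%s_%s", target[[1]], target[[2]])
  markers <- cohort$planted_markers[[set_name]]
  if (is.null(markers)) stopf("no planted marker set named %s", set_name)
  n_overlap <- round(overlap_fraction * size)
  if (n_overlap > length(markers)) {
    stopf("overlap demand (%d genes) exceeds available markers in %s (%d)",
          n_overlap, set_name, length(markers))
  }
  non_markers <- setdiff(cohort$counts$gene_ids,
                         unlist(cohort$planted_markers, use.names = FALSE))
  if (size - n_overlap > length(non_markers)) {
    stopf("not enough non-marker genes (%d needed, %d available)",
          size - n_overlap, length(non_markers))
  }
  with_seed(seed, {
    chosen <- c(sample(markers, n_overlap),
                sample(non_markers, size - n_overlap))
    sample(chosen)
  })
}

#' Write a synthetic cohort to disk
#'
#' Counts as TSV (genes x samples), clinical table as CSV, planted marker
#' sets as GMT, and truth labels plus the generating configuration as a
#' JSON sidecar.
#'
#' @param cohort A [gen_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    clinical = file.path(dir, "clinical.csv"),
    markers = file.path(dir, "planted_markers.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_counts_tsv(cohort$counts, paths[["counts"]])
  utils::write.csv(cohort$clinical, paths[["clinical"]], row.names = FALSE)
  write_gmt(cohort$planted_markers, paths[["markers"]])
  jsonlite::write_json(
    list(truth = as.list(cohort$truth),
         config = unclass(cohort$config)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
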