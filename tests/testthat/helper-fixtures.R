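## Shared fixtures, computed lazily and cached for the whole test run.
## The "study-conditions" fixture is the generator's default cohort
## (strong planted effects) taken through the full discovery arm.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, value_fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- value_fn()
  .fixture_cache[[key]]
}

## discovery cohort (defaults, seed 7) through preprocess + consensus +
## signatures; the conditions fixed by the study design
discovery_fixture <- function() {
  memo("discovery", function() {
    cohort <- gen_cohort(cohort_config(seed = 7))
    kept <- mad_filter(normalize_counts(expression_filter(cohort$counts)))
    res <- discover_subtypes(kept, k_range = 2:8, n_resamples = 250, seed = 7)
    de <- all_pairwise_de(kept, res$labels)
    sigs <- derive_signatures(de)
    ## discovered cluster -> planted subtype (majority vote; exact here)
    map <- vapply(sort(unique(res$labels)), function(cl) {
      as.integer(names(which.max(
        table(cohort$truth[names(res$labels)[res$labels == cl]])
      )))
    }, integer(1))
    list(cohort = cohort, kept = kept, res = res, de = de, sigs = sigs,
         map = map)
  })
}

## independent cohort from the same generative truth (seed 13), scored
## against the discovered signatures
validation_fixture <- function() {
  memo("validation", function() {
    d <- discovery_fixture()
    cohort <- gen_cohort(cohort_config(seed = 13))
    vnorm <- normalize_counts(expression_filter(cohort$counts), quantile = TRUE)
    enrich <- ssgsea_enrich(vnorm$logexpr, d$sigs$sets, n_perm = 1000, seed = 5)
    calls <- classify_samples(enrich)
    list(cohort = cohort, enrich = enrich, calls = calls)
  })
}

## cohort with no planted expression effects, for classifier calibration
null_cohort_fixture <- function() {
  memo("null_cohort", function() {
    d <- discovery_fixture()
    cohort <- gen_cohort(cohort_config(seed = 99, log2_effect = 0))
    nnorm <- normalize_counts(expression_filter(cohort$counts), quantile = TRUE)
    enrich <- suppressWarnings(
      ssgsea_enrich(nnorm$logexpr, d$sigs$sets, n_perm = 1000, seed = 6)
    )
    list(cohort = cohort, calls = classify_samples(enrich))
  })
}

## wrap plain matrices as a normalized_matrix for unit tests
as_norm <- function(E, W = NULL) {
  if (is.null(rownames(E))) rownames(E) <- sprintf("g%03d", seq_len(nrow(E)))
  if (is.null(colnames(E))) colnames(E) <- sprintf("s%03d", seq_len(ncol(E)))
  W <- W %||% matrix(1, nrow(E), ncol(E), dimnames = dimnames(E))
  structure(
    list(logexpr = E, weights = W, kept_genes = rownames(E),
         trend = NULL, libsize = stats::setNames(rep(1e6, ncol(E)), colnames(E))),
    class = "normalized_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## standard-normal noise from a locally scoped seed
with_seed_noise <- function(n, seed) {
  set.seed(seed)
  stats::rnorm(n)
}

## two-group exponential survival data with a given hazard ratio
sim_two_group <- function(n, hr, base_rate = 0.02, censor_rate = 0.005,
                          admin = Inf, seed = 1) {
  set.seed(seed)
  grp <- stats::rbinom(n, 1, 0.5)
  tt <- stats::rexp(n, rate = base_rate * hr^grp)
  cens <- pmin(if (censor_rate > 0) stats::rexp(n, censor_rate) else Inf, admin)
  data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens), grp = grp)
}
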