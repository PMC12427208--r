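# sarclust

Transcriptomic subtype discovery and prognostic evaluation for soft-tissue
sarcoma expression cohorts.

High-grade soft-tissue sarcomas (dedifferentiated liposarcoma,
leiomyosarcoma, undifferentiated pleomorphic sarcoma) are histologically
heterogeneous but poorly stratified by histology alone. A recurring finding
in sarcoma transcriptomics is that unsupervised clustering of bulk RNA-seq
profiles reveals a small number of expression subtypes with distinct
prognoses. `sarclust` packages that analysis as a tested, reusable
pipeline:

1. **Preprocess** raw gene × sample counts: CPM expression filter,
   variance-stabilizing log-CPM with precision weights
   (`w = trend(fitted log2 count)^-4` from a lowess mean–variance fit),
   and a top-55% median-absolute-deviation feature filter.
2. **Discover subtypes** by resampled consensus clustering
   (average-linkage hierarchical clustering on `1 − Pearson` over
   resampled sample subsets). The cluster number k* is chosen where the
   marginal gain of the consensus CDF area `A(k)` collapses:
   `k* = argmax_k m(k)/m(k+1)` with `m(k) = A(k) − A(k−1)`.
3. **Derive signatures** `C1_over, C1_under, …, Ck_over, Ck_under` by
   pairwise weighted moderated-t differential expression
   (empirical-Bayes variance shrinkage
   `s̃² = (d₀s₀² + d s²)/(d₀ + d)`, BH-FDR per contrast) and
   same-direction intersection across all contrasts of a cluster.
4. **Classify external samples** by single-sample gene-set enrichment: an
   alpha-weighted running-sum score on the sample's gene ranking,
   standardized against a gene-permutation null (NES), BH-adjusted per
   sample across all scored sets; each sample gets the cluster of its most
   significant signature (q < 0.05) or stays unassigned.
5. **Evaluate prognosis** with in-package survival machinery: Kaplan–Meier
   and log-rank, Cox proportional hazards with Efron ties
   (Newton–Raphson, Wald 95% CIs on the hazard-ratio scale), Schoenfeld
   proportional-hazards diagnostics, sequential likelihood-ratio ANOVA,
   Harrell's C-index model comparisons, sub-stratification at a predicted
   5-year-OS threshold of 60%, and gene-list overlap / NES rank-correlation
   against external comparator signatures.

A negative-binomial cohort simulator with planted subtypes,
subtype-linked exponential survival, clinical covariates, a noisy external
risk score and controlled-overlap comparator gene lists makes the whole
pipeline testable offline.

## Worked example

Discover subtypes on a synthetic cohort, transfer the signatures to an
independent cohort from the same generative truth, and evaluate prognosis:

```r
library(sarclust)

cohort <- gen_cohort(cohort_config(seed = 7))
kept   <- mad_filter(normalize_counts(expression_filter(cohort$counts)))
disc   <- discover_subtypes(kept, k_range = 2:8, n_resamples = 250, seed = 7)
disc
#> consensus_result: k in {2,3,4,5,6,7,8}, 250 resamples
#>   selected k* = 4 (cluster sizes: 30, 30, 30, 30)
round(disc$A, 3)
#>     2     3     4     5     6     7     8
#> 0.379 0.630 0.756 0.761 0.766 0.772 0.777

sigs <- derive_signatures(all_pairwise_de(kept, disc$labels))
sigs
#> signature_set:
#>   C1_over: 40 genes
#>   C1_under: 40 genes
#>   ... (8 sets, 40 genes each)

val   <- gen_cohort(cohort_config(seed = 13))
vnorm <- normalize_counts(expression_filter(val$counts), quantile = TRUE)
enr   <- ssgsea_enrich(vnorm, sigs$sets, n_perm = 1000, seed = 5)
calls <- classify_samples(enr)
table(calls$assigned_cluster, useNA = "ifany")
#>  1  2  3  4
#> 30 30 30 30

clin <- merge(val$clinical, calls[, c("sample_id", "assigned_cluster")])
clin$cluster <- factor(clin$assigned_cluster)
cox_fit(clin, "os_months", "os_event", c("cluster", "age_years"))
#> cox_fit (efron ties): n = 120, events = 95, loglik -382.306 -> -363.706
#>                coef     HR lower95 upper95       se      z         p
#> cluster2  -0.159400 0.8526  0.4850  1.4990 0.287800 -0.554 0.5796000
#> cluster3   0.288500 1.3340  0.7616  2.3380 0.286100  1.008 0.3134000
#> cluster4  -1.445000 0.2358  0.1213  0.4584 0.339100 -4.261 0.0000204
#> age_years -0.009649 0.9904  0.9734  1.0080 0.008821 -1.094 0.2740000

compare_models(clin, list(cluster = "cluster",
                          risk_score = "risk_score_5yOS",
                          cluster_age = c("cluster", "age_years")))
#>         model   c_index n_events n_pairs    loglik
#> 1 cluster_age 0.6634299       95    6076 -363.7057
#> 2     cluster 0.6550362       95    6076 -364.3023
#> 3  risk_score 0.6484529       95    6076 -366.8229
```

Reading the output: the CDF-area curve climbs steeply to k = 4 and then
plateaus (gain 0.126 → 0.005), so the elbow picks four subtypes; the
recovered signature sets hold 40 genes each (the planted marker-block
size); all 120 external samples are classified, and the Cox model shows
the classified clusters carrying survival signal (cluster 4 here maps to
the low-hazard planted subtype, HR 0.24 vs cluster 1) that beats the
external risk score on apparent C-index.

`run_pipeline(pipeline_config(outdir = "out"))` chains all of the above and
persists every artifact (TSV/CSV/GMT/JSON, 10 significant digits,
byte-reproducible per seed). A thin CLI covering each stage ships at
`inst/cli/sarclust.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","sarclust.R",package="sarclust"))')" \
    simulate --outdir cohort/ --seed 7
```

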