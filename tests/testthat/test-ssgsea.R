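test_that("enrichment score matches the hand running sum", {
  expr <- c(a = 3, b = 2, c = 1)
  ## S = top gene, alpha = 0: running diffs (1, 1/2, 0), ES = 1.5
  expect_equal(ssgsea_score(expr, "a", alpha = 0), 1.5)
  ## reversed sample: the set gene is now bottom-ranked
  expect_equal(ssgsea_score(c(a = 1, b = 2, c = 3), "a", alpha = 0), -1.5)
  expect_error(ssgsea_score(expr, "zz"), "empty")
  expect_error(ssgsea_score(expr, c("a", "b", "c")), "all genes")
})

test_that("ES is a rank statistic: invariant to monotone transforms", {
  set.seed(11)
  expr <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  s <- sample(names(expr), 8)
  for (alpha in c(0, 0.25, 1)) {
    expect_equal(ssgsea_score(expr, s, alpha),
                 ssgsea_score(exp(expr), s, alpha))
    expect_equal(ssgsea_score(expr, s, alpha),
                 ssgsea_score(2 * expr + 7, s, alpha))
  }
})

test_that("at alpha 0 a set and its complement score opposite signs", {
  set.seed(12)
  for (i in 1:20) {
    N <- sample(4:10, 1)
    expr <- setNames(rnorm(N), sprintf("g%02d", 1:N))
    m <- sample(seq_len(N - 1), 1)
    s <- sample(names(expr), m)
    comp <- setdiff(names(expr), s)
    expect_equal(ssgsea_score(expr, s, alpha = 0),
                 -ssgsea_score(expr, comp, alpha = 0))
  }
})

test_that("permutation null gives calibrated p-values on random sets", {
  set.seed(13)
  E <- matrix(rnorm(400 * 5), 400, 5,
              dimnames = list(sprintf("g%03d", 1:400), sprintf("s%d", 1:5)))
  sets <- lapply(1:100, function(i) sample(rownames(E), 20))
  names(sets) <- sprintf("null%03d", 1:100)
  enr <- ssgsea_enrich(E, sets, n_perm = 1000, seed = 14)
  ## 500 (sample, set) null scores; empirical size of the 5% test
  expect_equal(nrow(enr), 500)
  expect_lt(abs(mean(enr$p < 0.05) - 0.05), 0.02)
})

test_that("enrichment is deterministic given the seed", {
  set.seed(15)
  E <- matrix(rnorm(100 * 4), 100, 4,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:4)))
  sets <- list(C1_over = rownames(E)[1:12], C1_under = rownames(E)[20:35])
  a <- ssgsea_enrich(E, sets, n_perm = 200, seed = 42)
  b <- ssgsea_enrich(E, sets, n_perm = 200, seed = 42)
  expect_identical(a, b)
  c2 <- ssgsea_enrich(E, sets, n_perm = 200, seed = 43)
  expect_false(identical(a$NES, c2$NES))
  expect_error(ssgsea_enrich(E, sets, n_perm = 50, seed = 1), ">= 100")
})

test_that("undersized sets are skipped with a warning", {
  set.seed(16)
  E <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%d", 1:4)))
  sets <- list(C1_over = rownames(E)[1:10], C2_over = c("zz1", "zz2"))
  expect_warning(enr <- ssgsea_enrich(E, sets, n_perm = 150, seed = 1),
                 "skipping")
  expect_setequal(unique(enr$set), "C1_over")
})

mk_enrich <- function(df) structure(df, class = c("enrichment_table", "data.frame"))

test_that("classification picks the most significant signature set", {
  enr <- mk_enrich(data.frame(
    sample_id = "s1",
    set = c("C1_over", "C1_under", "C2_over", "C2_under"),
    size = 10, ES = c(5, -1, 1, -1), NES = c(4, -0.5, 0.5, -0.5),
    p = c(1e-5, 0.6, 0.5, 0.6)
  ))
  out <- classify_samples(enr)
  expect_equal(out$assigned_cluster, 1L)
  expect_equal(out$winning_set, "C1_over")
  expect_true(out$sign_concordant)
  ## nothing significant: unassigned
  enr2 <- mk_enrich(transform(enr, p = c(0.5, 0.6, 0.5, 0.6)))
  out2 <- classify_samples(enr2)
  expect_true(is.na(out2$assigned_cluster))
  ## exact q tie: first set name in ascending order wins
  enr3 <- mk_enrich(data.frame(
    sample_id = "s1", set = c("C2_over", "C1_over"), size = 10,
    ES = c(3, 3), NES = c(3, 3), p = c(0.001, 0.001)
  ))
  expect_equal(classify_samples(enr3)$winning_set, "C1_over")
})

test_that("context sets enter the BH adjustment but never win", {
  enr <- mk_enrich(data.frame(
    sample_id = "s1",
    set = c("C1_over", "KEGG_A", "KEGG_B"),
    size = 10, ES = 1, NES = c(2.2, 4, 4),
    p = c(0.028, 1e-6, 1e-6)
  ))
  out <- classify_samples(enr)
  ## q(C1_over) = BH over 3 sets = 0.028 * 3 / 3 = 0.028 < 0.05 -> assigned
  expect_equal(out$assigned_cluster, 1L)
  expect_equal(out$winning_q, 0.028)
  ## without the significant context sets the BH rank changes nothing here,
  ## but a borderline p can lose significance when context dilutes it
  enr2 <- mk_enrich(data.frame(
    sample_id = "s1",
    set = c("C1_over", "KEGG_A", "KEGG_B"),
    size = 10, ES = 1, NES = c(2.2, 0.1, 0.1),
    p = c(0.028, 0.9, 0.95)
  ))
  out2 <- classify_samples(enr2)
  expect_true(is.na(out2$assigned_cluster))  # 0.028 * 3 / 1 = 0.084 > 0.05
})

test_that("sign concordance gate blocks anti-signature winners", {
  ## significant *positive* enrichment of an _under set
  enr <- mk_enrich(data.frame(
    sample_id = "s1", set = c("C1_under", "C2_over"), size = 10,
    ES = c(6, 2), NES = c(5, 2.4), p = c(1e-6, 0.016)
  ))
  lit <- classify_samples(enr)                     # literal rule: C1 wins
  expect_equal(lit$assigned_cluster, 1L)
  expect_false(lit$sign_concordant)
  con <- classify_samples(enr, require_sign_concordance = TRUE)
  expect_equal(con$assigned_cluster, 2L)           # concordant runner-up wins
})

test_that("classification is invariant to row order of the table", {
  v <- validation_fixture()
  enr <- v$enrich
  set.seed(17)
  shuf <- enr[sample(nrow(enr)), ]
  expect_equal(classify_samples(shuf)[order(classify_samples(shuf)$sample_id), ],
               v$calls[order(v$calls$sample_id), ], ignore_attr = TRUE)
})
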