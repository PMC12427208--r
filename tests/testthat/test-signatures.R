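test_that("moderated t equals the hand-evaluated shrinkage formula", {
  ## one gene, two groups of 3, unit weights, injected prior d0=4, s0^2=0.5
  E <- matrix(c(1.0, 1.4, 0.9, 2.1, 2.6, 2.2), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  labels <- setNames(rep(c("a", "b"), each = 3), colnames(E))
  de <- fit_moderated_de(as_norm(E), labels, c("b", "a"),
                         prior_df = 4, prior_var = 0.5)
  ma <- mean(E[1, 1:3]); mb <- mean(E[1, 4:6])
  s2 <- (sum((E[1, 1:3] - ma)^2) + sum((E[1, 4:6] - mb)^2)) / 4
  s2_post <- (4 * 0.5 + 4 * s2) / 8
  t_hand <- (mb - ma) / sqrt(s2_post * (1 / 3 + 1 / 3))
  expect_equal(de$logFC, mb - ma, tolerance = 1e-10)
  expect_equal(de$t_mod, t_hand, tolerance = 1e-10)
  expect_equal(de$p, 2 * pt(-abs(t_hand), df = 8), tolerance = 1e-10)
})

test_that("shrinkage limits behave as the formula dictates", {
  set.seed(6)
  E <- matrix(rnorm(40 * 8), 40, 8)
  labels <- rep(c("a", "b"), each = 4)
  norm <- as_norm(E)
  ## d0 -> Inf: posterior variance is exactly s0^2 for every gene,
  ## so t * sqrt(v) / logFC is constant across genes
  de_inf <- fit_moderated_de(norm, labels, c("a", "b"),
                             prior_df = Inf, prior_var = 0.7)
  ratio <- de_inf$logFC / de_inf$t_mod   # = sqrt(s0^2 * v), v constant here
  expect_equal(ratio, rep(ratio[1], 40), tolerance = 1e-9)
  expect_equal(ratio[1]^2 / (1 / 4 + 1 / 4), 0.7, tolerance = 1e-9)
  ## d0 = dg: posterior variance is the plain average (s0^2 + s^2) / 2
  de_eq <- fit_moderated_de(norm, labels, c("a", "b"),
                            prior_df = 6, prior_var = 0.7)
  v <- 1 / 4 + 1 / 4
  expect_equal(de_eq$t_mod,
               de_eq$logFC / sqrt((0.7 + de_eq$sigma2) / 2 * v),
               tolerance = 1e-9)
  ## d0 -> 0: moderated t approaches the ordinary two-sample t
  de_0 <- fit_moderated_de(norm, labels, c("a", "b"),
                           prior_df = 1e-6, prior_var = 0.7)
  t_ord <- de_0$logFC / sqrt(de_0$sigma2 * v)
  expect_equal(de_0$t_mod, t_ord, tolerance = 1e-4)
})

test_that("moderated DE agrees with limma on weighted data", {
  skip_if_not_installed("limma")
  set.seed(7)
  G <- 120; n <- 16
  E <- matrix(rnorm(G * n, sd = 0.7), G, n,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:n)))
  E[1:10, 9:16] <- E[1:10, 9:16] + 1.5
  W <- matrix(runif(G * n, 0.5, 2), G, n, dimnames = dimnames(E))
  labels <- rep(c("c1", "c2"), each = 8)
  de <- fit_moderated_de(as_norm(E, W), labels, c("c2", "c1"))
  design <- model.matrix(~0 + factor(labels))
  colnames(design) <- c("c1", "c2")
  fit <- limma::lmFit(E, design, weights = W)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(c2 - c1, levels = design))
  fit <- limma::eBayes(fit)
  expect_equal(de$logFC, unname(fit$coefficients[, 1]), tolerance = 1e-8)
  expect_equal(attr(de, "hyper")$d0, fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(de, "hyper")$s02, fit$s2.prior, tolerance = 1e-4)
  expect_equal(de$t_mod, unname(fit$t[, 1]), tolerance = 1e-6)
  expect_equal(de$p, unname(fit$p.value[, 1]), tolerance = 1e-6)
})

test_that("BH adjustment equals the hand step-up on known cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  ## q(i) = min_j>=i m p(j)/j, by hand for a scattered vector
  p <- c(0.005, 0.9, 0.04, 0.03)
  expect_equal(bh_adjust(p), c(0.02, 0.9, 0.0533333333333333, 0.0533333333333333))
  set.seed(8)
  x <- runif(50)
  q <- bh_adjust(x)
  expect_true(all(sort(q) >= sort(x)))
  expect_true(all(diff(sort(q)) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("swapping contrast orientation negates effects, keeps p-values", {
  set.seed(9)
  E <- matrix(rnorm(30 * 9), 30, 9)
  labels <- rep(c("a", "b", "c"), each = 3)
  norm <- as_norm(E)
  ab <- fit_moderated_de(norm, labels, c("a", "b"))
  ba <- fit_moderated_de(norm, labels, c("b", "a"))
  expect_equal(ab$logFC, -ba$logFC)
  expect_equal(ab$t_mod, -ba$t_mod)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$q, ba$q)
})

test_that("signature membership follows the all-contrasts intersection rule", {
  mk_de <- function(genes, lfc, q, contrast) {
    structure(data.frame(gene = genes, logFC = lfc, sigma2 = 1, df = 10,
                         t_mod = lfc, p = q, q = q),
              contrast = contrast, class = c("de_result", "data.frame"))
  }
  genes <- c("gUp", "gMixed", "gWeak")
  de <- list(
    mk_de(genes, lfc = c( 2,  2, 2), q = c(0.01, 0.01, 0.20), c("1", "2")),
    mk_de(genes, lfc = c( 2, -2, 2), q = c(0.01, 0.01, 0.01), c("1", "3")),
    mk_de(genes, lfc = c( 1,  1, 1), q = c(0.04, 0.04, 0.04), c("2", "3"))
  )
  sigs <- derive_signatures(de)
  ## gUp: significant and up against both other clusters
  expect_true("gUp" %in% sigs$sets$C1_over)
  ## gMixed: up vs one cluster, down vs the other -> excluded everywhere for C1
  expect_false("gMixed" %in% sigs$sets$C1_over)
  expect_false("gMixed" %in% sigs$sets$C1_under)
  ## gWeak: not significant in one contrast -> excluded
  expect_false("gWeak" %in% sigs$sets$C1_over)
  ## flipped orientation is handled: gUp is below clusters 1 and 2 in the
  ## 3-vs-others orientation, so it lands in C3_under
  expect_true("gUp" %in% sigs$sets$C3_under)
  expect_false("gMixed" %in% sigs$sets$C3_under)
  expect_false("gMixed" %in% sigs$sets$C3_over)
  expect_error(derive_signatures(de[1:2]), "missing contrast")
})

test_that("tightening the FDR threshold shrinks every signature", {
  d <- discovery_fixture()
  loose <- derive_signatures(d$de, q_threshold = 0.05)
  tight <- derive_signatures(d$de, q_threshold = 0.01)
  for (nm in names(loose$sets)) {
    expect_true(all(tight$sets[[nm]] %in% loose$sets[[nm]]))
  }
})

test_that("null data admits few genes into any signature", {
  ## no planted effects: expected admission fraction is bounded by the FDR
  ## threshold (checked with x2 slack over 20 replicates)
  frac <- vapply(1:20, function(s) {
    set.seed(100 + s)
    E <- matrix(rnorm(200 * 40), 200, 40,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:40)))
    labels <- rep(1:4, each = 10)
    ## iid data is exactly homoscedastic, so the variance-prior moment
    ## estimate legitimately falls back to its default (warning expected)
    sigs <- suppressWarnings(
      derive_signatures(all_pairwise_de(as_norm(E), labels)))
    length(unique(unlist(sigs$sets))) / 200
  }, numeric(1))
  expect_lte(mean(frac), 2 * 0.05)
})
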