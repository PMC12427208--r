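test_that("Kaplan-Meier estimator matches hand product-limit values", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  ## all censored: survival stays at 1
  km_c <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km_c$surv == 1))
  ## adding a censoring at 1.5 shrinks later risk sets:
  ## S(1) = 3/4, S(2) = 3/4 * 1/2 = 3/8, S(3) = 0
  km2 <- km_curve(c(1, 1.5, 2, 3), c(1, 0, 1, 1))
  expect_equal(km2$surv, c(3 / 4, 3 / 4, 3 / 8, 0))
  expect_equal(km_surv_at(km2, c(0.5, 1.7, 10)), c(1, 3 / 4, 0))
  expect_error(km_curve(c(0, 1), c(1, 1)), "positive")
})

test_that("KM curve agrees with survival::survfit and stays monotone", {
  skip_if_not_installed("survival")
  set.seed(18)
  tt <- round(rexp(80, 0.1), 1) + 0.1
  ev <- rbinom(80, 1, 0.6)
  km <- km_curve(tt, ev)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(km_surv_at(km, sf$time), sf$surv, tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 0))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
})

test_that("log-rank test matches survdiff and is rank-invariant", {
  skip_if_not_installed("survival")
  ## identical groups: no signal at all
  same <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  ## 6-subject toy against the independent implementation
  tt <- c(1, 3, 5, 2, 4, 6); ev <- c(1, 1, 0, 1, 1, 1)
  gg <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(tt, ev, gg)
  sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ gg)
  expect_equal(lr$chi2, sd_$chisq, tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  ## monotone time transform leaves the statistic unchanged
  lr12 <- logrank_test(tt * 12, ev, gg)
  expect_equal(lr12$chi2, lr$chi2)
  lr_sq <- logrank_test(tt^2, ev, gg)
  expect_equal(lr_sq$chi2, lr$chi2)
  ## three groups with ties, larger data
  set.seed(19)
  tt2 <- round(rexp(90, 0.05)) + 1
  ev2 <- rbinom(90, 1, 0.7)
  gg2 <- sample(c("x", "y", "z"), 90, replace = TRUE)
  lr3 <- logrank_test(tt2, ev2, gg2)
  sd3 <- survival::survdiff(survival::Surv(tt2, ev2) ~ gg2)
  expect_equal(lr3$chi2, sd3$chisq, tolerance = 1e-10)
  expect_equal(lr3$df, 2L)
  expect_error(logrank_test(tt, ev, rep("a", 6)), "2 groups")
  expect_error(logrank_test(tt, rep(0, 6), gg), "one event")
})

test_that("Cox fit reproduces survival::coxph for both tie methods", {
  skip_if_not_installed("survival")
  set.seed(20)
  n <- 200
  d <- data.frame(
    time = round(rexp(n, 0.05), 0) + 1,   # heavy ties
    event = rbinom(n, 1, 0.7),
    x1 = rnorm(n),
    grp = sample(c("a", "b", "c"), n, replace = TRUE)
  )
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(d, "time", "event", c("x1", "grp"), ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x1 + grp, data = d,
                           ties = ties)
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-8)
    expect_equal(unname(fit$loglik), unname(ref$loglik), tolerance = 1e-8)
  }
  ## factor expansion is reference-coded on the first sorted level
  expect_named(cox_fit(d, "time", "event", "grp")$coefficients,
               c("grpb", "grpc"))
  ## contract: fitted loglik never below the null loglik
  fit <- cox_fit(d, "time", "event", c("x1", "grp"))
  expect_gte(fit$loglik[["final"]], fit$loglik[["null"]])
  expect_true(all(fit$ci_lower <= fit$hr & fit$hr <= fit$ci_upper))
  expect_error(cox_fit(transform(d, event = 0), "time", "event", "x1"),
               "at least one event")
  expect_error(cox_fit(transform(d, x1 = 1), "time", "event", "x1"),
               "constant")
})

test_that("binary-covariate beta is antisymmetric under label swap", {
  d <- sim_two_group(300, hr = 2, seed = 22)
  f1 <- cox_fit(d, "time", "event", "grp")
  d2 <- transform(d, grp = 1 - grp)
  f2 <- cox_fit(d2, "time", "event", "grp")
  expect_equal(unname(f1$coefficients), -unname(f2$coefficients),
               tolerance = 1e-9)
})

test_that("PH score test matches cox.zph and detects reversing effects", {
  skip_if_not_installed("survival")
  set.seed(23)
  n <- 250
  d <- data.frame(time = rexp(n, 0.03), event = rbinom(n, 1, 0.8),
                  x1 = rnorm(n), x2 = runif(n))
  fit <- cox_fit(d, "time", "event", c("x1", "x2"))
  ph <- schoenfeld_ph_test(fit)
  ref <- survival::cox.zph(
    survival::coxph(survival::Surv(time, event) ~ x1 + x2, data = d),
    transform = "identity")
  expect_equal(ph$chi2[ph$covariate == "x1"], ref$table["x1", "chisq"],
               tolerance = 1e-6)
  expect_equal(ph$chi2[ph$covariate == "x2"], ref$table["x2", "chisq"],
               tolerance = 1e-6)
  expect_equal(ph$chi2[ph$covariate == "GLOBAL"], ref$table["GLOBAL", "chisq"],
               tolerance = 1e-6)
  ## power: covariate effect reverses sign at the median time
  set.seed(5)
  n <- 1000
  grp <- rbinom(n, 1, 0.5)
  lam0 <- 0.03; t0 <- log(2) / lam0
  t1 <- rexp(n, lam0 * ifelse(grp == 1, 3, 1))
  tt <- ifelse(t1 <= t0, t1, t0 + rexp(n, lam0 * ifelse(grp == 1, 1 / 3, 1)))
  dd <- data.frame(time = tt, event = 1L, grp = grp)
  ph_pow <- schoenfeld_ph_test(cox_fit(dd, "time", "event", "grp"))
  expect_lt(ph_pow$p[ph_pow$covariate == "grp"], 0.01)
  ## single event is rejected
  d1 <- data.frame(time = c(1, 2, 3), event = c(1, 0, 0), x = c(1, 0, 1))
  expect_error(schoenfeld_ph_test(cox_fit(d1, "time", "event", "x")),
               "2 events")
})

test_that("sequential Cox ANOVA telescopes and gets factor df right", {
  set.seed(24)
  n <- 180
  d <- data.frame(
    time = rexp(n, 0.04), event = rbinom(n, 1, 0.75),
    grp = sample(c("a", "b", "c", "d"), n, replace = TRUE),
    age = rnorm(n, 60, 10), noise = rnorm(n)
  )
  an <- cox_anova(d, "time", "event",
                  blocks = list(grp = "grp", age = "age", noise = "noise"))
  expect_equal(an$df, c(3L, 1L, 1L))      # 4-level factor adds k - 1
  full <- cox_fit(d, "time", "event", c("grp", "age", "noise"))
  expect_equal(sum(an$chi2),
               2 * (full$loglik[["final"]] - full$loglik[["null"]]),
               tolerance = 1e-8)
})

test_that("null-covariate LRT p-values are uniform", {
  pvals <- vapply(1:200, function(s) {
    d <- sim_two_group(100, hr = 2, seed = 400 + s)
    set.seed(800 + s)
    d$noise <- rnorm(nrow(d))
    an <- cox_anova(d, "time", "event", blocks = list(grp = "grp", noise = "noise"))
    an$p[an$block == "noise"]
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("concordance matches brute force and behaves at the extremes", {
  ## perfectly anti-ordered risk, no censoring
  tt <- c(5, 4, 3, 2, 1); risk <- c(1, 2, 3, 4, 5)
  expect_equal(concordance_index(tt, rep(1, 5), risk)$c_index, 1)
  ## constant score
  expect_equal(concordance_index(tt, rep(1, 5), rep(2, 5))$c_index, 0.5)
  ## 8-subject censored fixture vs exhaustive pair enumeration
  tt8 <- c(2, 4, 4, 6, 7, 9, 12, 15)
  ev8 <- c(1, 1, 0, 1, 0, 1, 0, 1)
  rk8 <- c(8, 3, 5, 3, 1, 4, 2, 1)
  got <- concordance_index(tt8, ev8, rk8)
  conc <- disc <- tied <- 0
  for (i in 1:8) for (j in 1:8) {
    if (ev8[i] == 1 && tt8[i] < tt8[j]) {
      if (rk8[i] > rk8[j]) conc <- conc + 1
      else if (rk8[i] < rk8[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  expect_equal(got$concordant, conc)
  expect_equal(got$discordant, disc)
  expect_equal(got$tied, tied)
  expect_equal(got$c_index, (conc + 0.5 * tied) / (conc + disc + tied))
  ## reversing the score reflects C around 1/2 (no score ties here)
  tt5 <- c(1, 2, 3, 4, 5); rk5 <- c(3, 5, 1, 4, 2)
  c_pos <- concordance_index(tt5, rep(1, 5), rk5)$c_index
  c_neg <- concordance_index(tt5, rep(1, 5), -rk5)$c_index
  expect_equal(c_pos, 1 - c_neg)
  expect_error(concordance_index(c(1, 1), c(0, 0), c(1, 2)), "comparable")
})
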