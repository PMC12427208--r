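#' Cox proportional-hazards model with Efron tie handling
#'
#' Newton-Raphson maximization of the partial likelihood with Efron
#' (default) or Breslow handling of tied event times, with step-halving on
#' any likelihood decrease. Convergence is declared when the largest score
#' component is below 1e-9 or the relative log-likelihood change is below
#' 1e-12; non-convergence after 50 iterations is an error, never a silent
#' return. Factor covariates are expanded to reference-coded indicators
#' with the first sorted level as reference. Confidence intervals are Wald
#' intervals on the log-hazard scale.
#'
#' @param data Data frame of survival records.
#' @param time,event Column names of the follow-up time (months) and 0/1
#'   event indicator.
#' @param covariates Character vector of covariate column names (numeric,
#'   factor/character or logical).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: coefficients, `se`, `hr`,
#'   `ci_lower`/`ci_upper` (95%, hazard-ratio scale), per-coefficient Wald
#'   `z`/`p`, `loglik` (`c(null, final)`), `score_test` (chi2/df/p at beta
#'   = 0), variance matrix `var`, `linear_predictor`, iteration count and
#'   the design internals used by [schoenfeld_ph_test()].
#' @export
cox_fit <- function(data, time, event, covariates,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  t_ <- data[[time]]
  d_ <- data[[event]]
  if (is.null(t_) || is.null(d_)) stopf("time/event column missing")
  check_surv(t_, d_)
  if (sum(d_) < 1) stopf("Cox model needs at least one event")
  X <- build_design(data, covariates)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)

  p <- ncol(Xc)
  beta <- numeric(p)
  cur <- cox_partial(beta, t_, d_, Xc, ties)
  loglik0 <- cur$loglik
  score0 <- cur$score
  info0 <- cur$info
  iter <- 0L
  converged <- FALSE
  for (it in seq_len(50L)) {
    iter <- it
    if (max(abs(cur$score)) < 1e-9) { converged <- TRUE; break }
    delta <- solve(cur$info, cur$score)
    step <- 1
    repeat {
      cand_beta <- beta + step * delta
      cand <- cox_partial(cand_beta, t_, d_, Xc, ties)
      if (is.finite(cand$loglik) && cand$loglik >= cur$loglik - 1e-12) break
      step <- step / 2
      if (step < 1e-10) stopf("Cox fit failed: step-halving exhausted (possible separation)")
    }
    rel_change <- abs(cand$loglik - cur$loglik) /
      max(1, abs(cand$loglik))
    beta <- cand_beta
    cur <- cand
    if (rel_change < 1e-12) { converged <- TRUE; break }
  }
  if (!converged && max(abs(cur$score)) >= 1e-9) {
    stopf("Cox fit did not converge in 50 iterations (max |score| = %g)",
          max(abs(cur$score)))
  }
  V <- solve(cur$info)
  se <- sqrt(diag(V))
  z <- beta / se
  names(beta) <- names(se) <- colnames(X)
  score_chi2 <- drop(t(score0) %*% solve(info0, score0))
  structure(
    list(
      coefficients = beta, se = se, hr = exp(beta),
      ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
      z = z, p = 2 * stats::pnorm(-abs(z)),
      loglik = c(null = loglik0, final = cur$loglik),
      score_test = list(chi2 = score_chi2, df = p,
                        p = stats::pchisq(score_chi2, p, lower.tail = FALSE)),
      var = V, info = cur$info,
      linear_predictor = drop(Xc %*% beta),
      n = length(t_), n_events = sum(d_), iter = iter, ties = ties,
      time = t_, event = d_, X = Xc, xnames = colnames(X)
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties): n = %d, events = %d, loglik %.3f -> %.3f\n",
              x$ties, x$n, x$n_events, x$loglik[1], x$loglik[2]))
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    lower95 = x$ci_lower, upper95 = x$ci_upper,
                    se = x$se, z = x$z, p = x$p)
  print(signif(tab, 4))
  invisible(x)
}

## reference-coded design matrix; errors on constant covariates
build_design <- function(data, covariates) {
  if (!length(covariates)) stopf("no covariates supplied")
  cols <- list()
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.null(x)) stopf("covariate column not found: %s", cv)
    if (is.numeric(x)) {
      if (stats::sd(x) == 0) stopf("constant covariate: %s", cv)
      cols[[cv]] <- matrix(x, dimnames = list(NULL, cv))
    } else {
      f <- factor(as.character(x), levels = sort(unique(as.character(x))))
      if (nlevels(f) < 2L) stopf("constant covariate: %s", cv)
      ind <- vapply(levels(f)[-1L], function(l) as.numeric(f == l),
                    numeric(length(f)))
      if (!is.matrix(ind)) ind <- matrix(ind, ncol = 1L)
      colnames(ind) <- paste0(cv, levels(f)[-1L])
      cols[[cv]] <- ind
    }
  }
  do.call(cbind, cols)
}

## partial log-likelihood, score and information at beta (Efron/Breslow)
cox_partial <- function(beta, time, event, X, ties) {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)        # guard against overflow; cancels in ratios
  th <- exp(eta)
  ord <- order(time, decreasing = TRUE)
  ut_desc <- sort(unique(time[event == 1]), decreasing = TRUE)
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  ptr <- 1L
  n <- length(time)
  for (t_ev in ut_desc) {
    while (ptr <= n && time[ord[ptr]] >= t_ev) {
      i <- ord[ptr]
      S0 <- S0 + th[i]
      S1 <- S1 + th[i] * X[i, ]
      S2 <- S2 + th[i] * tcrossprod(X[i, ])
      ptr <- ptr + 1L
    }
    D <- which(time == t_ev & event == 1)
    d <- length(D)
    thD <- th[D]
    XD <- X[D, , drop = FALSE]
    S0D <- sum(thD)
    S1D <- colSums(thD * XD)
    S2D <- crossprod(XD, thD * XD)
    ll <- ll + sum(eta[D])
    U <- U + colSums(XD)
    for (l in seq_len(d) - 1L) {
      r <- if (ties == "efron") l / d else 0
      phi <- S0 - r * S0D
      xb <- (S1 - r * S1D) / phi
      ll <- ll - log(phi)
      U <- U - xb
      I <- I + (S2 - r * S2D) / phi - tcrossprod(xb)
    }
  }
  ## the max-eta shift cancels exactly: each tie group contributes d shifted
  ## eta terms and d shifted log(phi) terms, so ll is the true partial loglik
  list(loglik = ll, score = U, info = I)
}

#' Grambsch-Therneau test of proportional hazards
#'
#' Scaled Schoenfeld residuals at each event time are tested for linear
#' association with a transform of time (identity by default, optionally
#' the complement of the pooled KM curve). Reported per covariate:
#' correlation `rho` between the time transform and the scaled residuals,
#' score chi-square and p-value; plus a global chi-square with df = number
#' of coefficients. Small p-values indicate a time-varying effect, i.e., a
#' proportional-hazards violation.
#'
#' @param fit A [cox_fit()].
#' @param transform `"identity"` (default) or `"km"`.
#' @return Data.frame with rows per covariate plus `GLOBAL`: columns
#'   `rho` (`NA` for the global row), `chi2`, `df`, `p`.
#' @export
schoenfeld_ph_test <- function(fit, transform = c("identity", "km")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  time <- fit$time; event <- fit$event; X <- fit$X
  K <- sum(event == 1)
  if (K < 2) stopf("Schoenfeld test needs at least 2 events")
  res <- schoenfeld_residuals(fit)        # K x p, ordered by event time
  ev_times <- attr(res, "event_times")
  Vk <- attr(res, "info_k")               # per-event information, p x p x K
  g <- if (transform == "identity") ev_times else {
    km <- km_curve(time, event)
    1 - km_surv_at(km, ev_times)
  }
  w <- g - mean(g)
  p <- ncol(X)
  U <- drop(crossprod(res, w))            # p-vector score for beta(t) slope
  ## exact score-test variance: sum w^2 V_k minus the projection onto the
  ## total information (the average-information shortcut is conservative
  ## when risk-set information varies over time)
  I_tot <- apply(Vk, c(1, 2), sum)
  A <- apply(Vk * rep(w, each = p * p), c(1, 2), sum)
  B <- apply(Vk * rep(w^2, each = p * p), c(1, 2), sum)
  Vs <- B - A %*% solve(I_tot, A)
  chi2_cov <- U^2 / diag(Vs)
  scaled <- res %*% fit$var                # proportional to scaled residuals
  rho <- vapply(seq_len(p), function(j) stats::cor(w, scaled[, j]), numeric(1))
  chi2_global <- drop(t(U) %*% solve(Vs, U))
  out <- data.frame(
    covariate = c(fit$xnames, "GLOBAL"),
    rho = c(rho, NA),
    chi2 = c(chi2_cov, chi2_global),
    df = c(rep(1L, p), p),
    p = c(stats::pchisq(chi2_cov, 1, lower.tail = FALSE),
          stats::pchisq(chi2_global, p, lower.tail = FALSE)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "transform") <- transform
  out
}

## Efron-adjusted Schoenfeld residuals, one row per event, ordered by time;
## each death in a tie group gets x_i minus the tie-averaged risk-set mean.
## Also returns the per-event information contribution V_k (tie-averaged),
## needed by the exact proportional-hazards score test.
schoenfeld_residuals <- function(fit) {
  time <- fit$time; event <- fit$event; X <- fit$X
  beta <- fit$coefficients
  eta <- drop(X %*% beta); eta <- eta - max(eta)
  th <- exp(eta)
  ties <- fit$ties
  ord <- order(time, decreasing = TRUE)
  ut_desc <- sort(unique(time[event == 1]), decreasing = TRUE)
  p <- ncol(X)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  ptr <- 1L; n <- length(time)
  rows <- list(); tlist <- list(); vlist <- list()
  for (t_ev in ut_desc) {
    while (ptr <= n && time[ord[ptr]] >= t_ev) {
      i <- ord[ptr]
      S0 <- S0 + th[i]
      S1 <- S1 + th[i] * X[i, ]
      S2 <- S2 + th[i] * tcrossprod(X[i, ])
      ptr <- ptr + 1L
    }
    D <- which(time == t_ev & event == 1)
    d <- length(D)
    S0D <- sum(th[D])
    S1D <- colSums(th[D] * X[D, , drop = FALSE])
    S2D <- crossprod(X[D, , drop = FALSE], th[D] * X[D, , drop = FALSE])
    xbar <- numeric(p)
    Vbar <- matrix(0, p, p)
    for (l in seq_len(d) - 1L) {
      r <- if (ties == "efron") l / d else 0
      phi <- S0 - r * S0D
      xb <- (S1 - r * S1D) / phi
      xbar <- xbar + xb / d
      Vbar <- Vbar + ((S2 - r * S2D) / phi - tcrossprod(xb)) / d
    }
    rows[[length(rows) + 1L]] <- sweep(X[D, , drop = FALSE], 2, xbar)
    tlist[[length(tlist) + 1L]] <- rep(t_ev, d)
    vlist[[length(vlist) + 1L]] <- replicate(d, Vbar)
  }
  res <- do.call(rbind, rev(rows))
  out_t <- unlist(rev(tlist))
  Vk <- array(unlist(rev(vlist)), dim = c(p, p, length(out_t)))
  o <- order(out_t)
  res <- res[o, , drop = FALSE]
  attr(res, "event_times") <- out_t[o]
  attr(res, "info_k") <- Vk[, , o, drop = FALSE]
  res
}

#' Sequential likelihood-ratio decomposition of a Cox model
#'
#' Adds the covariate blocks left to right and reports, per block, the
#' likelihood-ratio chi-square against the previous model, with df equal
#' to the number of added coefficients (analysis-of-deviance table for the
#' Cox model).
#'
#' @param data,time,event As in [cox_fit()].
#' @param blocks Named list of covariate vectors; block i is tested given
#'   blocks 1..i-1.
#' @param ties Tie handling, as in [cox_fit()].
#' @return Data.frame with per-block `df`, `chi2`, `p` and the cumulative
#'   `loglik`; the null-model log-likelihood is in the first row's
#'   `loglik_prev`.
#' @export
cox_anova <- function(data, time, event, blocks, ties = "efron") {
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stopf("blocks must be named")
  }
  lls <- numeric(length(blocks))
  dfs <- integer(length(blocks))
  covs <- character(0)
  ll_prev <- NULL
  rows <- list()
  for (i in seq_along(blocks)) {
    covs <- c(covs, blocks[[i]])
    fit <- cox_fit(data, time, event, covs, ties = ties)
    if (is.null(ll_prev)) ll_prev <- fit$loglik[["null"]]
    df_i <- length(fit$coefficients) - sum(vapply(rows, function(r) r$df, numeric(1)))
    chi2 <- 2 * (fit$loglik[["final"]] - ll_prev)
    rows[[i]] <- data.frame(
      block = names(blocks)[i], df = df_i, chi2 = chi2,
      p = stats::pchisq(chi2, df_i, lower.tail = FALSE),
      loglik_prev = ll_prev, loglik = fit$loglik[["final"]],
      stringsAsFactors = FALSE
    )
    ll_prev <- fit$loglik[["final"]]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
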