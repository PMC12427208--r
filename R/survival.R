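#' Kaplan-Meier product-limit curve
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Object of class `km_curve`: data.frame with one row per
#'   distinct observed time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`), right-continuous survival estimate.
#' @export
km_curve <- function(time, event) {
  check_surv(time, event)
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    data.frame(time = ut, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, surv = surv),
    class = c("km_curve", "data.frame"), n = length(time)
  )
}

check_surv <- function(time, event) {
  if (!length(time)) stopf("need at least one record")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stopf("times must be finite and positive")
  }
  if (!all(event %in% c(0, 1))) stopf("event indicator must be 0/1")
  if (length(time) != length(event)) stopf("time and event lengths differ")
  invisible(TRUE)
}

#' Survival probability at given times from a KM curve
#'
#' @param km A [km_curve()].
#' @param t Times at which to evaluate the right-continuous step function.
#' @return Vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Median survival time from a KM curve
#'
#' Smallest observed time at which the survival estimate drops to 0.5 or
#' below; `NA` if the curve never reaches 0.5.
#'
#' @param km A [km_curve()].
#' @return A single time (or `NA`).
#' @export
km_median <- function(km) {
  i <- which(km$surv <= 0.5)
  if (!length(i)) NA_real_ else km$time[min(i)]
}

#' @export
plot.km_curve <- function(x, ..., xlab = "time", ylab = "survival") {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

#' Log-rank test for survival differences between groups
#'
#' Observed-minus-expected events over the pooled distinct event times
#' with the hypergeometric variance; the chi-square statistic uses the
#' covariance matrix of g-1 groups, df = #groups - 1.
#'
#' @param time,event Survival data (see [km_curve()]).
#' @param group Group label per record (>= 2 observed groups).
#' @return List with `chi2`, `df`, `p`, `observed`, `expected` (per
#'   group).
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- factor(group)
  g <- nlevels(group)
  if (g < 2L) stopf("log-rank test needs at least 2 groups")
  if (sum(event) < 1) stopf("log-rank test needs at least one event")
  ut <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(g), levels(group))
  V <- matrix(0, g, g, dimnames = list(levels(group), levels(group)))
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1)
    n_tg <- vapply(levels(group), function(l) sum(at_risk & group == l),
                   numeric(1))
    d_tg <- vapply(levels(group), function(l) {
      sum(time == t & event == 1 & group == l)
    }, numeric(1))
    O <- O + d_tg
    E <- E + d_t * n_tg / n_t
    if (n_t > 1) {
      frac <- n_tg / n_t
      V_t <- d_t * (n_t - d_t) / (n_t - 1) *
        (diag(frac, g) - tcrossprod(frac))
      V <- V + V_t
    }
  }
  om <- (O - E)[-g]
  Vi <- V[-g, -g, drop = FALSE]
  chi2 <- tryCatch(
    drop(t(om) %*% solve(Vi, om)),
    error = function(e) {
      sv <- svd(Vi)
      pos <- sv$d > max(sv$d) * 1e-10
      drop(t(om) %*% sv$v[, pos, drop = FALSE] %*%
             ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE])) %*% om)
    }
  )
  df <- g - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Harrell's concordance index
#'
#' Over all comparable pairs (the earlier time is an event), the fraction
#' in which the higher risk score belongs to the earlier event; tied
#' scores count 1/2. Higher score must mean worse prognosis.
#'
#' @param time,event Survival data (see [km_curve()]).
#' @param risk Risk score per record (higher = worse).
#' @return List with `c_index`, `n_pairs`, `concordant`, `discordant`,
#'   `tied`.
#' @export
concordance_index <- function(time, event, risk) {
  check_surv(time, event)
  if (length(risk) != length(time)) stopf("risk must match the records")
  usable <- outer(time, time, "<") & (event == 1)
  n_pairs <- sum(usable)
  if (n_pairs == 0) stopf("no comparable pairs")
  conc <- sum(usable & outer(risk, risk, ">"))
  tied <- sum(usable & outer(risk, risk, "=="))
  disc <- n_pairs - conc - tied
  list(c_index = (conc + 0.5 * tied) / n_pairs, n_pairs = n_pairs,
       concordant = conc, discordant = disc, tied = tied)
}
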