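#' Kaplan-Meier estimate with Greenwood variance and median CI
#'
#' Product-limit estimator per group. The survival-curve confidence band
#' uses the log(-log) transform with Greenwood variance; the median and its
#' 95% CI follow the band-inversion construction: the median is the smallest
#' time with `S(t) <= 0.5`, its lower (upper) confidence limit the smallest
#' time at which the lower (upper) band reaches 0.5. Limits never reached
#' within follow-up are `NA` ("not reached").
#'
#' @param time positive times.
#' @param event 0/1 indicators.
#' @param group optional group labels; one curve per level.
#' @return a `km_curve` (single group) or named list of them: each has
#'   `time` (event times), `n_risk`, `n_event`, `surv`, `greenwood_var`,
#'   `lower`, `upper`, `median`, `median_lower`, `median_upper`, `n`,
#'   `n_events`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (is.null(group)) return(km_one(time, event))
  stopifnot(length(group) == length(time))
  out <- lapply(split(seq_along(time), group), function(idx) {
    km_one(time[idx], event[idx])
  })
  out
}

km_one <- function(time, event) {
  if (any(!is.finite(time) | time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  if (!length(ut)) {
    out <- list(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                surv = numeric(0), greenwood_var = numeric(0),
                lower = numeric(0), upper = numeric(0),
                median = NA_real_, median_lower = NA_real_,
                median_upper = NA_real_, n = n, n_events = 0L)
    class(out) <- "km_curve"
    return(out)
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  frac <- 1 - n_event / n_risk
  surv <- cumprod(frac)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gw_term <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), NA)
  gw <- surv^2 * cumsum(ifelse(is.na(gw_term), 0, gw_term))
  # log(-log) band
  ok <- surv > 0 & surv < 1
  se_cll <- rep(NA_real_, length(surv))
  se_cll[ok] <- sqrt(gw[ok]) / (surv[ok] * abs(log(surv[ok])))
  lower <- upper <- surv
  lower[ok] <- surv[ok]^exp(1.96 * se_cll[ok])
  upper[ok] <- surv[ok]^exp(-1.96 * se_cll[ok])
  lower[surv == 0] <- 0
  upper[surv == 0] <- 0
  first_at_or_below <- function(v, cut = 0.5) {
    i <- which(!is.na(v) & v <= cut)
    if (length(i)) ut[min(i)] else NA_real_
  }
  out <- list(time = ut, n_risk = n_risk, n_event = n_event, surv = surv,
              greenwood_var = gw, lower = lower, upper = upper,
              median = first_at_or_below(surv),
              median_lower = first_at_or_below(lower),
              median_upper = first_at_or_below(upper),
              n = n, n_events = sum(event))
  class(out) <- "km_curve"
  out
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else sprintf("%.2f", x$median)
  lo <- if (is.na(x$median_lower)) "NR" else sprintf("%.2f", x$median_lower)
  hi <- if (is.na(x$median_upper)) "NR" else sprintf("%.2f", x$median_upper)
  cat(sprintf("KM curve: n = %d, events = %d, median = %s (95%% CI %s-%s)\n",
              x$n, x$n_events, med, lo, hi))
  invisible(x)
}

#' Log-rank test
#'
#' Unweighted K-sample log-rank chi-square with `K - 1` degrees of freedom,
#' built from the observed-minus-expected event counts and the
#' hypergeometric variance at every event time.
#'
#' @param time,event survival outcome.
#' @param group group labels (>= 2 levels).
#' @return a `logrank_result`: `statistic`, `df`, `p`, `observed`,
#'   `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  levs <- levels(droplevels(group))
  K <- length(levs)
  if (K < 2L) stop("log-rank test needs at least two groups")
  check_survival_inputs(time, event)
  g <- match(as.character(group), levs)
  ut <- sort(unique(time[event == 1]))
  O <- E <- numeric(K)
  V <- matrix(0, K, K)
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1)
    n_k <- vapply(seq_len(K), function(k) sum(at_risk & g == k), numeric(1))
    d_k <- vapply(seq_len(K),
                  function(k) sum(time == t & event == 1 & g == k), numeric(1))
    O <- O + d_k
    E <- E + n_k * d_t / n_t
    if (n_t > 1) {
      cc <- d_t * (n_t - d_t) / (n_t - 1)
      pk <- n_k / n_t
      # V_kl = cc * (p_k delta_kl - p_k p_l)
      V <- V + cc * (diag(pk, nrow = K) - tcrossprod(pk))
    }
  }
  idx <- seq_len(K - 1L)
  om <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(om) %*% solve(Vi, om)), error = function(e) 0)
  out <- list(statistic = stat, df = K - 1L,
              p = stats::pchisq(stat, df = K - 1L, lower.tail = FALSE),
              observed = setNames(O, levs), expected = setNames(E, levs))
  class(out) <- "logrank_result"
  out
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Post hoc power for a two-group survival comparison
#'
#' Schoenfeld approximation:
#' `power = Phi(|log HR| * sqrt(d * p * (1 - p)) - z_{1 - alpha/2})`,
#' with `d` observed events and `p` the fraction in one group.
#'
#' @param hr hazard ratio (> 0).
#' @param n_events observed number of events (> 0).
#' @param group_fraction fraction of subjects in one group, in (0, 1).
#' @param alpha two-sided significance level.
#' @return power in \[0, 1\].
#' @export
posthoc_power <- function(hr, n_events, group_fraction = 0.5, alpha = 0.05) {
  stopifnot(hr > 0, group_fraction > 0, group_fraction < 1)
  if (n_events <= 0) stop("n_events must be positive")
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(abs(log(hr)) *
                 sqrt(n_events * group_fraction * (1 - group_fraction)) - z)
}
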