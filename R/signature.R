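new_risk_signature <- function(features, coefficients, cutoff, ties_method,
                               created_from = "training", fit = NULL) {
  stopifnot(length(features) == length(coefficients))
  out <- list(features = as.character(features),
              coefficients = setNames(as.numeric(coefficients),
                                      as.character(features)),
              cutoff = as.numeric(cutoff),
              ties_method = ties_method,
              created_from = created_from,
              fit = fit)
  class(out) <- "risk_signature"
  out
}

#' @export
print.risk_signature <- function(x, ...) {
  cat("Risk signature:\n")
  for (f in x$features) {
    cat(sprintf("  %-20s %+.4f\n", f, x$coefficients[[f]]))
  }
  cat(sprintf("  cutoff (training median): %.4f\n", x$cutoff))
  invisible(x)
}

#' Fit a risk signature by unpenalized Cox refit
#'
#' Refits an ordinary (unpenalized) Cox model on the selected features in
#' the training cohort; the resulting coefficients define the linear risk
#' score, and the exact median of the training risk scores becomes the
#' dichotomization cutoff used for every cohort (for even n the two middle
#' order statistics are averaged).
#'
#' @param expr features x samples expression matrix (training cohort).
#' @param clinical matching `clinical_cohort`.
#' @param features ordered feature ids (subset of `rownames(expr)`).
#' @param ties ties method for the refit.
#' @param created_from free-text provenance label stored in the signature.
#' @return a `risk_signature`: `features`, `coefficients`, `cutoff`,
#'   `ties_method`, `created_from`, and the underlying `cox_fit` in `$fit`.
#' @export
fit_signature <- function(expr, clinical, features, ties = "breslow",
                          created_from = "training") {
  miss <- setdiff(features, rownames(expr))
  if (length(miss)) stop("feature(s) absent from expression matrix: ",
                         paste(miss, collapse = ", "))
  ids <- intersect(colnames(expr), clinical$sample_id)
  if (!length(ids)) stop("no overlapping sample ids")
  cl <- clinical[match(ids, clinical$sample_id), ]
  X <- t(expr[features, ids, drop = FALSE])
  fit <- fit_cox(cl$pfs_months, cl$event, X, ties = ties)
  scores <- drop(X %*% fit$coefficients)
  new_risk_signature(features, fit$coefficients,
                     cutoff = stats::median(scores),
                     ties_method = ties, created_from = created_from,
                     fit = fit)
}

#' Linear risk score
#'
#' `score_i = sum_j beta_j * x_{j,i}` over the signature features.
#'
#' @param signature a `risk_signature`.
#' @param expr features x samples matrix (or named vector for one patient)
#'   containing every signature feature.
#' @return named numeric vector of per-sample scores.
#' @export
risk_score <- function(signature, expr) {
  stopifnot(inherits(signature, "risk_signature"))
  if (is.null(dim(expr))) expr <- matrix(expr, ncol = 1,
                                         dimnames = list(names(expr), "sample"))
  miss <- setdiff(signature$features, rownames(expr))
  if (length(miss)) stop("missing feature value(s): ",
                         paste(miss, collapse = ", "))
  sub <- expr[signature$features, , drop = FALSE]
  if (anyNA(sub)) {
    bad <- signature$features[apply(is.na(sub), 1L, any)]
    stop("missing feature value(s): ", paste(bad, collapse = ", "))
  }
  drop(crossprod(sub, signature$coefficients))
}

#' Dichotomize risk scores at a cutoff
#'
#' Scores strictly above the cutoff are `high` risk; scores at or below it
#' are `low` (a patient attaining the training median lands in the low-risk
#' group). Validation cohorts must be classified with the TRAINING cutoff.
#'
#' @param scores named numeric vector of risk scores.
#' @param cutoff finite numeric cutoff (training-median by convention).
#' @return a `risk_assignment` data frame: `sample_id`, `score`, `group`
#'   (factor low/high).
#' @export
classify_risk <- function(scores, cutoff) {
  stopifnot(is.finite(cutoff), all(is.finite(scores)))
  out <- data.frame(
    sample_id = names(scores) %||% as.character(seq_along(scores)),
    score = as.numeric(scores),
    group = factor(ifelse(scores > cutoff, "high", "low"),
                   levels = c("low", "high")),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("risk_assignment", "data.frame")
  out
}

#' Kaplan-Meier and log-rank evaluation by risk group
#'
#' @param assignment a `risk_assignment`.
#' @param clinical matching `clinical_cohort`.
#' @return list with `km` (named list of `km_curve`, low/high), `logrank`
#'   (a `logrank_result`), and `n` per group.
#' @export
evaluate_km_by_risk <- function(assignment, clinical) {
  m <- merge(as.data.frame(assignment),
             as.data.frame(clinical)[, c("sample_id", "pfs_months", "event")],
             by = "sample_id")
  if (!nrow(m)) stop("no overlapping sample ids")
  if (any(table(m$group) == 0)) stop("both risk groups must be non-empty")
  list(km = km_estimate(m$pfs_months, m$event, m$group),
       logrank = logrank_test(m$pfs_months, m$event, m$group),
       n = table(m$group))
}

#' Response-by-risk contingency table
#'
#' Cross-tabulates best-response category against risk group, collapsing
#' CR and PR into one level as is conventional for response tables.
#'
#' @param assignment a `risk_assignment`.
#' @param clinical `clinical_cohort` with a `response` column.
#' @return integer matrix, rows `CR+PR`/`SD`/`PD`, columns `low`/`high`.
#' @export
response_by_risk <- function(assignment, clinical) {
  if (!"response" %in% colnames(clinical)) stop("clinical table lacks 'response'")
  m <- merge(as.data.frame(assignment),
             as.data.frame(clinical)[, c("sample_id", "response")],
             by = "sample_id")
  m <- m[!is.na(m$response), ]
  cat3 <- factor(ifelse(m$response %in% c("CR", "PR"), "CR+PR", m$response),
                 levels = c("CR+PR", "SD", "PD"))
  tab <- table(cat3, m$group)
  mat <- matrix(as.integer(tab), nrow = 3,
                dimnames = list(rownames(tab), colnames(tab)))
  mat
}

#' Progressive rate per risk group
#'
#' Fraction of patients whose best response is PD (progressive disease) in
#' each risk group, reported as a percentage rounded to 2 decimals; the
#' exact fractions are retained in attribute `fraction`.
#'
#' @param counts contingency matrix with a `PD` row (e.g. from
#'   [response_by_risk()]), columns = risk groups.
#' @return named numeric vector of percentages (2 dp), with attributes
#'   `fraction` (exact), `pd` and `n` (counts).
#' @export
progressive_rate <- function(counts) {
  if (!"PD" %in% rownames(counts)) stop("contingency table lacks a PD row")
  n_group <- colSums(counts)
  if (any(n_group == 0)) stop("zero group size")
  frac <- counts["PD", ] / n_group
  out <- round(100 * frac, 2)
  attr(out, "fraction") <- frac
  attr(out, "pd") <- counts["PD", ]
  attr(out, "n") <- n_group
  out
}

#' Pearson chi-square or Fisher exact test on a contingency table
#'
#' Pearson's chi-square (without continuity correction) by default; for 2x2
#' tables with any expected cell below 5 the Fisher exact test is used
#' instead. The method actually applied is recorded.
#'
#' @param counts non-negative integer contingency matrix.
#' @return list `statistic` (NA for Fisher), `p`, `method`.
#' @export
chisq_or_fisher <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate margin (all-zero row or column)")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(dim(counts) == c(2L, 2L)) && any(expected < 5)) {
    ft <- stats::fisher.test(counts)
    return(list(statistic = NA_real_, p = ft$p.value, method = "fisher"))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value, method = "chisq")
}

#' Time-dependent ROC AUC for censored survival
#'
#' Cumulative-case / dynamic-control AUC at horizon `t`: cases experienced
#' the event by `t`, controls are still event-free beyond `t`. The default
#' estimator weights each case by the inverse probability of remaining
#' uncensored just before its event time and each control by the inverse
#' probability of remaining uncensored through `t` (IPCW, with the
#' censoring distribution estimated by Kaplan-Meier on the censoring
#' indicator); with no censoring the weights collapse to 1 and the naive
#' case/control AUC is recovered exactly. The CI is a percentile bootstrap
#' over subjects.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param time,event survival outcome.
#' @param t evaluation horizon (within follow-up).
#' @param estimator `"ipcw"` (default) or `"naive"`.
#' @param boot bootstrap resamples for the CI (0 to skip).
#' @param seed seed for the bootstrap.
#' @return a `td_roc` list: `t`, `auc`, `estimator`, `ci_lower`,
#'   `ci_upper`, `n_cases`, `n_controls`.
#' @export
td_auc <- function(scores, time, event, t, estimator = c("ipcw", "naive"),
                   boot = 200L, seed = 1L) {
  estimator <- match.arg(estimator)
  check_survival_inputs(time, event)
  stopifnot(length(scores) == length(time))
  if (t <= 0 || t > max(time)) stop("t must lie within observed follow-up")
  point <- td_auc_once(scores, time, event, t, estimator)
  if (is.na(point$auc)) {
    if (point$n_cases == 0) stop("no cases by time t")
    stop("no controls beyond time t")
  }
  ci <- c(NA_real_, NA_real_)
  if (boot > 0L) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    n <- length(time)
    reps <- vapply(seq_len(boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      td_auc_once(scores[idx], time[idx], event[idx], t, estimator)$auc
    }, numeric(1))
    reps <- reps[is.finite(reps)]
    if (length(reps) >= 10L) {
      ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
    }
  }
  out <- list(t = t, auc = point$auc, estimator = estimator,
              ci_lower = ci[1L], ci_upper = ci[2L],
              n_cases = point$n_cases, n_controls = point$n_controls)
  class(out) <- "td_roc"
  out
}

td_auc_once <- function(scores, time, event, t, estimator) {
  case <- time <= t & event == 1
  control <- time > t
  n_cases <- sum(case)
  n_controls <- sum(control)
  if (n_cases == 0 || n_controls == 0) {
    return(list(auc = NA_real_, n_cases = n_cases, n_controls = n_controls))
  }
  if (estimator == "ipcw") {
    cens_km <- km_one(time, 1 - event)
    G <- function(u, strict = FALSE) {
      # censoring-survival step function; strict = left limit G(u-)
      if (!length(cens_km$time)) return(rep(1, length(u)))
      vapply(u, function(ui) {
        idx <- if (strict) which(cens_km$time < ui) else which(cens_km$time <= ui)
        if (length(idx)) cens_km$surv[max(idx)] else 1
      }, numeric(1))
    }
    w_case <- 1 / pmax(G(time[case], strict = TRUE), 1e-10)
    w_control <- rep(1 / pmax(G(t), 1e-10), n_controls)
  } else {
    w_case <- rep(1, n_cases)
    w_control <- rep(1, n_controls)
  }
  sc <- scores[case]
  sk <- scores[control]
  cmp <- outer(sc, sk, function(a, b) (a > b) + 0.5 * (a == b))
  wmat <- outer(w_case, w_control)
  list(auc = sum(wmat * cmp) / sum(wmat),
       n_cases = n_cases, n_controls = n_controls)
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("AUC(t = %g) = %.3f [%s] (95%% CI %.3f-%.3f; %d cases, %d controls)\n",
              x$t, x$auc, x$estimator, x$ci_lower, x$ci_upper,
              x$n_cases, x$n_controls))
  invisible(x)
}
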