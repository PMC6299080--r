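#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Maximizes the Breslow (default) or Efron partial likelihood with full
#' Newton steps, step-halving whenever a step would decrease the log partial
#' likelihood, convergence when the largest score component drops below 1e-8
#' or the likelihood gain below 1e-10, and an iteration cap of 50 (hitting
#' the cap with a still-growing likelihood is flagged as possible monotone
#' likelihood / separation). Wald standard errors come from the inverse
#' observed information at the maximum; 95% confidence intervals are
#' `exp(beta +/- 1.96 se)`.
#'
#' @param time positive event/censoring times.
#' @param event 0/1 event indicators (at least one event).
#' @param x covariate matrix (or vector), numeric, full rank on the data.
#' @param ties `"breslow"` or `"efron"`.
#' @return object of class `cox_fit`: `coefficients`, `se`, `z`, `p`, `hr`,
#'   `ci_lower`, `ci_upper`, `loglik`, `loglik_null`, `iterations`,
#'   `converged`, `ties`, `n`, `n_events`.
#' @export
fit_cox <- function(time, event, x, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  check_survival_inputs(time, event, x)
  p <- ncol(x)
  xc <- sweep(x, 2L, colMeans(x))
  qrx <- qr(xc)
  if (qrx$rank < p) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- rep(0, p)
  ll <- cox_pl(beta, time, event, x, ties, derivs = TRUE)
  loglik_null <- ll$loglik
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(50L)) {
    step <- tryCatch(solve(ll$hessian, ll$gradient),
                     error = function(e) NULL)
    if (is.null(step)) {
      stop("singular information matrix during Newton iteration")
    }
    new_beta <- beta + step
    new_ll <- cox_pl(new_beta, time, event, x, ties, derivs = TRUE)
    halvings <- 0L
    while ((!is.finite(new_ll$loglik) || new_ll$loglik < ll$loglik) &&
           halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- cox_pl(new_beta, time, event, x, ties, derivs = TRUE)
      halvings <- halvings + 1L
    }
    gain <- new_ll$loglik - ll$loglik
    beta <- new_beta
    ll <- new_ll
    if (max(abs(ll$gradient)) < 1e-8 || (gain >= 0 && gain < 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged || any(abs(beta) > 15)) {
    warning("Cox fit did not converge cleanly after ", iter,
            " iterations (possible monotone likelihood / separation)")
  }
  nm <- colnames(x)
  beta <- setNames(beta, nm)
  se <- setNames(sqrt(diag(solve(ll$hessian))), nm)
  z <- beta / se
  out <- list(
    coefficients = beta,
    se = se,
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    loglik = ll$loglik,
    loglik_null = loglik_null,
    iterations = iter,
    converged = converged,
    ties = ties,
    n = length(time),
    n_events = sum(event)
  )
  class(out) <- "cox_fit"
  out
}

check_survival_inputs <- function(time, event, x = NULL) {
  if (any(!is.finite(time) | time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 1) stop("need at least one event")
  if (!is.null(x)) {
    stopifnot(nrow(x) == length(time), length(event) == length(time))
    if (any(!is.finite(x))) stop("covariates must be finite")
  }
  invisible(TRUE)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties), n = %d, events = %d, loglik = %.4f\n",
              x$ties, x$n, x$n_events, x$loglik))
  tab <- data.frame(coef = x$coefficients, HR = x$hr, se = x$se, z = x$z,
                    p = x$p, lower95 = x$ci_lower, upper95 = x$ci_upper)
  print(round(tab, 4))
  invisible(x)
}

# Log partial likelihood with analytic gradient/Hessian.
# Breslow is fully vectorized over suffix sums; Efron loops over tied event
# groups (few in practice).
cox_pl <- function(beta, time, event, x, ties = "breslow", derivs = FALSE) {
  x <- as.matrix(x)
  n <- length(time)
  p <- ncol(x)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; x_s <- x[ord, , drop = FALSE]
  ut <- unique(t_s)
  grp <- match(t_s, ut)
  G <- length(ut)
  eta <- drop(x_s %*% beta)
  eta <- eta - max(eta)  # guard overflow; cancels in all ratios and in loglik via offset below
  r <- exp(eta)
  m_g <- as.vector(rowsum(e_s, grp))              # events per tied-time group
  agg_r <- as.vector(rowsum(r, grp))
  Rsum <- rev(cumsum(rev(agg_r)))                 # sum of r over risk set of group g
  ev_eta_g <- as.vector(rowsum(eta * e_s, grp))
  if (ties == "breslow") {
    loglik <- sum(ev_eta_g) - sum(m_g * log(Rsum))
    if (!derivs) return(list(loglik = loglik))
    agg_rx <- rowsum(r * x_s, grp)                # G x p
    Sx <- apply(agg_rx, 2L, function(cc) rev(cumsum(rev(cc))))
    Sx <- matrix(Sx, nrow = G)
    U <- colSums(x_s * e_s) - colSums(m_g * Sx / Rsum)
    H <- matrix(0, p, p)
    xbar <- Sx / Rsum
    for (j in seq_len(p)) {
      for (k in j:p) {
        col <- r * x_s[, j] * x_s[, k]
        Sxx_jk <- rev(cumsum(rev(as.vector(rowsum(col, grp)))))
        hjk <- sum(m_g * (Sxx_jk / Rsum - xbar[, j] * xbar[, k]))
        H[j, k] <- hjk
        H[k, j] <- hjk
      }
    }
    return(list(loglik = loglik, gradient = U, hessian = H))
  }
  # Efron
  loglik <- sum(ev_eta_g)
  U <- if (derivs) colSums(x_s * e_s) else NULL
  H <- if (derivs) matrix(0, p, p) else NULL
  agg_rx <- rowsum(r * x_s, grp)
  Sx <- apply(agg_rx, 2L, function(cc) rev(cumsum(rev(cc))))
  Sx <- matrix(Sx, nrow = G)
  for (g in which(m_g > 0)) {
    idx <- which(grp == g & e_s == 1)
    m <- length(idx)
    rD <- sum(r[idx])
    SxD <- colSums(x_s[idx, , drop = FALSE] * r[idx])
    for (l in seq_len(m) - 1L) {
      denom <- Rsum[g] - (l / m) * rD
      loglik <- loglik - log(denom)
      if (derivs) {
        num <- Sx[g, ] - (l / m) * SxD
        U <- U - num / denom
        # second-moment suffix sums for this group
        Sxx_num <- matrix(0, p, p)
        for (j in seq_len(p)) {
          for (k in j:p) {
            col <- r * x_s[, j] * x_s[, k]
            sfx <- sum(col[grp >= g])
            sD <- sum(col[idx])
            v <- sfx - (l / m) * sD
            Sxx_num[j, k] <- v
            Sxx_num[k, j] <- v
          }
        }
        H <- H + Sxx_num / denom - tcrossprod(num / denom)
      }
    }
  }
  if (!derivs) return(list(loglik = loglik))
  list(loglik = loglik, gradient = U, hessian = H)
}

#' Univariate Cox screen over all features
#'
#' Fits one single-covariate Cox model per expression feature against the
#' matched clinical outcomes and keeps the features whose Wald p-value is
#' below `alpha` (the screening threshold, default 0.1).
#'
#' @param expr features x samples matrix.
#' @param clinical a `clinical_cohort` (needs `sample_id`, `pfs_months`,
#'   `event`).
#' @param alpha Wald p-value threshold.
#' @param ties ties method passed to [fit_cox()].
#' @return list with `kept` (feature ids, screen survivors), `table`
#'   (per-feature beta/HR/se/z/p), `n` (matched samples).
#' @export
univariate_cox_screen <- function(expr, clinical, alpha = 0.1,
                                  ties = "breslow") {
  ids <- intersect(colnames(expr), clinical$sample_id)
  if (!length(ids)) stop("no overlapping sample ids between expression and clinical data")
  cl <- clinical[match(ids, clinical$sample_id), ]
  ex <- expr[, ids, drop = FALSE]
  res <- lapply(rownames(ex), function(f) {
    xi <- ex[f, ]
    if (stats::sd(xi) < .Machine$double.eps * 100) {
      return(data.frame(feature_id = f, beta = NA_real_, hr = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_))
    }
    fit <- suppressWarnings(
      fit_cox(cl$pfs_months, cl$event, matrix(xi, ncol = 1), ties = ties))
    data.frame(feature_id = f, beta = fit$coefficients[1L], hr = fit$hr[1L],
               se = fit$se[1L], z = fit$z[1L], p = fit$p[1L])
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  kept <- tab$feature_id[!is.na(tab$p) & tab$p < alpha]
  list(kept = kept, table = tab, n = length(ids))
}

#' Cox model with a two-factor interaction
#'
#' Fits main effects of two binary factors plus their product term; reports
#' the interaction hazard ratio, confidence interval and Wald p. An empty
#' cell in the 2x2 factor table is flagged (the product term is then poorly
#' identified); a constant factor raises the usual rank-deficiency error
#' naming the offending columns.
#'
#' @param time,event survival outcome.
#' @param factor_a,factor_b binary (0/1) vectors.
#' @param ties ties method.
#' @return a `cox_fit` with covariates `a`, `b`, `a_x_b`; the 2x2 cell
#'   counts are attached as attribute `cells`.
#' @export
fit_interaction_cox <- function(time, event, factor_a, factor_b,
                                ties = "breslow") {
  stopifnot(all(factor_a %in% c(0, 1)), all(factor_b %in% c(0, 1)))
  cells <- table(factor(factor_a, levels = 0:1),
                 factor(factor_b, levels = 0:1))
  if (any(cells == 0)) {
    warning("empty cell in the 2x2 factor table; interaction fit unstable")
  }
  x <- cbind(a = factor_a, b = factor_b, a_x_b = factor_a * factor_b)
  fit <- fit_cox(time, event, x, ties = ties)
  attr(fit, "cells") <- cells
  fit
}
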