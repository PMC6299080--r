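#' qPCR-scale normalization
#'
#' Maps relative expression values (2^-dCt, strictly positive) onto a
#' readable log2 scale: `log2(10000 * x)`, i.e. `log2(10000) - dCt`.
#'
#' @param x numeric vector or matrix of strictly positive relative values.
#' @return object of the same shape on the log2 scale.
#' @export
normalize_qpcr <- function(x) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    if (is.matrix(x)) {
      rc <- arrayInd(bad[1L], dim(x))
      stop(sprintf("non-positive value at row %s, column %s",
                   rownames(x)[rc[1]] %||% rc[1],
                   colnames(x)[rc[2]] %||% rc[2]))
    }
    stop("non-positive value at position ", bad[1L])
  }
  log2(10000 * x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tied-time bookkeeping shared by the path solver and its KKT checks:
# subjects sorted by ascending time, 1-based tie-group index, events/group.
surv_parts <- function(time, event) {
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  ut <- unique(t_s)
  grp <- match(t_s, ut)
  m_g <- as.vector(rowsum(e_s, grp))
  list(ord = ord, grp = grp, m_g = m_g, G = length(ut), d = e_s)
}

# Per-subject score residuals u_i = d_i - r_i * A_i of the Breslow partial
# likelihood at linear predictor eta (subjects in sorted order).
breslow_score_resid <- function(eta, parts) {
  r <- exp(eta - max(eta))
  rsum <- rev(cumsum(rev(as.vector(rowsum(r, parts$grp)))))
  A <- cumsum(parts$m_g / rsum)
  parts$d - r * A[parts$grp]
}

# Breslow log partial likelihood for every column of a coefficient matrix at
# once (used by the CV deviance, where 100 path solutions are scored per
# fold). Invariant to the per-column max shift.
breslow_loglik_multi <- function(Beta, time, event, x) {
  parts <- surv_parts(time, event)
  xs <- as.matrix(x)[parts$ord, , drop = FALSE]
  eta <- xs %*% Beta
  shift <- apply(eta, 2L, max)
  eta <- sweep(eta, 2L, shift)
  r <- exp(eta)
  aggr <- rowsum(r, parts$grp)
  rsum <- apply(aggr, 2L, function(cc) rev(cumsum(rev(cc))))
  rsum <- matrix(rsum, nrow = parts$G)
  drop(crossprod(eta, parts$d)) - drop(crossprod(log(rsum), parts$m_g))
}

#' L1-penalized Cox regression over a lambda path
#'
#' Minimizes `-(1/n) logPL(beta) + lambda * sum(|beta_j|)` (Breslow partial
#' likelihood) by iteratively reweighted least squares with cyclic
#' coordinate-wise soft-thresholding, warm-started along a descending
#' log-spaced lambda grid from `lambda_max` (the smallest penalty at which
#' all coefficients vanish, `max_j |(1/n) U_j(0)|`) down to
#' `lambda_max * lambda_min_ratio`. Features are standardized internally
#' (mean 0, population variance 1); coefficients are returned on the
#' original scale. Karush-Kuhn-Tucker conditions are verified at every
#' solution (tolerance 1e-6 on the standardized scale).
#'
#' @param time,event survival outcome (at least one event).
#' @param x design matrix, samples in rows, features in columns.
#' @param nlambda path length.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda-max.
#' @param lambda optional explicit descending grid (overrides the above).
#' @param kkt_check verify the KKT conditions at every path solution
#'   (default); inner cross-validation refits skip it for speed.
#' @param tol solver tolerance: the outer loop stops when the true KKT
#'   residual falls below `tol`. The default 1e-7 comfortably meets the
#'   1e-6 path guarantee; the bagging loop relaxes it to selection-grade
#'   1e-5 (the active set is insensitive to the last decimals).
#' @param on_nonconvergence `"error"` (default) raises an error naming the
#'   first non-converged lambda index; `"truncate"` instead returns the path
#'   up to the last converged lambda. Saturated fits deep in the path
#'   (monotone likelihood on small resamples) are the usual cause, and
#'   cross-validation/bagging use truncation, matching standard
#'   survival-lasso practice of stopping the path before saturation.
#' @return a `lasso_path`: `lambda`, `beta` (features x lambda, original
#'   scale), `beta_std`, `df` (nonzero counts), `lambda_max`, `center`,
#'   `scale`, `kkt_max_violation`, `iterations`.
#' @export
lasso_cox_path <- function(time, event, x, nlambda = 100L,
                           lambda_min_ratio = 0.01, lambda = NULL,
                           kkt_check = TRUE, tol = 1e-7,
                           on_nonconvergence = c("error", "truncate")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  check_survival_inputs(time, event, x)
  n <- nrow(x)
  p <- ncol(x)
  parts <- surv_parts(time, event)
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2L, ctr)^2))
  keep <- scl > 1e-12
  xs <- sweep(x, 2L, ctr)
  xs[, keep] <- sweep(xs[, keep, drop = FALSE], 2L, scl[keep], "/")
  xs[, !keep] <- 0
  xs_sorted <- xs[parts$ord, , drop = FALSE]
  u0 <- breslow_score_resid(rep(0, n), parts)
  score0 <- drop(crossprod(xs_sorted, u0)) / n
  lambda_max <- max(abs(score0))
  if (is.null(lambda)) {
    if (lambda_max <= 0) lambda_max <- 1e-3
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  truncate_mode <- on_nonconvergence == "truncate"
  fit <- cox_cd_path(xs_sorted, parts$d, parts$grp, parts$m_g, lambda,
                     tol = tol, max_irls = if (truncate_mode) 50L else 500L,
                     max_cd = 5L, early_stop = truncate_mode)
  if (!all(fit$converged)) {
    first_bad <- which(!fit$converged)[1L]
    if (on_nonconvergence == "error" || first_bad == 1L) {
      stop("coordinate descent failed to converge at lambda index ",
           first_bad)
    }
    keep_k <- seq_len(first_bad - 1L)
    lambda <- lambda[keep_k]
    fit$beta <- fit$beta[, keep_k, drop = FALSE]
    fit$iterations <- fit$iterations[keep_k]
  }
  beta_std <- fit$beta
  # clip numerically-null coefficients (last-bit score noise at lambda_max
  # can leave ~1e-12 remnants that would miscount the active set)
  beta_std[abs(beta_std) < 1e-10] <- 0
  rownames(beta_std) <- colnames(x)
  beta <- beta_std
  beta[keep, ] <- beta_std[keep, , drop = FALSE] / scl[keep]
  # KKT residuals on the standardized scale
  kkt <- NA_real_
  if (kkt_check) {
    kkt <- 0
    for (k in seq_along(lambda)) {
      eta <- drop(xs_sorted %*% beta_std[, k])
      gj <- drop(crossprod(xs_sorted, breslow_score_resid(eta, parts))) / n
      bz <- beta_std[, k] == 0
      viol <- max(c(pmax(0, abs(gj[bz]) - lambda[k]),
                    abs(gj[!bz] - lambda[k] * sign(beta_std[!bz, k]))), 0)
      kkt <- max(kkt, viol)
    }
    if (kkt > 1e-6) {
      warning(sprintf("KKT violation %.2g exceeds 1e-6", kkt))
    }
  }
  out <- list(lambda = lambda, beta = beta, beta_std = beta_std,
              df = colSums(beta != 0), lambda_max = lambda_max,
              center = ctr, scale = scl, kkt_max_violation = kkt,
              iterations = fit$iterations, n = n, p = p)
  class(out) <- "lasso_path"
  out
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("LASSO-Cox path: %d lambdas in [%.4g, %.4g], %d features, max KKT violation %.2g\n",
              length(x$lambda), min(x$lambda), max(x$lambda), x$p,
              x$kkt_max_violation))
  invisible(x)
}

#' Cross-validated LASSO-Cox with the 1-SE rule
#'
#' K-fold cross-validation of the penalized Cox path using the
#' Verweij-Van Houwelingen cross-validated partial-likelihood deviance:
#' for held-out fold k, `dev_k(lambda) = -2 * (l_full(beta_-k) -
#' l_-k(beta_-k))`, where `beta_-k` is the path fitted without fold k.
#' `lambda_min` minimizes the fold-mean deviance; `lambda_1se` is the
#' largest lambda whose mean deviance is within one standard error of that
#' minimum. The selected feature set is the nonzero set of the full-data
#' path at `lambda_1se`.
#'
#' @param time,event survival outcome.
#' @param x design matrix, samples in rows.
#' @param folds number of CV folds (>= 2).
#' @param seed integer seed for the fold deal.
#' @param nlambda,lambda_min_ratio path geometry (see [lasso_cox_path()]).
#' @param kkt_check verify KKT conditions on the full-data path (off by
#'   default here; the bagging loop calls this thousands of times).
#' @param tol solver KKT tolerance (see [lasso_cox_path()]).
#' @return a `cv_result`: `lambda`, `mean_dev`, `se_dev`, `lambda_min`,
#'   `lambda_1se`, `selected` (feature ids), `fold_id`, `path` (full-data
#'   `lasso_path`).
#' @export
cv_lasso <- function(time, event, x, folds = 10L, seed = 1L, nlambda = 100L,
                     lambda_min_ratio = 0.01, kkt_check = FALSE, tol = 1e-7) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  n <- nrow(x)
  if (folds < 2L) stop("folds must be >= 2")
  path <- lasso_cox_path(time, event, x, nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio,
                         kkt_check = kkt_check, tol = tol,
                         on_nonconvergence = "truncate")
  lambda <- path$lambda
  deal <- function(s) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(s)
    sample(rep_len(seq_len(folds), n))
  }
  fold_id <- deal(seed)
  ok_folds <- function(fid) {
    all(vapply(seq_len(folds), function(k) sum(event[fid != k]) >= 1,
               logical(1)))
  }
  if (!ok_folds(fold_id)) {
    fold_id <- deal(child_seed(seed, 999L))
    if (!ok_folds(fold_id)) stop("a training fold has zero events after re-dealing")
  }
  dev <- matrix(NA_real_, folds, length(lambda))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    fit_k <- lasso_cox_path(time[tr], event[tr], x[tr, , drop = FALSE],
                            lambda = lambda, kkt_check = FALSE, tol = tol,
                            on_nonconvergence = "truncate")
    kk <- seq_along(fit_k$lambda)  # fold path may be truncated further
    l_full <- breslow_loglik_multi(fit_k$beta, time, event, x)
    l_train <- breslow_loglik_multi(fit_k$beta, time[tr], event[tr],
                                    x[tr, , drop = FALSE])
    dev[k, kk] <- -2 * (l_full - l_train)
  }
  valid <- which(colSums(is.na(dev)) == 0L)
  if (!length(valid)) stop("cross-validation failed at every lambda")
  mean_dev <- colMeans(dev)
  se_dev <- apply(dev, 2L, stats::sd) / sqrt(folds)
  i_min <- valid[which.min(mean_dev[valid])]
  thresh <- mean_dev[i_min] + se_dev[i_min]
  i_1se <- min(valid[mean_dev[valid] <= thresh + 1e-12])
  selected <- rownames(path$beta)[path$beta[, i_1se] != 0]
  out <- list(lambda = lambda, mean_dev = mean_dev, se_dev = se_dev,
              lambda_min = lambda[i_min], lambda_1se = lambda[i_1se],
              index_min = i_min, index_1se = i_1se,
              selected = selected, fold_id = fold_id, path = path)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV LASSO-Cox: lambda_min = %.4g, lambda_1se = %.4g, %d feature(s) selected\n",
              x$lambda_min, x$lambda_1se, length(x$selected)))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Bootstrap bagging of the LASSO-Cox selection (RMIP)
#'
#' Draws `B` bootstrap resamples of the subjects (with replacement,
#' duplicates entering the partial likelihood as repeated rows), runs the
#' full cross-validated LASSO-Cox selection on each (its own lambda path and
#' its own seeded fold deal), and records the nonzero set at that resample's
#' `lambda_1se`. The resample model inclusion proportion of feature j is
#' `RMIP_j = count_j / B`. Resamples whose cross-validation degenerates
#' (e.g. a training fold without events) are redrawn; more than 10%
#' redraws aborts with a diagnostic.
#'
#' @param time,event survival outcome.
#' @param x design matrix, samples in rows, features in columns.
#' @param B number of bootstrap resamples.
#' @param folds CV folds per resample.
#' @param seed master seed; each resample gets a derived child seed.
#' @param nlambda,lambda_min_ratio path geometry.
#' @param tol solver KKT tolerance; the selection-grade default 1e-5 is
#'   looser than the path default because only the active set matters here.
#' @return an `rmip_table` data frame: `feature_id`, `rmip`, `count`, `B`,
#'   `rank` (descending RMIP, ties broken lexicographically); number of
#'   redraws in attribute `redraws`.
#' @export
bag_lasso <- function(time, event, x, B = 1000L, folds = 10L, seed = 1L,
                      nlambda = 100L, lambda_min_ratio = 0.01, tol = 1e-5) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  stopifnot(B >= 1L)
  n <- nrow(x)
  counts <- setNames(integer(ncol(x)), colnames(x))
  redraws <- 0L
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      sb <- child_seed(child_seed(seed, b), attempt + 1L)
      old <- get_rng_state()
      set.seed(sb)
      idx <- sample.int(n, n, replace = TRUE)
      restore_rng_state(old)
      res <- tryCatch(
        cv_lasso(time[idx], event[idx], x[idx, , drop = FALSE],
                 folds = folds, seed = child_seed(sb, 2L),
                 nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                 tol = tol),
        error = function(e) e)
      if (!inherits(res, "error")) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (redraws > 0.1 * B + 1L) {
        stop("more than 10% of bootstrap resamples degenerate: ",
             conditionMessage(res))
      }
    }
    counts[res$selected] <- counts[res$selected] + 1L
  }
  out <- new_rmip_table(counts, B)
  attr(out, "redraws") <- redraws
  out
}

new_rmip_table <- function(counts, B) {
  stopifnot(!is.null(names(counts)))
  df <- data.frame(feature_id = names(counts),
                   rmip = as.numeric(counts) / B,
                   count = as.integer(counts),
                   B = as.integer(B),
                   stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-df$rmip, df$feature_id)
  df$rank <- integer(nrow(df))
  df$rank[ord] <- seq_len(nrow(df))
  class(df) <- c("rmip_table", "data.frame")
  df
}

#' Pick the top-k features by RMIP
#'
#' Orders features by descending RMIP (ties broken lexicographically by
#' feature id, which is logged) and returns the first `k`. With
#' `elbow = TRUE` the position of the largest consecutive RMIP drop is
#' attached as attribute `suggested_k`.
#'
#' @param rmip an `rmip_table`.
#' @param k number of features to keep.
#' @param elbow also report the largest-drop position.
#' @return character vector of feature ids, RMIP-descending order.
#' @export
select_top_features <- function(rmip, k, elbow = FALSE) {
  stopifnot(inherits(rmip, "rmip_table"), k >= 1L, k <= nrow(rmip))
  if (all(rmip$rmip == 0)) stop("all RMIP values are zero: no signal to select from")
  ord <- order(rmip$rank)
  sorted <- rmip[ord, ]
  if (k < nrow(sorted) && sorted$rmip[k] == sorted$rmip[k + 1L]) {
    message("RMIP tie at rank ", k, "; keeping lexicographically smaller id '",
            sorted$feature_id[k], "'")
  }
  out <- sorted$feature_id[seq_len(k)]
  if (elbow) {
    drops <- -diff(sorted$rmip)
    attr(out, "suggested_k") <- which.max(drops)
  }
  out
}
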