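#' Paired two-group t-test per feature
#'
#' Classical paired Student's t on tumour-minus-normal log2 differences,
#' one feature at a time. Features whose within-pair differences have zero
#' variance get `p = 1` and a `zero_var` flag (the statistic is undefined
#' there); they are later excluded from the moderated-t hyperparameter fit.
#'
#' @param expr numeric matrix, features x samples.
#' @param pairing data frame with columns `pair_id`, `tumour`, `normal`
#'   naming columns of `expr`.
#' @return a `de_result` data frame with per-feature `mean_diff`, `s2`
#'   (sample variance of differences), `df`, `t`, `p`, `direction`,
#'   `zero_var`.
#' @export
paired_t <- function(expr, pairing) {
  stopifnot(is.matrix(expr))
  if (nrow(pairing) < 3L) stop("need at least 3 pairs")
  missing_members <- pairing$pair_id[!(pairing$tumour %in% colnames(expr)) |
                                       !(pairing$normal %in% colnames(expr))]
  if (length(missing_members)) {
    stop("pair(s) missing a member in the expression matrix: ",
         paste(missing_members, collapse = ", "))
  }
  d <- expr[, pairing$tumour, drop = FALSE] -
    expr[, pairing$normal, drop = FALSE]
  if (anyNA(d)) {
    drop <- rownames(d)[apply(is.na(d), 1L, any)]
    warning("dropping ", length(drop),
            " feature(s) with missing values in the paired screen")
    d <- d[!rownames(d) %in% drop, , drop = FALSE]
  }
  n <- ncol(d)
  mean_diff <- rowMeans(d)
  s2 <- apply(d, 1L, stats::var)
  zero_var <- s2 <= .Machine$double.eps * 100
  df <- n - 1L
  tstat <- ifelse(zero_var, NA_real_, mean_diff / sqrt(s2 / n))
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(tstat), df = df))
  out <- data.frame(
    feature_id = rownames(d),
    mean_diff = mean_diff,
    s2 = s2,
    df = df,
    t = tstat,
    p = p,
    direction = ifelse(mean_diff > 0, "up", ifelse(mean_diff < 0, "down", "none")),
    zero_var = zero_var,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("de_result", "data.frame")
  out
}

#' Empirical-Bayes moderated t
#'
#' Shrinks the per-feature variances towards a pooled prior:
#' `s2_post = (d0 * s02 + df * s2) / (d0 + df)`, with the moderated t using
#' `s2_post` and `d0 + df` degrees of freedom. The prior degrees of freedom
#' `d0` and prior variance `s02` are estimated by the method of moments on
#' `log(s2)` (matching the scaled-F marginal of the hierarchical model):
#' the excess spread of `log(s2)` beyond `trigamma(df/2)` identifies `d0`
#' through the trigamma function, and the mean identifies `s02` through the
#' digamma function. Zero-variance features are excluded from the fit.
#'
#' @param de a `de_result` from [paired_t()].
#' @param d0,s02 optional forced hyperparameters (e.g. `d0 = 0` recovers the
#'   classical t exactly; `d0 = Inf` uses the common prior variance for every
#'   feature). When supplied, both must be given.
#' @return the `de_result` with added columns `s2_post`, `t_mod`, `p_mod`,
#'   `q` (BH-adjusted moderated p), and attributes `d0`, `s02`.
#' @export
moderated_t <- function(de, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(de, "de_result"))
  use <- !de$zero_var
  if (sum(use) < 2L) stop("need at least 2 features with positive variance")
  df <- de$df[1L]
  if (is.null(d0) != is.null(s02)) {
    stop("supply both d0 and s02, or neither")
  }
  if (is.null(d0)) {
    hp <- fit_f_dist(de$s2[use], df)
    d0 <- hp$d0
    s02 <- hp$s02
  }
  if (d0 < 0 || s02 <= 0) stop("d0 must be >= 0 and s02 > 0")
  if (is.infinite(d0)) {
    s2_post <- rep(s02, nrow(de))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- de$s2
    df_total <- df
  } else {
    s2_post <- (d0 * s02 + df * de$s2) / (d0 + df)
    df_total <- d0 + df
  }
  n <- df + 1L
  t_mod <- de$mean_diff / sqrt(s2_post / n)
  bad <- !is.finite(t_mod)
  p_mod <- ifelse(bad, 1,
                  if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod))
                  else 2 * stats::pt(-abs(t_mod), df = df_total))
  de$s2_post <- s2_post
  de$t_mod <- ifelse(bad, NA_real_, t_mod)
  de$p_mod <- p_mod
  de$q <- bh_fdr(de$p_mod)
  attr(de, "d0") <- d0
  attr(de, "s02") <- s02
  attr(de, "df_total") <- df_total
  de
}

# Method-of-moments fit of the scaled-F model for sample variances:
# log(s2) = log(s02) + digamma-corrected chi-square terms.
fit_f_dist <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  evar <- sum((e - ebar)^2) / (n - 1L) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(ebar)
  }
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function (monotone decreasing on (0,Inf)).
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1L, is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order; always `>= p` elementwise.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

#' Call differentially expressed features
#'
#' Thresholds the moderated-t q-values (default) or raw moderated p-values
#' and splits the calls by direction of the tumour-minus-normal difference.
#'
#' @param de a `de_result`; if [moderated_t()] has not been run, the raw
#'   paired-t p-values are used.
#' @param alpha significance threshold.
#' @param use_fdr threshold BH q-values (`TRUE`, default) or raw p-values.
#' @return list with character vectors `up`, `down`, and the full `called`
#'   id vector.
#' @export
call_de <- function(de, alpha = 0.05, use_fdr = TRUE) {
  stopifnot(inherits(de, "de_result"), alpha > 0, alpha < 1)
  p <- if ("p_mod" %in% colnames(de)) de$p_mod else de$p
  stat <- if (use_fdr) bh_fdr(p) else p
  hit <- stat < alpha
  list(
    up = de$feature_id[hit & de$direction == "up"],
    down = de$feature_id[hit & de$direction == "down"],
    called = de$feature_id[hit]
  )
}
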