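#' Pipeline configuration
#'
#' Bundles every tunable of the signature-discovery pipeline in one validated
#' object. Defaults reproduce the canonical procedure: 1000 bootstrap
#' resamples, 10-fold cross-validation with the 1-SE rule, a 100-point
#' log-spaced lambda path down to 1% of lambda-max, a BH-FDR 0.05
#' differential-expression screen, a Wald p < 0.1 univariate Cox screen, and
#' a top-2 signature.
#'
#' @param seed integer; master seed. Expanded into independent per-stage
#'   child seeds by a fixed counter scheme (see [child_seed()]).
#' @param B_resamples positive integer; bootstrap resamples for the bagging
#'   stage.
#' @param cv_folds positive integer; cross-validation folds.
#' @param lambda_path_length positive integer; points on the lambda path.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda-max,
#'   in (0,1).
#' @param de_alpha significance level of the differential-expression screen.
#' @param de_use_fdr logical; if `TRUE` (default) threshold BH q-values,
#'   otherwise raw p-values.
#' @param cox_screen_alpha Wald p-value threshold of the univariate Cox
#'   screen.
#' @param top_k number of top-RMIP features in the final signature.
#' @param ties_method `"breslow"` or `"efron"` partial-likelihood ties
#'   handling.
#' @param expression_scale `"relative"` if cohort expression arrives as
#'   2^-dCt relative values (the qPCR normalization `log2(10000 * x)` is then
#'   applied), `"log2"` if it is already on a log2 scale.
#'
#' @return an object of class `pipeline_config` (a validated list).
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 1, B_resamples = 100)
#' cfg$top_k
pipeline_config <- function(seed = 1L,
                            B_resamples = 1000L,
                            cv_folds = 10L,
                            lambda_path_length = 100L,
                            lambda_min_ratio = 0.01,
                            de_alpha = 0.05,
                            de_use_fdr = TRUE,
                            cox_screen_alpha = 0.1,
                            top_k = 2L,
                            ties_method = c("breslow", "efron"),
                            expression_scale = c("relative", "log2")) {
  ties_method <- match.arg(ties_method)
  expression_scale <- match.arg(expression_scale)
  cfg <- list(
    seed = as.integer(seed),
    B_resamples = as.integer(B_resamples),
    cv_folds = as.integer(cv_folds),
    lambda_path_length = as.integer(lambda_path_length),
    lambda_min_ratio = as.numeric(lambda_min_ratio),
    de_alpha = as.numeric(de_alpha),
    de_use_fdr = isTRUE(de_use_fdr),
    cox_screen_alpha = as.numeric(cox_screen_alpha),
    top_k = as.integer(top_k),
    ties_method = ties_method,
    expression_scale = expression_scale
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(length(cfg$seed) == 1L && is.finite(cfg$seed), "seed must be a single integer")
  chk(cfg$B_resamples >= 1L, "B_resamples must be >= 1")
  chk(cfg$cv_folds >= 2L, "cv_folds must be >= 2")
  chk(cfg$lambda_path_length >= 2L, "lambda_path_length must be >= 2")
  chk(cfg$lambda_min_ratio > 0 && cfg$lambda_min_ratio < 1,
      "lambda_min_ratio must lie in (0,1)")
  chk(cfg$de_alpha > 0 && cfg$de_alpha < 1, "de_alpha must lie in (0,1)")
  chk(cfg$cox_screen_alpha > 0 && cfg$cox_screen_alpha < 1,
      "cox_screen_alpha must lie in (0,1)")
  chk(cfg$top_k >= 1L, "top_k must be a positive integer")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Serialize / parse a pipeline configuration
#'
#' Round-trips exactly: `read_config(write_config(cfg, f))` equals `cfg`.
#'
#' @param cfg a [pipeline_config()] object.
#' @param path file path for the JSON snapshot.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Derive a per-stage child seed from the master seed
#'
#' A fixed counter scheme (`(seed * 101 + 7919 * stage) mod (2^31 - 1)`,
#' nonzero) so that each pipeline stage draws from its own reproducible
#' stream and stages can be re-run individually.
#'
#' @param seed master integer seed.
#' @param stage integer stage counter (>= 1).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(stage >= 1)
  s <- (as.numeric(seed) * 101 + 7919 * as.numeric(stage)) %% 2147483647
  as.integer(if (s == 0) 1 else s)
}
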