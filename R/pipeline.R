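#' Run the full signature-discovery pipeline
#'
#' Chains every stage on in-memory inputs: paired differential-expression
#' screen (moderated t + BH) -> qPCR-scale normalization of the cohort
#' expression -> univariate Cox Wald screen over the DE candidates ->
#' bootstrap-bagged cross-validated LASSO-Cox with RMIP -> top-k signature
#' refit with median cutoff -> per-cohort evaluation (KM + log-rank,
#' progressive rates with chi-square/Fisher, risk-by-response interaction
#' Cox, IPCW time-dependent AUC). Each stage draws from its own child seed
#' of `config$seed`, so identical inputs and config reproduce identical
#' outputs. Any stage that leaves zero surviving features aborts with an
#' error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @param paired_expr features x samples log2 expression of the paired
#'   tumour/normal arm.
#' @param pairing pairing map (`pair_id`, `tumour`, `normal`).
#' @param cohort_expr features x samples expression of the training cohort,
#'   on the scale declared by `config$expression_scale`.
#' @param clinical training `clinical_cohort`.
#' @param validation optional named list of validation cohorts, each a list
#'   with elements `expression` and `clinical` (same scale as the training
#'   cohort). They are scored with the TRAINING cutoff.
#' @param auc_time horizon (months) of the time-dependent AUC.
#' @param out_dir optional directory; when given, every stage artifact and a
#'   run manifest are written there (deterministically, byte-identical for
#'   identical runs).
#' @return a `run_manifest` list: `config`, `stage_seeds`, `de`,
#'   `candidates`, `cox_screen`, `rmip`, `signature`, `evaluation` (one
#'   entry per cohort), `report`, and (if written) `files` with md5 digests.
#' @export
run_pipeline <- function(config, paired_expr, pairing, cohort_expr, clinical,
                         validation = list(), auc_time = 12, out_dir = NULL) {
  validate_config(config)
  ids <- intersect(colnames(cohort_expr), clinical$sample_id)
  if (!length(ids)) stop("no overlapping sample ids between cohort expression and clinical table")

  stage_seeds <- c(bagging = child_seed(config$seed, 4L),
                   auc_boot = child_seed(config$seed, 6L))

  # stage 1: paired DE screen
  de <- moderated_t(paired_t(paired_expr, pairing))
  calls <- call_de(de, alpha = config$de_alpha, use_fdr = config$de_use_fdr)
  if (!length(calls$called)) stop("de_screen stage left zero surviving features")

  # stage 2: scale normalization of the cohort arm
  norm_expr <- if (config$expression_scale == "relative") {
    normalize_qpcr(cohort_expr)
  } else cohort_expr
  candidates <- intersect(calls$called, rownames(norm_expr))
  if (!length(candidates)) stop("normalization stage left zero surviving features")

  # stage 3: univariate Cox screen on the training cohort
  screen <- univariate_cox_screen(norm_expr[candidates, , drop = FALSE],
                                  clinical, alpha = config$cox_screen_alpha,
                                  ties = config$ties_method)
  if (!length(screen$kept)) stop("cox_screen stage left zero surviving features")

  # stage 4: bootstrap-bagged LASSO-Cox selection
  cl <- clinical[match(ids, clinical$sample_id), ]
  Xtrain <- t(norm_expr[screen$kept, ids, drop = FALSE])
  rmip <- bag_lasso(cl$pfs_months, cl$event, Xtrain,
                    B = config$B_resamples, folds = config$cv_folds,
                    seed = stage_seeds[["bagging"]],
                    nlambda = config$lambda_path_length,
                    lambda_min_ratio = config$lambda_min_ratio)
  if (all(rmip$rmip == 0)) stop("bagging stage left zero surviving features")

  # stage 5: top-k signature with training-median cutoff
  top <- select_top_features(rmip, k = config$top_k, elbow = TRUE)
  signature <- fit_signature(norm_expr, clinical, as.character(top),
                             ties = config$ties_method)

  # stage 6: evaluation, training cutoff everywhere
  cohorts <- c(list(training = list(expression = cohort_expr,
                                    clinical = clinical)),
               validation)
  evaluation <- lapply(seq_along(cohorts), function(i) {
    co <- cohorts[[i]]
    ex <- if (config$expression_scale == "relative") {
      normalize_qpcr(co$expression)
    } else co$expression
    evaluate_cohort(signature, ex, co$clinical, auc_time = auc_time,
                    auc_seed = child_seed(stage_seeds[["auc_boot"]], i))
  })
  names(evaluation) <- names(cohorts)

  report <- build_report(config, de, screen, rmip, signature, evaluation)
  manifest <- list(config = config, stage_seeds = stage_seeds, de = de,
                   candidates = candidates, cox_screen = screen, rmip = rmip,
                   signature = signature, evaluation = evaluation,
                   report = report)
  class(manifest) <- "run_manifest"
  if (!is.null(out_dir)) {
    manifest$files <- write_run_artifacts(manifest, out_dir)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat(sprintf("  DE candidates: %d; Cox screen kept: %d\n",
              length(x$candidates), length(x$cox_screen$kept)))
  cat(sprintf("  Bagging: B = %d resamples\n", x$rmip$B[1L]))
  print(x$signature)
  for (nm in names(x$evaluation)) {
    ev <- x$evaluation[[nm]]
    cat(sprintf("  [%s] n = %d, log-rank p = %.3g\n",
                nm, nrow(ev$assignment), ev$logrank$p))
  }
  invisible(x)
}

#' Evaluate a fitted signature on one cohort
#'
#' Scores the cohort, dichotomizes at the signature's (training) cutoff and
#' computes the evaluation battery: KM + median PFS per risk group with
#' log-rank comparison, response-by-risk contingency with progressive rates
#' and chi-square/Fisher, the risk-by-progression interaction Cox model,
#' and the IPCW time-dependent AUC.
#'
#' @param signature a `risk_signature`.
#' @param expr features x samples log2-scale expression.
#' @param clinical matching `clinical_cohort`.
#' @param auc_time AUC horizon in months.
#' @param auc_seed seed for the AUC bootstrap CI.
#' @return list: `assignment`, `km`, `logrank`, `contingency`,
#'   `progressive_rate`, `response_test`, `interaction`, `auc`.
#' @export
evaluate_cohort <- function(signature, expr, clinical, auc_time = 12,
                            auc_seed = 1L) {
  ids <- intersect(colnames(expr), clinical$sample_id)
  if (!length(ids)) stop("no overlapping sample ids")
  cl <- clinical[match(ids, clinical$sample_id), ]
  scores <- risk_score(signature, expr[, ids, drop = FALSE])
  assignment <- classify_risk(scores, signature$cutoff)
  km_eval <- evaluate_km_by_risk(assignment, cl)
  contingency <- NULL
  prog <- NULL
  rtest <- NULL
  interaction <- NULL
  if ("response" %in% colnames(cl)) {
    contingency <- response_by_risk(assignment, cl)
    prog <- progressive_rate(contingency)
    rtest <- tryCatch(chisq_or_fisher(contingency), error = function(e) NULL)
    is_pd <- as.integer(cl$response == "PD")
    is_high <- as.integer(assignment$group == "high")
    interaction <- tryCatch(
      suppressWarnings(
        fit_interaction_cox(cl$pfs_months, cl$event, is_high, is_pd,
                            ties = signature$ties_method)),
      error = function(e) NULL)
  }
  auc <- tryCatch(
    td_auc(assignment$score, cl$pfs_months, cl$event, t = auc_time,
           seed = auc_seed),
    error = function(e) NULL)
  list(assignment = assignment, km = km_eval$km, logrank = km_eval$logrank,
       contingency = contingency, progressive_rate = prog,
       response_test = rtest, interaction = interaction, auc = auc)
}

#' Assemble the pipeline report
#'
#' One plain list (JSON-serializable) with the selection results and the
#' per-cohort evaluation summary; echoes the configuration used.
#'
#' @param config,de,screen,rmip,signature,evaluation stage outputs of
#'   [run_pipeline()].
#' @return a nested list ready for `jsonlite::write_json`.
#' @export
build_report <- function(config, de, screen, rmip, signature, evaluation) {
  stopifnot(inherits(signature, "risk_signature"))
  km_block <- function(km) {
    list(median = unname(km$median), median_lower = unname(km$median_lower),
         median_upper = unname(km$median_upper), n = km$n,
         n_events = km$n_events)
  }
  eval_block <- function(ev) {
    out <- list(
      n = nrow(ev$assignment),
      n_low = sum(ev$assignment$group == "low"),
      n_high = sum(ev$assignment$group == "high"),
      km = lapply(ev$km, km_block),
      logrank = list(statistic = ev$logrank$statistic, df = ev$logrank$df,
                     p = ev$logrank$p))
    if (!is.null(ev$progressive_rate)) {
      out$progressive_rate <- as.list(unclass(ev$progressive_rate))
      out$response_test <- ev$response_test
    }
    if (!is.null(ev$interaction)) {
      i <- which(names(ev$interaction$coefficients) == "a_x_b")
      out$interaction <- list(hr = unname(ev$interaction$hr[i]),
                              ci_lower = unname(ev$interaction$ci_lower[i]),
                              ci_upper = unname(ev$interaction$ci_upper[i]),
                              p = unname(ev$interaction$p[i]))
    }
    if (!is.null(ev$auc)) {
      out$auc <- list(t = ev$auc$t, auc = ev$auc$auc,
                      ci_lower = ev$auc$ci_lower, ci_upper = ev$auc$ci_upper)
    }
    out
  }
  list(
    config = unclass(config),
    de_screen = list(n_features = nrow(de),
                     d0 = attr(de, "d0"), s02 = attr(de, "s02")),
    cox_screen = list(n_candidates = nrow(screen$table),
                      n_kept = length(screen$kept), kept = screen$kept),
    rmip = as.data.frame(rmip)[order(rmip$rank), ],
    signature = list(features = signature$features,
                     coefficients = unname(signature$coefficients),
                     cutoff = signature$cutoff,
                     ties_method = signature$ties_method),
    evaluation = lapply(evaluation, eval_block)
  )
}

write_run_artifacts <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    de = file.path(out_dir, "de_result.tsv"),
    cox_screen = file.path(out_dir, "cox_screen.tsv"),
    rmip = file.path(out_dir, "rmip.tsv"),
    signature = file.path(out_dir, "signature.json"),
    report = file.path(out_dir, "report.json")
  )
  utils::write.table(as.data.frame(manifest$de), paths[["de"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(manifest$cox_screen$table, paths[["cox_screen"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_rmip_table(manifest$rmip, paths[["rmip"]])
  write_signature(manifest$signature, paths[["signature"]])
  jsonlite::write_json(manifest$report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  digests <- tools::md5sum(paths)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = unclass(manifest$config),
         stage_seeds = as.list(manifest$stage_seeds),
         files = as.list(setNames(unname(digests), basename(paths)))),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(paths, manifest = manifest_path)
}

#' Seeded random cohort split
#'
#' Utility for splitting one cohort's sample ids into training and internal
#' testing sets of given sizes (no claim is made about matching any
#' particular historical split).
#'
#' @param sample_ids character vector.
#' @param n_train training-set size.
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_cohort <- function(sample_ids, n_train, seed = 1L) {
  stopifnot(n_train >= 1L, n_train < length(sample_ids))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  tr <- sample(sample_ids, n_train)
  list(train = tr, test = setdiff(sample_ids, tr))
}
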