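#' Simulation design for the synthetic study
#'
#' Parameters of the synthetic paired-tissue and survival-cohort generator.
#' Defaults mirror the study structure the package is built around: 21
#' tumour/normal pairs for the expression arm, a 67-patient training cohort,
#' ~15% differentially expressed features at 1.5 log2-fold, a planted
#' prognostic pair with coefficients -0.26 and +0.09 (the magnitude of
#' published two-feature signature weights), exponential baseline hazard
#' with a ~9-month median progression-free survival, and ~25% censoring.
#'
#' @param n_features number of expression features.
#' @param n_pairs tumour/normal pairs in the paired-tissue arm.
#' @param n_patients patients in the survival cohort arm.
#' @param de_fraction fraction of features differentially expressed.
#' @param log2_fold_effect tumour-vs-normal shift (log2 units) of DE
#'   features (half up, half down).
#' @param feature_sd residual standard deviation of expression (log2 units).
#' @param planted_beta named vector of true log-hazard coefficients (names
#'   must be feature ids).
#' @param baseline_hazard_scale Weibull scale (months).
#' @param weibull_shape Weibull shape (1 = exponential).
#' @param censor_rate_target target fraction censored, in \[0, 1).
#' @param response_link_slope slope of the ordinal-logit link from the true
#'   linear predictor to the response category (higher risk => more PD).
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(n_features = 200L,
                              n_pairs = 21L,
                              n_patients = 67L,
                              de_fraction = 0.15,
                              log2_fold_effect = 1.5,
                              feature_sd = 0.8,
                              planted_beta = c(f001 = -0.26, f002 = 0.09),
                              baseline_hazard_scale = 13,
                              weibull_shape = 1,
                              censor_rate_target = 0.25,
                              response_link_slope = 1) {
  d <- list(n_features = as.integer(n_features), n_pairs = as.integer(n_pairs),
            n_patients = as.integer(n_patients),
            de_fraction = de_fraction, log2_fold_effect = log2_fold_effect,
            feature_sd = feature_sd, planted_beta = planted_beta,
            baseline_hazard_scale = baseline_hazard_scale,
            weibull_shape = weibull_shape,
            censor_rate_target = censor_rate_target,
            response_link_slope = response_link_slope)
  stopifnot(d$n_features >= 2L, d$feature_sd > 0, d$baseline_hazard_scale > 0,
            d$weibull_shape > 0, d$censor_rate_target >= 0,
            d$censor_rate_target < 1)
  feat <- feature_ids(d$n_features)
  bad <- setdiff(names(d$planted_beta), feat)
  if (length(bad)) stop("planted_beta names not among feature ids: ",
                        paste(bad, collapse = ", "))
  class(d) <- "simulation_design"
  d
}

feature_ids <- function(n) sprintf("f%03d", seq_len(n))

# Baseline log2 feature means of the cohort arm. Drawn from a fixed stream so
# that every cohort simulated from the same design shares its feature scale
# (training and validation cohorts of one study measure the same assays);
# per-seed randomness enters through patient-level noise only.
cohort_feature_means <- function(n_features) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(104729L)
  runif(n_features, 2, 10)
}

#' Simulate paired tumour/normal expression
#'
#' Log2-scale expression for `n_pairs` tumour/normal pairs with a shared
#' within-pair effect (so tumour-minus-normal differences have standard
#' deviation `feature_sd * sqrt(2)`). A `de_fraction` of features is shifted
#' by `+/- log2_fold_effect` in tumour (half up, half down); the rest share
#' their mean across tissues.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed.
#' @return list: `expression` (features x 2*n_pairs matrix), `pairing`
#'   (data frame `pair_id`/`tumour`/`normal`), `ground_truth` (list with
#'   `de_up`, `de_down`, `de_features`).
#' @export
simulate_paired_tissues <- function(design, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$n_pairs < 3L) stop("need n_pairs >= 3")
  n_de <- round(design$de_fraction * design$n_features)
  if (n_de < 1) stop("de_fraction * n_features must be at least 1")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  nf <- design$n_features
  np <- design$n_pairs
  feat <- feature_ids(nf)
  mu <- runif(nf, 6, 12)
  delta <- numeric(nf)
  n_up <- ceiling(n_de / 2)
  de_idx <- seq_len(n_de)
  delta[de_idx[seq_len(n_up)]] <- design$log2_fold_effect
  delta[de_idx[-seq_len(n_up)]] <- -design$log2_fold_effect
  pair_eff <- matrix(rnorm(nf * np, sd = design$feature_sd), nf, np)
  tum <- mu + pair_eff + delta +
    matrix(rnorm(nf * np, sd = design$feature_sd), nf, np)
  nor <- mu + pair_eff +
    matrix(rnorm(nf * np, sd = design$feature_sd), nf, np)
  tum_ids <- sprintf("P%02d_T", seq_len(np))
  nor_ids <- sprintf("P%02d_N", seq_len(np))
  expr <- cbind(tum, nor)
  dimnames(expr) <- list(feat, c(tum_ids, nor_ids))
  gt <- list(de_up = feat[delta > 0], de_down = feat[delta < 0],
             de_features = feat[delta != 0])
  list(expression = expr,
       pairing = data.frame(pair_id = sprintf("P%02d", seq_len(np)),
                            tumour = tum_ids, normal = nor_ids,
                            stringsAsFactors = FALSE),
       ground_truth = gt)
}

#' Simulate a survival cohort with planted prognostic features
#'
#' Expression is drawn on the `log2(10000 * 2^-dCt)` scale (feature means
#' uniform on 2-10, residual sd `feature_sd`). Event times follow a Weibull
#' proportional-hazards model, `S(t|x) = exp(-(t/b)^a * exp(lp))` with
#' `lp = sum_j beta_j (x_j - mu_j)` over the planted features. Censoring is
#' an independent exponential (rate calibrated numerically to hit
#' `censor_rate_target`) truncated at a 60-month administrative horizon;
#' a target of 0 disables censoring entirely. The best-response category is
#' drawn from an ordinal logit on the true linear predictor with cutpoints
#' giving roughly 34% CR+PR / 46% SD / 20% PD at baseline risk.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed.
#' @param n_patients optional override of `design$n_patients` (e.g. for
#'   validation cohorts).
#' @param id_prefix sample-id prefix.
#' @return list: `expression` (features x patients, log2 scale), `clinical`
#'   (`clinical_cohort`), `ground_truth` (planted coefficients, true linear
#'   predictor, censoring rate achieved).
#' @export
simulate_cohort <- function(design, seed = 1L, n_patients = NULL,
                            id_prefix = "S") {
  stopifnot(inherits(design, "simulation_design"))
  n <- if (is.null(n_patients)) design$n_patients else as.integer(n_patients)
  if (n < 10L) stop("need n_patients >= 10")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  nf <- design$n_features
  feat <- feature_ids(nf)
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  mu <- cohort_feature_means(nf)
  X <- mu + matrix(rnorm(nf * n, sd = design$feature_sd), nf, n)
  dimnames(X) <- list(feat, ids)
  beta <- design$planted_beta
  lp <- if (length(beta)) {
    drop(crossprod(X[names(beta), , drop = FALSE] - mu[match(names(beta), feat)],
                   beta))
  } else rep(0, n)
  if (all(beta == 0) && design$response_link_slope != 0 && length(beta)) {
    warning("planted_beta is all zero: response categories are uninformative")
  }
  a <- design$weibull_shape
  b <- design$baseline_hazard_scale
  t_event <- b * (-log(runif(n)) * exp(-lp))^(1 / a)
  t_event <- pmax(t_event, 1e-6)
  if (design$censor_rate_target > 0) {
    t_admin <- 60
    rate <- censoring_rate_for_target(lp, a, b, t_admin,
                                      design$censor_rate_target)
    cens <- pmin(rexp(n, rate), t_admin)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  cuts <- stats::qlogis(c(0.03, 0.34, 0.80))
  s <- design$response_link_slope
  u <- runif(n)
  p1 <- stats::plogis(cuts[1] - s * lp)
  p2 <- stats::plogis(cuts[2] - s * lp)
  p3 <- stats::plogis(cuts[3] - s * lp)
  response <- ifelse(u < p1, "CR", ifelse(u < p2, "PR",
                                          ifelse(u < p3, "SD", "PD")))
  clinical <- as_clinical_cohort(data.frame(
    sample_id = ids, pfs_months = time, event = event, response = response,
    stringsAsFactors = FALSE))
  gt <- list(prognostic_features = names(beta),
             true_beta = beta,
             linear_predictor = setNames(lp, ids),
             censoring_rate = mean(event == 0))
  list(expression = X, clinical = clinical, ground_truth = gt)
}

# Calibrate the exponential censoring rate so that the expected censoring
# fraction (exponential truncated at t_admin, competing with the Weibull-PH
# event times of this cohort's linear predictors) hits the target.
censoring_rate_for_target <- function(lp, shape, scale, t_admin, target) {
  grid <- seq(0, t_admin, length.out = 600L)
  # survival of T for each patient on the grid: n x length(grid)
  St <- exp(-outer(exp(lp), (grid / scale)^shape))
  censor_frac <- function(rate) {
    dens <- rate * exp(-rate * grid)                  # censoring density
    integrand <- sweep(St, 2L, dens, "*")
    p_before <- apply(integrand, 1L, function(y) {
      sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
    })
    p_admin <- exp(-rate * t_admin) * St[, length(grid)]
    mean(p_before + p_admin) - target
  }
  lo <- 1e-6
  hi <- 2
  if (censor_frac(lo) > 0) return(lo)  # administrative censoring alone exceeds target
  stats::uniroot(censor_frac, c(lo, hi), tol = 1e-6)$root
}

#' Write a complete synthetic fixture set
#'
#' Emits the four pipeline-readable files (paired expression, pairing map,
#' cohort expression on the raw relative 2^-dCt scale, clinical table) plus
#' the ground-truth JSON, which no pipeline stage reads.
#'
#' @param out_dir output directory.
#' @param design a [simulation_design()].
#' @param seed master seed; the two arms use derived child seeds.
#' @param force overwrite a non-empty directory.
#' @return invisible character vector of file paths (the manifest).
#' @export
write_fixture_set <- function(out_dir, design = simulation_design(),
                              seed = 1L, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory is not empty (use force = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paired <- simulate_paired_tissues(design, seed = child_seed(seed, 1L))
  cohort <- simulate_cohort(design, seed = child_seed(seed, 2L))
  files <- c(
    expression_paired = file.path(out_dir, "expression_paired.tsv"),
    pairing = file.path(out_dir, "pairing.tsv"),
    expression_cohort = file.path(out_dir, "expression_cohort_relative.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  write_expression(paired$expression, files[["expression_paired"]])
  write_pairing(paired$pairing, files[["pairing"]])
  # inverse of the qPCR normalization: back to relative 2^-dCt values
  write_expression(2^cohort$expression / 10000, files[["expression_cohort"]])
  write_clinical(cohort$clinical, files[["clinical"]])
  jsonlite::write_json(
    list(paired = paired$ground_truth,
         cohort = cohort$ground_truth[c("prognostic_features", "true_beta",
                                        "censoring_rate")]),
    files[["ground_truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
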