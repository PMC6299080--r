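test_that("paired-tissue simulation is deterministic and structured", {
  des <- simulation_design(n_features = 50, n_pairs = 6)
  s1 <- simulate_paired_tissues(des, seed = 7)
  s2 <- simulate_paired_tissues(des, seed = 7)
  expect_identical(s1$expression, s2$expression)
  s3 <- simulate_paired_tissues(des, seed = 8)
  expect_false(identical(s1$expression, s3$expression))
  expect_equal(dim(s1$expression), c(50, 12))
  expect_equal(nrow(s1$pairing), 6)
  expect_length(s1$ground_truth$de_features, round(0.15 * 50))
  expect_error(simulate_paired_tissues(
    simulation_design(n_features = 50, de_fraction = 0.001), seed = 1),
    "at least 1")
  expect_error(simulate_paired_tissues(
    simulation_design(n_pairs = 2), seed = 1), "n_pairs")
})

test_that("null paired simulation flags about 5% of features at p < 0.05", {
  des <- simulation_design(n_features = 200, log2_fold_effect = 0)
  rates <- vapply(1:20, function(r) {
    s <- simulate_paired_tissues(des, seed = 100 + r)
    de <- moderated_t(paired_t(s$expression, s$pairing))
    length(call_de(de, alpha = 0.05, use_fdr = FALSE)$called) / 200
  }, numeric(1))
  # binomial 95% band around 0.05 for 20 x 200 draws
  expect_lt(abs(mean(rates) - 0.05), 2 * sqrt(0.05 * 0.95 / (20 * 200)) + 0.01)
  # with FDR control on a global null, calls are (almost) never made
  s <- simulate_paired_tissues(des, seed = 500)
  de <- moderated_t(paired_t(s$expression, s$pairing))
  expect_lte(length(call_de(de, alpha = 0.05, use_fdr = TRUE)$called), 2)
})

test_that("planted fold-changes are recovered at FDR < 0.05 with high power", {
  des <- simulation_design()   # 200 features, 21 pairs, 1.5 log2-fold
  s <- simulate_paired_tissues(des, seed = 7)
  de <- moderated_t(paired_t(s$expression, s$pairing))
  calls <- call_de(de, alpha = 0.05, use_fdr = TRUE)
  truth <- s$ground_truth$de_features
  expect_gte(length(intersect(calls$called, truth)) / length(truth), 0.9)
  expect_setequal(intersect(calls$up, truth), s$ground_truth$de_up)
})

test_that("cohort survival times follow the planted hazards", {
  # Cox refit on the true features recovers the planted coefficients
  des <- simulation_design(planted_beta = c(f001 = -0.26, f002 = 0.09))
  s <- simulate_cohort(des, seed = 11, n_patients = 300)
  X <- t(s$expression[c("f001", "f002"), ])
  fit <- fit_cox(s$clinical$pfs_months, s$clinical$event, X)
  expect_lt(max(abs(fit$coefficients - c(-0.26, 0.09))), 0.15)
})

test_that("censoring calibration hits its target and zero disables it", {
  des <- simulation_design(censor_rate_target = 0.25)
  s <- simulate_cohort(des, seed = 13, n_patients = 1000)
  expect_lt(abs(mean(s$clinical$event == 0) - 0.25), 0.1)
  s0 <- simulate_cohort(simulation_design(censor_rate_target = 0),
                        seed = 13, n_patients = 100)
  expect_true(all(s0$clinical$event == 1))
})

test_that("null cohort calibrates the univariate Cox screen near alpha", {
  des <- simulation_design(n_features = 100,
                           planted_beta = setNames(numeric(0), character(0)))
  rates <- vapply(1:10, function(r) {
    s <- simulate_cohort(des, seed = 200 + r, n_patients = 150)
    scr <- univariate_cox_screen(s$expression, s$clinical, alpha = 0.1)
    length(scr$kept) / 100
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.1), 2 * sqrt(0.1 * 0.9 / 1000) + 0.015)
})

test_that("response categories shift toward PD with risk", {
  des <- simulation_design(planted_beta = c(f001 = -2, f002 = 1.2))
  s <- simulate_cohort(des, seed = 17, n_patients = 2000)
  lp <- s$ground_truth$linear_predictor
  pd <- s$clinical$response == "PD"
  expect_gt(mean(lp[pd]), mean(lp[!pd]))
  # approximate target mix at baseline risk
  s0 <- simulate_cohort(simulation_design(
    planted_beta = setNames(numeric(0), character(0)),
    response_link_slope = 0), seed = 18, n_patients = 4000)
  mix <- prop.table(table(factor(
    ifelse(s0$clinical$response %in% c("CR", "PR"), "CR+PR",
           s0$clinical$response), levels = c("CR+PR", "SD", "PD"))))
  expect_equal(unname(mix[["CR+PR"]]), 0.34, tolerance = 0.05)
  expect_equal(unname(mix[["SD"]]), 0.46, tolerance = 0.05)
  expect_equal(unname(mix[["PD"]]), 0.20, tolerance = 0.05)
})

test_that("an all-zero planted beta with a response link warns", {
  des <- simulation_design(planted_beta = c(f001 = 0, f002 = 0))
  expect_warning(simulate_cohort(des, seed = 1), "uninformative")
})

test_that("fixture sets are written, re-readable, and seed-sensitive", {
  dir1 <- withr::local_tempdir()
  files <- write_fixture_set(file.path(dir1, "fx"), seed = 3)
  expect_length(files, 5)
  expect_true(all(file.exists(files)))
  pe <- read_expression(files[["expression_paired"]])
  pr <- read_pairing(files[["pairing"]])
  ce <- read_expression(files[["expression_cohort"]])
  cl <- read_clinical(files[["clinical"]])
  expect_equal(ncol(pe), 2 * 21)
  expect_true(all(ce > 0))                 # relative 2^-dCt scale
  expect_setequal(colnames(ce), cl$sample_id)
  expect_error(write_fixture_set(file.path(dir1, "fx"), seed = 3),
               "not empty")
  # different seed, different content
  files2 <- write_fixture_set(file.path(dir1, "fx2"), seed = 4)
  expect_false(unname(tools::md5sum(files[["clinical"]])) ==
                 unname(tools::md5sum(files2[["clinical"]])))
})
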