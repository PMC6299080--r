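paper_signature <- function() {
  rmipsig:::new_risk_signature(c("miR-125b-2-3p", "miR-933"),
                               c(-0.259, 0.092), cutoff = 0.022,
                               ties_method = "breslow")
}

test_that("risk score is the published linear combination", {
  sig <- paper_signature()
  x <- c("miR-125b-2-3p" = 1, "miR-933" = 1)
  expect_equal(unname(risk_score(sig, x)), 0.092 - 0.259, tolerance = 1e-12)
  x2 <- c("miR-125b-2-3p" = 2.5, "miR-933" = 4.0)
  expect_equal(unname(risk_score(sig, x2)), 0.092 * 4 - 0.259 * 2.5,
               tolerance = 1e-12)
  expect_equal(unname(risk_score(sig, c("miR-125b-2-3p" = 0, "miR-933" = 0))),
               0)
  expect_error(risk_score(sig, c("miR-933" = 1)), "miR-125b-2-3p")
  # linearity in the expression vector
  set.seed(1)
  v <- c("miR-125b-2-3p" = rnorm(1), "miR-933" = rnorm(1))
  expect_equal(unname(risk_score(sig, 3 * v)),
               3 * unname(risk_score(sig, v)), tolerance = 1e-12)
})

test_that("classification at the cutoff follows the <=/> boundary rule", {
  a <- classify_risk(c(p1 = -0.1, p2 = 0.022, p3 = 0.5), cutoff = 0.022)
  expect_equal(as.character(a$group), c("low", "low", "high"))
  # shifting scores and cutoff together changes nothing
  b <- classify_risk(c(p1 = -0.1, p2 = 0.022, p3 = 0.5) + 5, cutoff = 5.022)
  expect_equal(a$group, b$group)
})

test_that("the training median split balances group sizes", {
  set.seed(23)
  for (n in c(10, 11, 67, 100)) {
    scores <- setNames(rnorm(n), sprintf("s%d", 1:n))
    a <- classify_risk(scores, cutoff = median(scores))
    expect_lte(abs(sum(a$group == "low") - sum(a$group == "high")), 1)
  }
})

test_that("signature refit recovers planted coefficients and the median cutoff", {
  des <- simulation_design(planted_beta = c(f001 = -0.26, f002 = 0.09))
  est <- vapply(31:35, function(sd) {
    s <- simulate_cohort(des, seed = sd, n_patients = 300)
    fit_signature(s$expression, s$clinical, c("f001", "f002"))$coefficients
  }, numeric(2))
  expect_lt(max(abs(rowMeans(est) - c(-0.26, 0.09))), 0.15)
  s <- simulate_cohort(des, seed = 31, n_patients = 300)
  sig <- fit_signature(s$expression, s$clinical, c("f001", "f002"))
  scores <- risk_score(sig, s$expression)
  expect_equal(sig$cutoff, median(scores), tolerance = 1e-12)
  # single-feature signature is valid
  sig1 <- fit_signature(s$expression, s$clinical, "f001")
  expect_length(sig1$coefficients, 1)
  # cutoff of scores (-1, 0, 1) is the middle order statistic
  expect_equal(median(c(-1, 0, 1)), 0)
  expect_error(fit_signature(s$expression, s$clinical, c("f001", "nope")),
               "nope")
})

test_that("progressive rates are exact fractions displayed to 2 decimals", {
  counts <- matrix(c(15, 11, 4, 8, 20, 9), nrow = 3,
                   dimnames = list(c("CR+PR", "SD", "PD"), c("low", "high")))
  pr <- progressive_rate(counts)
  expect_equal(as.numeric(pr), c(13.33, 24.32))
  expect_equal(unname(attr(pr, "fraction")), c(4 / 30, 9 / 37),
               tolerance = 1e-15)
  zero <- counts; zero["PD", ] <- 0L
  expect_equal(as.numeric(progressive_rate(zero)), c(0, 0))
  expect_error(progressive_rate(counts[1:2, ]), "PD")
})

test_that("chi-square/Fisher dispatch and values are correct", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r <- chisq_or_fisher(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$method, "chisq")
  # small expected cells switch to Fisher, which matches enumeration
  tab <- matrix(c(1, 8, 9, 2), 2)
  r2 <- chisq_or_fisher(tab)
  expect_equal(r2$method, "fisher")
  expect_equal(r2$p, fisher_oracle(tab), tolerance = 1e-9)
  # Pearson X2 scales linearly in the counts
  big <- matrix(c(30, 10, 15, 25), 2)
  r3 <- chisq_or_fisher(big)
  r6 <- chisq_or_fisher(2 * big)
  expect_equal(r6$statistic, 2 * r3$statistic, tolerance = 1e-12)
  expect_error(chisq_or_fisher(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("Fisher p matches hypergeometric enumeration on random tables", {
  set.seed(55)
  done <- 0
  while (done < 500) {
    tab <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || sum(tab) > 30) next
    expect_equal(stats::fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-9)
    done <- done + 1
  }
})

test_that("time-dependent AUC is 1 for perfect scores and 0.5 under the null", {
  set.seed(61)
  time <- rexp(120) + 0.1
  # perfectly concordant: score = -time, no censoring
  r <- td_auc(-time, time, rep(1, 120), t = median(time), boot = 0)
  expect_equal(r$auc, 1)
  # random scores: AUC near 1/2
  r2 <- td_auc(rnorm(500), rexp(500) + 0.1, rbinom(500, 1, 0.8),
               t = 0.7, boot = 0)
  expect_lt(abs(r2$auc - 0.5), 0.1)
})

test_that("IPCW equals the naive AUC exactly when nothing is censored", {
  set.seed(62)
  n <- 80
  time <- rexp(n) + 0.1
  scores <- -time + rnorm(n)
  a1 <- td_auc(scores, time, rep(1, n), t = median(time), boot = 0,
               estimator = "ipcw")
  a2 <- td_auc(scores, time, rep(1, n), t = median(time), boot = 0,
               estimator = "naive")
  expect_equal(a1$auc, a2$auc, tolerance = 1e-12)
  expect_error(td_auc(scores, time, rep(1, n), t = min(time) / 2, boot = 0),
               "no cases")
})

test_that("KM-by-risk evaluation separates a planted group effect", {
  set.seed(70)
  n <- 150
  group <- rep(c("low", "high"), length.out = n)
  lp <- ifelse(group == "high", log(2.8), 0)
  time <- rexp(n, 0.08 * exp(lp))
  cl <- as_clinical_cohort(data.frame(
    sample_id = sprintf("p%03d", 1:n), pfs_months = time,
    event = rep(1, n), stringsAsFactors = FALSE))
  assignment <- structure(
    data.frame(sample_id = cl$sample_id, score = lp,
               group = factor(group, levels = c("low", "high")),
               stringsAsFactors = FALSE),
    class = c("risk_assignment", "data.frame"))
  ev <- evaluate_km_by_risk(assignment, cl)
  expect_gt(ev$km$low$median, ev$km$high$median)
  expect_lt(ev$logrank$p, 0.01)
  # identical event-time multisets in both groups give a null statistic
  cl2 <- cl
  cl2$pfs_months <- rep(cl$pfs_months[1:(n / 2)], times = 2)
  assignment2 <- assignment
  assignment2$group <- factor(rep(c("low", "high"), each = n / 2),
                              levels = c("low", "high"))
  ev2 <- evaluate_km_by_risk(assignment2, cl2)
  expect_lt(ev2$logrank$statistic, 1e-9)
})
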