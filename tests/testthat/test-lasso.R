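make_surv_design <- function(n, p, beta = NULL, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  lp <- if (is.null(beta)) rep(0, n) else
    drop(x[, seq_along(beta), drop = FALSE] %*% beta)
  time <- rexp(n, 0.1 * exp(lp))
  event <- rbinom(n, 1, 0.8)
  if (sum(event) == 0) event[1] <- 1
  list(x = x, time = time, event = event)
}

test_that("qPCR normalization is the exact log2(10000 x) map", {
  expect_equal(normalize_qpcr(1), log2(10000), tolerance = 1e-12)
  expect_equal(normalize_qpcr(0.0001), 0, tolerance = 1e-12)
  expect_equal(normalize_qpcr(0.37), log2(3700), tolerance = 1e-12)
  m <- matrix(c(1, 0.5, -1, 2), 2, 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  expect_error(normalize_qpcr(m), "r1.*c2")
  expect_error(normalize_qpcr(c(0.1, 0)), "position 2")
})

test_that("all coefficients are exactly zero at lambda >= lambda_max", {
  d <- make_surv_design(50, 10, beta = c(0.8, -0.5), seed = 2)
  path <- lasso_cox_path(d$time, d$event, d$x)
  expect_identical(unname(path$beta[, 1]), rep(0, 10))
  bigger <- lasso_cox_path(d$time, d$event, d$x,
                           lambda = path$lambda_max * c(3, 2, 1))
  expect_true(all(bigger$beta == 0))
})

test_that("KKT conditions hold along the path within 1e-6", {
  for (s in 1:5) {
    d <- make_surv_design(45, 12, beta = c(1, -0.7, 0.4), seed = 10 + s)
    path <- lasso_cox_path(d$time, d$event, d$x)
    expect_lt(path$kkt_max_violation, 1e-6)
  }
})

test_that("the path at lambda -> 0 matches the unpenalized Newton fit", {
  d <- make_surv_design(60, 5, beta = c(0.7, -0.5), seed = 3)
  path <- lasso_cox_path(d$time, d$event, d$x, nlambda = 60,
                         lambda_min_ratio = 1e-4)
  newton <- fit_cox(d$time, d$event, d$x)
  expect_lt(max(abs(path$beta[, 60] - newton$coefficients)), 1e-3)
})

test_that("path coefficients agree with an independent penalized fitter", {
  skip_if_not_installed("glmnet")
  skip_if_not_installed("survival")
  for (s in 1:3) {
    d <- make_surv_design(55, 9, beta = c(0.9, -0.6), seed = 40 + s)
    path <- lasso_cox_path(d$time, d$event, d$x, nlambda = 40,
                           lambda_min_ratio = 0.05)
    ref <- glmnet::glmnet(d$x, survival::Surv(d$time, d$event),
                          family = "cox", lambda = path$lambda,
                          standardize = TRUE, thresh = 1e-14)
    expect_lt(max(abs(path$beta - as.matrix(coef(ref)))), 1e-4)
  }
})

test_that("a single strong feature is the first to enter the path", {
  d <- make_surv_design(60, 21, beta = c(1), seed = 5)
  path <- lasso_cox_path(d$time, d$event, d$x)
  first_nonzero <- apply(path$beta != 0, 1, function(r) {
    w <- which(r); if (length(w)) min(w) else Inf
  })
  expect_equal(names(which.min(first_nonzero)), "f01")
})

test_that("cv_lasso is reproducible and honours its invariants", {
  d <- make_surv_design(60, 12, beta = c(1.2, -0.8), seed = 6)
  cv1 <- cv_lasso(d$time, d$event, d$x, folds = 5, seed = 9)
  cv2 <- cv_lasso(d$time, d$event, d$x, folds = 5, seed = 9)
  expect_identical(cv1$fold_id, cv2$fold_id)
  expect_identical(cv1$mean_dev, cv2$mean_dev)
  expect_identical(cv1$selected, cv2$selected)
  expect_gte(cv1$lambda_1se, cv1$lambda_min)
  i_min <- cv1$index_min
  expect_lte(cv1$mean_dev[cv1$index_1se],
             cv1$mean_dev[i_min] + cv1$se_dev[i_min] + 1e-12)
})

test_that("RMIP is pure arithmetic on recorded selections", {
  counts <- c(a = 3L, b = 1L, z = 0L)
  rm <- rmipsig:::new_rmip_table(counts, B = 4L)
  expect_equal(rm$rmip[match(c("a", "b", "z"), rm$feature_id)],
               c(0.75, 0.25, 0))
  expect_true(all(rm$rmip * rm$B == rm$count))
  expect_setequal(rm$rank, 1:3)
})

test_that("bag_lasso with B = 1 equals one seed-matched bootstrap cv run", {
  d <- make_surv_design(50, 8, beta = c(1.1), seed = 7)
  rm <- bag_lasso(d$time, d$event, d$x, B = 1, folds = 5, seed = 3)
  sb <- child_seed(child_seed(3, 1), 1)
  set.seed(sb)
  idx <- sample.int(50, 50, replace = TRUE)
  cv <- cv_lasso(d$time[idx], d$event[idx], d$x[idx, ],
                 folds = 5, seed = child_seed(sb, 2), tol = 1e-5)
  expect_setequal(rm$feature_id[rm$count == 1], cv$selected)
})

test_that("zero-variance features never get selected and RMIP is equivariant", {
  d <- make_surv_design(50, 6, beta = c(1.3), seed = 8)
  d$x[, 4] <- 5  # constant column
  rm <- bag_lasso(d$time, d$event, d$x, B = 10, folds = 5, seed = 2)
  expect_equal(rm$rmip[rm$feature_id == "f04"], 0)
  # permuting feature columns permutes RMIP identically
  perm <- c(3, 1, 2, 6, 5, 4)
  rm_p <- bag_lasso(d$time, d$event, d$x[, perm], B = 10, folds = 5, seed = 2)
  expect_equal(setNames(rm_p$rmip, rm_p$feature_id)[rm$feature_id],
               setNames(rm$rmip, rm$feature_id))
})

test_that("top-k selection follows RMIP order with documented tie-breaks", {
  rm <- rmipsig:::new_rmip_table(c(w = 9L, x = 8L, y = 2L, z = 1L), B = 10L)
  top <- select_top_features(rm, 2, elbow = TRUE)
  expect_equal(as.character(top[1:2]), c("w", "x"))
  expect_equal(attr(top, "suggested_k"), 2)  # largest drop 0.8 -> 0.2
  # tie at rank k: lexicographically smaller id kept, with a message
  rm2 <- rmipsig:::new_rmip_table(c(b = 5L, a = 5L, c = 1L), B = 10L)
  expect_message(top2 <- select_top_features(rm2, 1), "lexicographically")
  expect_equal(as.character(top2), "a")
  # k equal to feature count: identity ordering by RMIP
  expect_equal(as.character(select_top_features(rm, 4)),
               c("w", "x", "y", "z"))
  rm0 <- rmipsig:::new_rmip_table(c(a = 0L, b = 0L), B = 5L)
  expect_error(select_top_features(rm0, 1), "zero")
})
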