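make_paired <- function(diffs_by_feature, base = 8) {
  # build an expression matrix whose tumour-minus-normal differences are the
  # given per-feature vectors
  nf <- length(diffs_by_feature)
  np <- length(diffs_by_feature[[1]])
  tum <- base + do.call(rbind, diffs_by_feature)
  nor <- matrix(base, nf, np)
  expr <- cbind(tum, nor)
  dimnames(expr) <- list(names(diffs_by_feature) %||%
                           sprintf("g%d", seq_len(nf)),
                         c(sprintf("P%d_T", 1:np), sprintf("P%d_N", 1:np)))
  list(expr = expr,
       pairing = data.frame(pair_id = sprintf("P%d", 1:np),
                            tumour = sprintf("P%d_T", 1:np),
                            normal = sprintf("P%d_N", 1:np)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("paired t reproduces the hand-computed statistic", {
  dat <- make_paired(list(a = c(1, 2, 3), b = c(0, 0, 0), c = c(2, 2, 2)))
  de <- paired_t(dat$expr, dat$pairing)
  # differences (1,2,3): mean 2, sd 1, t = 2 / (1/sqrt(3)) = 2*sqrt(3)
  expect_equal(de$t[de$feature_id == "a"], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(de$df[1], 2)
  expect_equal(de$p[de$feature_id == "a"],
               2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  # all-zero differences: zero variance, p reported as 1 and flagged
  expect_true(de$zero_var[de$feature_id == "b"])
  expect_equal(de$p[de$feature_id == "b"], 1)
  # constant nonzero difference is also zero-variance
  expect_true(de$zero_var[de$feature_id == "c"])
})

test_that("paired t is invariant to pair relabeling and errors on broken pairs", {
  set.seed(2)
  dat <- make_paired(lapply(1:5, function(i) rnorm(6)))
  de1 <- paired_t(dat$expr, dat$pairing)
  perm <- dat$pairing[sample(6), ]
  de2 <- paired_t(dat$expr, perm)
  expect_equal(de1$p, de2$p, tolerance = 1e-12)
  broken <- dat$pairing
  broken$normal[2] <- "absent_sample"
  expect_error(paired_t(dat$expr, broken), "P2")
})

test_that("moderated t reduces to the classical t at d0 = 0 and pools at d0 = Inf", {
  set.seed(5)
  dat <- make_paired(lapply(1:40, function(i) rnorm(8, sd = runif(1, .5, 2))))
  de <- paired_t(dat$expr, dat$pairing)
  m0 <- moderated_t(de, d0 = 0, s02 = 1)
  expect_equal(m0$t_mod, m0$t, tolerance = 1e-15)
  expect_equal(m0$p_mod, m0$p, tolerance = 1e-15)
  mInf <- moderated_t(de, d0 = Inf, s02 = 2)
  # common denominator: moderated t proportional to the mean difference
  ratio <- mInf$t_mod / mInf$mean_diff
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("moderated-t hyperparameters match limma and recover truth", {
  skip_if_not_installed("limma")
  set.seed(31)
  # hierarchical truth: s2_g ~ s02 * d0 / chisq(d0), data with df = 7
  nf <- 500; np <- 8; d0_true <- 6; s02_true <- 1.44
  s2g <- s02_true * d0_true / rchisq(nf, d0_true)
  diffs <- lapply(sqrt(s2g), function(s) rnorm(np, sd = s))
  dat <- make_paired(diffs)
  de <- moderated_t(paired_t(dat$expr, dat$pairing))
  expect_lt(abs(attr(de, "d0") - d0_true) / d0_true, 0.25)
  expect_lt(abs(attr(de, "s02") - s02_true) / s02_true, 0.25)
  # cross-check the whole moderated pipeline against limma
  d <- dat$expr[, dat$pairing$tumour] - dat$expr[, dat$pairing$normal]
  lf <- limma::eBayes(limma::lmFit(d))
  expect_equal(attr(de, "d0"), lf$df.prior, tolerance = 0.02)
  expect_equal(attr(de, "s02"), lf$s2.prior, tolerance = 0.02)
  expect_equal(de$t_mod, unname(lf$t[, 1]), tolerance = 1e-3)
})

test_that("BH step-up matches its definition, brute force and p.adjust", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(numeric(0)), "empty")
  set.seed(77)
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- runif(m)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
  p <- runif(200)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("call_de splits by direction and respects the threshold switch", {
  set.seed(9)
  up <- lapply(1:10, function(i) rnorm(10, mean = 3))
  null <- lapply(1:50, function(i) rnorm(10))
  dat <- make_paired(c(up, null))
  de <- moderated_t(paired_t(dat$expr, dat$pairing))
  calls <- call_de(de, alpha = 0.05, use_fdr = TRUE)
  expect_gte(length(intersect(sprintf("g%d", 1:10), calls$up)), 9)
  # direction bookkeeping: every "up" call has a positive mean difference,
  # and any stray BH false positive among the nulls lands on its true side
  expect_true(all(de$mean_diff[match(calls$up, de$feature_id)] > 0))
  expect_true(all(de$mean_diff[match(calls$down, de$feature_id)] < 0))
  expect_lte(length(calls$down), 2)
  # at a stringent threshold the null side is silent
  strict <- call_de(de, alpha = 0.001, use_fdr = TRUE)
  expect_length(strict$down, 0)
  # feature order must not matter
  shuf <- sample(nrow(dat$expr))
  de2 <- moderated_t(paired_t(dat$expr[shuf, ], dat$pairing))
  calls2 <- call_de(de2, alpha = 0.05, use_fdr = TRUE)
  expect_setequal(calls$called, calls2$called)
})
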