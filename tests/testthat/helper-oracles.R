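# Independent brute-force oracles. These deliberately use naive O(n^2)/
# enumeration formulations so they share no code path with the package.

# 1-D Breslow partial likelihood, evaluated directly from its definition
breslow_loglik_naive <- function(beta, time, event, x) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# grid-search maximizer of the 1-covariate Breslow partial likelihood
cox_grid_oracle <- function(time, event, x, lo = -8, hi = 8, steps = 4001) {
  grid <- seq(lo, hi, length.out = steps)
  ll <- vapply(grid, breslow_loglik_naive, numeric(1),
               time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  # refine twice around the winner
  for (r in 1:2) {
    span <- (hi - lo) / steps * 4
    grid <- seq(b0 - span, b0 + span, length.out = 801)
    ll <- vapply(grid, breslow_loglik_naive, numeric(1),
                 time = time, event = event, x = x)
    b0 <- grid[which.max(ll)]
    steps <- 801
    lo <- min(grid); hi <- max(grid)
  }
  b0
}

# log-rank statistic assembled from the 2xK table at every event time
logrank_oracle <- function(time, event, group) {
  group <- as.factor(group)
  levs <- levels(droplevels(group))
  stopifnot(length(levs) == 2L)
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n1 <- sum(time >= t & group == levs[1])
    n2 <- sum(time >= t & group == levs[2])
    d1 <- sum(time == t & event == 1 & group == levs[1])
    d2 <- sum(time == t & event == 1 & group == levs[2])
    n <- n1 + n2; d <- d1 + d2
    O <- O + d1
    E <- E + n1 * d / n
    if (n > 1) V <- V + d * (n - d) / (n - 1) * n1 * n2 / n^2
  }
  if (V == 0) return(0)
  (O - E)^2 / V
}

# O(m^2) literal step-up: q_(i) = min_{j >= i} m p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration over all tables with the same margins
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive product-limit estimator at a time point
km_oracle_at <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1 & time <= at]))) {
    n_t <- sum(time >= t)
    d_t <- sum(time == t & event == 1)
    s <- s * (1 - d_t / n_t)
  }
  s
}

# simple survival data generator used across fuzz tests
rand_surv <- function(n, seed, p_event = 0.7, tie_fraction = 0) {
  set.seed(seed)
  time <- rexp(n) + 0.1
  if (tie_fraction > 0) time <- ceiling(time * 4) / 4
  event <- rbinom(n, 1, p_event)
  if (sum(event) == 0) event[sample(n, 1)] <- 1
  x <- rnorm(n)
  list(time = time, event = event, x = x)
}
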