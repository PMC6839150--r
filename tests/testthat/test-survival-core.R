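# Unit and property tests for the from-scratch survival statistics.
# The CRAN `survival` package serves as an extra cross-check oracle next to
# the independent constructions in helper-oracles.R.

test_that("km_estimate matches closed forms and conventions", {
  k <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(k$at_risk, c(3L, 2L, 1L))

  # censoring after the last event: no further drop
  k2 <- km_estimate(c(1, 2), c(1, 0))
  expect_equal(k2$event_times, 1)
  expect_equal(k2$survival, 0.5)

  # all censored: curve identically 1, median undefined, not an error
  k3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(k3$survival, 0)
  expect_true(is.na(km_median(k3)))

  # median convention: first event time with S <= 0.5
  expect_equal(km_median(km_estimate(1:4, rep(1, 4))), 2)
})

test_that("KM with zero censoring equals the empirical survival function", {
  set.seed(101)
  for (rep in 1:5) {
    t <- round(rexp(40, 0.5), 2) + 0.01
    k <- km_estimate(t, rep(1, 40))
    emp <- vapply(k$event_times, function(x) mean(t > x), 0)
    expect_equal(k$survival, emp, tolerance = 1e-12)
  }
})

test_that("KM agrees with the redistribute-to-the-right oracle under censoring", {
  set.seed(202)
  for (rep in 1:5) {
    t <- sample(1:20, 50, replace = TRUE) / 4 # induces ties
    e <- rbinom(50, 1, 0.6)
    if (sum(e) == 0) e[1] <- 1
    k <- km_estimate(t, e)
    o <- oracle_km_redistribute(t, e)
    expect_equal(k$event_times, o$event_times)
    expect_equal(k$survival, o$survival, tolerance = 1e-12)
  }
})

test_that("km_median recovers the analytic median of exponential lifetimes", {
  set.seed(7)
  t <- rexp(200, rate = log(2)) # analytic median = 1
  m <- km_median(km_estimate(t, rep(1, 200)))
  expect_lt(abs(m - 1), 0.15)
})

test_that("log-rank: symmetry, sign, and agreement with survival::survdiff", {
  # two identical groups -> chi = 0, p = 1
  t <- c(1, 2, 3, 4)
  e <- c(1, 0, 1, 1)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_equal(sum(lr$table$observed - lr$table$expected), 0, tolerance = 1e-10)

  # early-event group has positive observed - expected
  lr3 <- logrank_test(
    times = c(0.2, 0.4, 0.5, 3, 4, 5, 6, 7, 8),
    events = rep(1, 9),
    group = rep(c("early", "mid", "late"), each = 3)
  )
  expect_identical(lr3$df, 2L)
  tab <- lr3$table
  expect_gt(tab$observed[tab$group == "early"] - tab$expected[tab$group == "early"], 0)

  # cross-check chi-square and p against survival::survdiff on random data
  set.seed(33)
  for (rep in 1:5) {
    n <- 60
    tt <- rexp(n, 0.3)
    ee <- rbinom(n, 1, 0.7)
    gg <- sample(c("x", "y", "z"), n, replace = TRUE)
    mine <- logrank_test(tt, ee, gg)
    ref <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
    expect_equal(mine$chi_square, ref$chisq, tolerance = 1e-8)
  }
  expect_error(logrank_test(t, e, rep("a", 4)), "at least 2")
})

test_that("log-rank p-values are approximately uniform under the null", {
  set.seed(404)
  reps <- 1000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    t <- rexp(60, 0.4)
    e <- rbinom(60, 1, 0.75)
    if (sum(e) < 2) e[1:2] <- 1
    g <- rep(c(0, 1), each = 30)
    rej[i] <- logrank_test(t, e, g)$p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("cox_fit: symmetry, oracle agreement, and coxph cross-check", {
  # identical event patterns in both covariate levels -> beta ~ 0
  t <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x <- rep(c(0, 1), each = 4)
  f <- cox_fit(t, e, cbind(x = x))
  expect_lt(abs(f$table$coef), 1e-6)
  expect_equal(f$table$hr, 1, tolerance = 1e-5)

  # 8-patient toy data vs brute-force likelihood maximization
  t8 <- c(0.5, 1, 1, 2, 3, 3.5, 4, 5)
  e8 <- c(1, 1, 1, 0, 1, 1, 0, 1)
  x8 <- c(1, 0, 1, 1, 0, 1, 0, 0)
  f8 <- cox_fit(t8, e8, cbind(x = x8))
  b_oracle <- oracle_cox_beta(t8, e8, x8)
  expect_lt(abs(f8$table$coef - b_oracle), 1e-4)

  # agreement with survival::coxph (both tie methods, multiple covariates)
  set.seed(55)
  n <- 120
  X <- cbind(a = rbinom(n, 1, 0.4), b = rnorm(n), c = runif(n))
  tt <- round(rexp(n, exp(0.5 * X[, "a"] - 0.3 * X[, "b"])), 1) + 0.1
  ee <- rbinom(n, 1, 0.8)
  for (tie in c("efron", "breslow")) {
    mine <- cox_fit(tt, ee, X, ties = tie)
    ref <- survival::coxph(survival::Surv(tt, ee) ~ a + b + c,
                           data = data.frame(X), ties = tie)
    expect_equal(mine$table$coef, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(mine$table$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-8)
  }

  expect_error(cox_fit(t8, e8, cbind(k = rep(1, 8))), "constant covariate.*k")
})

test_that("cox_fit recovers a planted binary effect and flags separation", {
  set.seed(66)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.3 * exp(-0.8 * x))
  f <- cox_fit(t, rep(1, n), cbind(x = x))
  expect_lt(abs(f$table$coef - (-0.8)), 0.2)
  expect_true(f$converged)

  # perfect separation: all events in one level -> monotone likelihood
  ts <- c(1, 2, 3, 4, 10, 11, 12, 13)
  es <- c(1, 1, 1, 1, 0, 0, 0, 0)
  xs <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_warning(fs <- cox_fit(ts, es, cbind(x = xs)), "converge")
  expect_false(fs$converged)
})

test_that("cox score test at beta = 0 equals the log-rank chi-square", {
  set.seed(77)
  t <- sort(runif(30, 1, 10)) + seq(0, 0.29, by = 0.01) # untied
  e <- rbinom(30, 1, 0.8)
  g <- rbinom(30, 1, 0.5)
  if (sum(e) < 2 || length(unique(g)) < 2) skip("degenerate draw")
  f <- cox_fit(t, e, cbind(g = g))
  lr <- logrank_test(t, e, g)
  expect_equal(f$score_test, lr$chi_square, tolerance = 1e-6)
})

test_that("cox HR is invariant to rescaling time", {
  set.seed(88)
  n <- 80
  x <- rnorm(n)
  t <- rexp(n, exp(0.4 * x))
  e <- rbinom(n, 1, 0.7)
  f1 <- cox_fit(t, e, cbind(x = x))
  f2 <- cox_fit(t * 365.25, e, cbind(x = x))
  expect_equal(f1$table$hr, f2$table$hr, tolerance = 1e-8)
})

test_that("pearson_r matches the textbook formula and cor.test", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)

  set.seed(99)
  a <- rnorm(20)
  b <- 0.5 * a + rnorm(20)
  res <- pearson_r(a, b)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  ref <- cor.test(a, b)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("auc_mann_whitney: closed cases, pair enumeration, invariance", {
  expect_equal(auc_mann_whitney(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  expect_equal(auc_mann_whitney(rep(3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)

  set.seed(111)
  s <- sample(1:10, 30, replace = TRUE) # ties on purpose
  l <- rbinom(30, 1, 0.5)
  if (all(l == 0) || all(l == 1)) l[1:2] <- c(0, 1)
  mine <- auc_mann_whitney(s, l)
  expect_equal(mine$auc, oracle_auc_pairs(s, l), tolerance = 1e-12)

  # strictly monotone transform leaves AUC unchanged
  expect_equal(auc_mann_whitney(exp(s / 2), l)$auc, mine$auc)
  expect_error(auc_mann_whitney(1:5, rep(1, 5)), "non-empty")
})
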