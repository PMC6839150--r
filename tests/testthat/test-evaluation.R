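# helpers to make a scored cohort directly (bypassing screening)
make_scored <- function(scores_int, K = 25L) {
  df <- data.frame(sample_id = sprintf("P%03d", seq_along(scores_int)),
                   score = as.integer(scores_int),
                   n_genes_used = K, group = NA_character_)
  attr(df, "K") <- K
  attr(df, "genes_used") <- sprintf("G%02d", seq_len(K))
  class(df) <- c("ros_scores", "data.frame")
  suppressWarnings(assign_groups(df))
}

test_that("compare_groups: symmetry and agreement with the univariate Cox", {
  # two groups with identical survival -> HR = 1, chi-square = 0
  sc <- make_scored(c(rep(5, 10), rep(20, 10)))
  clin <- make_clin(rep(c(1, 2, 3, 4, 5), 4), rep(c(1, 1, 0, 1, 1), 4))
  cmp <- compare_groups(sc, clin)
  expect_equal(cmp$hr, 1, tolerance = 1e-6)
  expect_equal(cmp$logrank$chi_square, 0, tolerance = 1e-10)

  # consistency: equals multivariable fit with no extra covariates
  set.seed(12)
  sc2 <- make_scored(sample(0:25, 80, replace = TRUE))
  clin2 <- make_clin(rexp(80, 0.3), rbinom(80, 1, 0.8))
  cmp2 <- compare_groups(sc2, clin2)
  mc2 <- multivariable_cox(sc2, clin2, score_form = "categorical",
                           covariates = character(0))
  expect_equal(cmp2$hr, mc2$table$hr_multi[1], tolerance = 1e-10)

  # empty group
  sc3 <- make_scored(rep(3, 20))
  expect_error(compare_groups(sc3, make_clin(rexp(20, 0.3), rep(1, 20))),
               "empty")
})

test_that("compare_groups detects a planted protective score effect", {
  set.seed(22)
  hits <- 0L
  for (i in 1:15) {
    n <- 300
    s <- sample(0:25, n, replace = TRUE)
    grp_high <- s > 12.5
    t <- rexp(n, 0.25 * exp(-0.9 * grp_high))
    sc <- make_scored(s)
    clin <- make_clin(t, rbinom(n, 1, 0.8))
    cmp <- compare_groups(sc, clin)
    if (cmp$hr < 1 && cmp$logrank$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 15L * 0.95)
})

test_that("null coverage: the HR confidence interval covers 1", {
  set.seed(32)
  cover <- 0L
  reps <- 100L
  for (i in seq_len(reps)) {
    n <- 80
    sc <- make_scored(sample(0:25, n, replace = TRUE))
    clin <- make_clin(rexp(n, 0.3), rbinom(n, 1, 0.8))
    cmp <- tryCatch(compare_groups(sc, clin), error = function(e) NULL)
    if (is.null(cmp)) { reps <- reps - 1L; next }
    if (cmp$ci[1] <= 1 && cmp$ci[2] >= 1) cover <- cover + 1L
  }
  expect_gt(cover / reps, 0.90)
  expect_lt(cover / reps, 0.99)
})

test_that("multivariable_cox builds the Table-2-style layout", {
  set.seed(42)
  n <- 260
  s <- sample(0:25, n, replace = TRUE)
  t <- rexp(n, 0.2 * exp(-0.1 * s))
  clin <- make_clin(t, rbinom(n, 1, 0.85),
                    age = round(rnorm(n, 60, 10)),
                    stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                                   prob = c(.05, .05, .7, .2)),
                    grade = sample(c("1", "2", "3", "other"), n, TRUE,
                                   prob = c(.1, .3, .55, .05)),
                    residual_mm = sample(c(0, 5, 20), n, TRUE))
  sc <- make_scored(s)
  mc <- multivariable_cox(sc, clin, ties = "breslow")
  expect_setequal(mc$table$term,
                  c("score", "age", "grade_2_vs_1", "grade_3_vs_1",
                    "grade_other", "stage_III", "stage_IV",
                    "residual_suboptimal"))
  # score drives the hazard; it must be significant with HR < 1
  row <- mc$table[mc$table$term == "score", ]
  expect_lt(row$p_multi, 0.05)
  expect_lt(row$hr_multi, 1)

  # duplicating the dataset leaves the point estimates unchanged (exact for
  # the Breslow likelihood; Efron's tie correction is not duplication-stable)
  sc_dup <- make_scored(c(s, s))
  clin_dup <- make_clin(c(t, t), c(clin$os_event, clin$os_event),
                        age = c(clin$age, clin$age),
                        stage = c(as.character(clin$stage), as.character(clin$stage)),
                        grade = c(as.character(clin$grade), as.character(clin$grade)),
                        residual_mm = c(clin$residual_mm, clin$residual_mm))
  mc_dup <- multivariable_cox(sc_dup, clin_dup, ties = "breslow")
  expect_equal(mc_dup$table$hr_multi, mc$table$hr_multi, tolerance = 1e-6)
  # and standard errors shrink
  expect_true(all(mc_dup$fit_multi$table$se < mc$fit_multi$table$se))

  # single-level covariate dropped with warning
  clin1 <- clin
  clin1$stage <- factor(rep("III", n), levels = c("I", "II", "III", "IV"))
  expect_warning(mc1 <- multivariable_cox(sc, clin1), "single observed level")
  expect_false("stage_IV" %in% mc1$table$term)
})

test_that("noise covariates stay null when only the score matters", {
  set.seed(52)
  cover_age <- 0L
  sig_score <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    n <- 250
    s <- sample(0:25, n, replace = TRUE)
    clin <- make_clin(rexp(n, 0.2 * exp(-0.12 * s)), rbinom(n, 1, 0.85),
                      age = round(rnorm(n, 60, 10)),
                      stage = sample(c("III", "IV"), n, TRUE))
    # only stages III/IV are sampled, so one stage dummy is aliased and
    # dropped with a warning each replicate; that is the intended behavior
    mc <- suppressWarnings(multivariable_cox(make_scored(s), clin,
                                             covariates = c("age", "stage")))
    tab <- mc$table
    if (tab$p_multi[tab$term == "score"] < 0.05) sig_score <- sig_score + 1L
    arow <- tab[tab$term == "age", ]
    if (arow$ci_lower_multi <= 1 && arow$ci_upper_multi >= 1) {
      cover_age <- cover_age + 1L
    }
  }
  expect_gte(sig_score / reps, 0.9)
  expect_gte(cover_age / reps, 0.9)
})

test_that("score_survival_correlation: exact linearity, exclusions, errors", {
  # construct bins whose KM medians are exactly linear in score:
  # per score s, 3 patients all dying at time s + 1 -> median = s + 1
  s <- rep(1:5, each = 3)
  clin <- make_clin(rep(1:5 + 1, each = 3), rep(1, 15))
  sc <- make_scored(s)
  res <- score_survival_correlation(sc, clin)
  expect_equal(res$r, 1)
  expect_identical(nrow(res$excluded), 0L)

  # an all-censored bin is excluded and reported
  clin2 <- make_clin(c(rep(2:6, each = 3)[1:12], 9, 9, 9),
                     c(rep(1, 12), 0, 0, 0))
  res2 <- score_survival_correlation(sc, clin2)
  expect_identical(res2$excluded$score, 5L)
  expect_match(res2$excluded$reason, "median not reached")
  expect_identical(nrow(res2$pairs), 4L)

  # small bins excluded by min_bin_size
  s3 <- c(rep(1:3, each = 3), 4)
  clin3 <- make_clin(c(rep(1:3 + 1, each = 3), 7), rep(1, 10))
  res3 <- score_survival_correlation(make_scored(s3), clin3)
  expect_identical(res3$excluded$score, 4L)

  # fewer than 3 usable bins: error
  expect_error(
    score_survival_correlation(make_scored(rep(1:2, each = 5)),
                               make_clin(rexp(10, .2) + .1, rep(1, 10))),
    "fewer than 3")
})

test_that("correlation p-values behave under the null", {
  set.seed(62)
  rej <- 0L
  reps <- 200L
  done <- 0L
  for (i in seq_len(reps)) {
    n <- 150
    s <- sample(0:12, n, replace = TRUE)
    clin <- make_clin(rexp(n, 0.4), rbinom(n, 1, 0.9))
    res <- tryCatch(score_survival_correlation(make_scored(s, K = 12L), clin),
                    error = function(e) NULL)
    if (is.null(res)) next
    done <- done + 1L
    if (res$p < 0.05) rej <- rej + 1L
  }
  expect_gt(done, 150L)
  expect_lt(abs(rej / done - 0.05), 0.05)
})

test_that("roc_comparison: exclusion rule and AUC ordering", {
  set.seed(72)
  n <- 200L
  s <- sample(0:25, n, replace = TRUE)
  t <- rexp(n, 0.2 * exp(-0.15 * s))
  e <- rbinom(n, 1, 0.75)
  clin <- make_clin(t, e, age = round(rnorm(n, 60, 10)))
  sc <- make_scored(s)
  res <- roc_comparison(sc, clin, covariates = "age")
  med <- res$median_os

  # censored before the median are excluded; everyone else included
  expect_identical(res$n_included + res$n_excluded, n)
  expect_setequal(res$excluded_ids, clin$sample_id[t < med & e == 0])
  # no event-flagged patient is ever excluded
  expect_false(any(clin$sample_id[e == 1] %in% res$excluded_ids))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  # the score carries the signal here
  expect_gt(res$auc[["score"]], res$auc[["agsr"]])
})

test_that("roc_comparison: a perfectly ordered score gives AUC 1", {
  # deaths before the median all at low scores, survivors at high scores
  s <- c(0:9, 16:25)
  t <- c(seq(0.2, 1.1, by = 0.1), rep(10, 10))
  e <- rep(1L, 20)
  clin <- make_clin(t, e)
  res <- roc_comparison(make_scored(s), clin, covariates = character(0))
  expect_equal(res$auc[["score"]], 1)

  # a patient censored before the median is excluded
  clin2 <- clin
  clin2$os_years[1] <- 1.2
  clin2$os_event[1] <- 0L
  med <- km_median(km_estimate(clin2$os_years, clin2$os_event))
  expect_gt(med, 1.2)
  res2 <- roc_comparison(make_scored(s), clin2, covariates = character(0))
  expect_identical(res2$excluded_ids, "P001")
})

test_that("subgroup_analysis: identity stratum and skip contract", {
  set.seed(82)
  n <- 120
  s <- sample(0:25, n, replace = TRUE)
  clin <- make_clin(rexp(n, 0.25 * exp(-0.05 * s)), rbinom(n, 1, 0.8),
                    regimen = rep("platinum_taxane", n))
  sc <- make_scored(s)
  sub <- subgroup_analysis(sc, clin, "regimen")
  whole <- compare_groups(sc, clin)
  expect_equal(sub$strata$platinum_taxane$hr, whole$hr, tolerance = 1e-10)

  # a stratum with no high-score patients is skipped with a reason
  clin$subtype <- ifelse(s > 12, "A", "B") # stratum B has only low scores
  sub2 <- subgroup_analysis(sc, clin, "subtype")
  expect_true("B" %in% sub2$skipped$stratum)
  expect_false("B" %in% names(sub2$strata))
  expect_error(subgroup_analysis(sc, clin, "nope"), "not found")
})
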