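# Stage 3: everything reported on a scored cohort — group KM/log-rank,
# univariate and multivariable Cox, score vs median-OS correlation,
# subgroup analyses, and the survival-threshold ROC comparison of the
# score against the clinical covariate set (age, grade, stage, residual).

merge_scores_clinical <- function(scores, clinical) {
  stopifnot(inherits(scores, "ros_scores"), inherits(clinical, "ros_clinical"))
  m <- merge(as.data.frame(scores), as.data.frame(clinical), by = "sample_id",
             sort = FALSE)
  if (nrow(m) < 2L) stop("fewer than 2 samples shared between scores and clinical",
                         call. = FALSE)
  m
}

#' Compare low vs high score groups
#'
#' Kaplan-Meier curve and censoring-aware median per group, the log-rank
#' test, and the univariate Cox hazard ratio of high vs low (HR < 1 means
#' the high-score group has the lower death hazard).
#'
#' @param scores a `ros_scores` table with groups assigned.
#' @param clinical a `ros_clinical` table (matched by `sample_id`).
#' @return list of class `ros_group_comparison`: `km` (named list of
#'   `ros_km`), `median_os` (named), `logrank` (`ros_logrank`), `cox`
#'   (`ros_cox`), `hr`, `ci`, `p`, `n`.
#' @export
compare_groups <- function(scores, clinical) {
  m <- merge_scores_clinical(scores, clinical)
  if (anyNA(m$group)) stop("groups not assigned; call assign_groups()", call. = FALSE)
  counts <- table(factor(m$group, levels = c("low", "high")))
  if (any(counts == 0L)) {
    stop("group '", names(counts)[counts == 0L][1],
         "' is empty; review the score threshold or panel size", call. = FALSE)
  }
  km <- lapply(split(m, m$group), function(d) km_estimate(d$os_years, d$os_event))
  lr <- logrank_test(m$os_years, m$os_event, m$group)
  hi <- as.integer(m$group == "high")
  fit <- cox_fit(m$os_years, m$os_event,
                 matrix(hi, ncol = 1, dimnames = list(NULL, "high_vs_low")))
  out <- list(
    km = km, median_os = vapply(km, km_median, 0),
    logrank = lr, cox = fit,
    hr = fit$table$hr[1],
    ci = c(fit$table$ci_lower[1], fit$table$ci_upper[1]),
    p = fit$table$p[1], n = as.vector(counts)
  )
  class(out) <- "ros_group_comparison"
  out
}

#' @export
print.ros_group_comparison <- function(x, ...) {
  cat(sprintf("High vs low score: HR = %.3f (95%% CI %.3f-%.3f), Cox p = %s\n",
              x$hr, x$ci[1], x$ci[2], format.pval(x$p, digits = 3)))
  cat(sprintf("Median OS: high = %s, low = %s; log-rank p = %s\n",
              format(x$median_os[["high"]], digits = 3),
              format(x$median_os[["low"]], digits = 3),
              format.pval(x$logrank$p, digits = 3)))
  invisible(x)
}

# Build the Table-2-style model matrix. Returns list(X, dropped).
build_covariate_matrix <- function(m, terms, score_form = "continuous",
                                   age_coding = "continuous") {
  cols <- list()
  if ("score" %in% terms) {
    cols$score <- if (score_form == "continuous") {
      as.numeric(m$score)
    } else {
      as.integer(m$group == "high")
    }
    if (score_form != "continuous") names(cols)[names(cols) == "score"] <- "score_high_vs_low"
  }
  if ("age" %in% terms && "age" %in% names(m)) {
    cols$age <- if (age_coding == "continuous") {
      as.numeric(m$age)
    } else {
      as.integer(m$age >= 60)
    }
    if (age_coding != "continuous") names(cols)[names(cols) == "age"] <- "age_ge60"
  }
  if ("grade" %in% terms && "grade" %in% names(m)) {
    g <- m$grade
    cols$grade_2_vs_1 <- as.integer(g == "2")
    cols$grade_3_vs_1 <- as.integer(g == "3")
    cols$grade_other <- as.integer(g == "other")
    cols$grade_2_vs_1[is.na(g)] <- NA_integer_
    cols$grade_3_vs_1[is.na(g)] <- NA_integer_
    cols$grade_other[is.na(g)] <- NA_integer_
  }
  if ("stage" %in% terms && "stage" %in% names(m)) {
    s <- m$stage # reference: stage I-II combined
    cols$stage_III <- as.integer(s == "III")
    cols$stage_IV <- as.integer(s == "IV")
    cols$stage_III[is.na(s)] <- NA_integer_
    cols$stage_IV[is.na(s)] <- NA_integer_
  }
  if ("residual" %in% terms && "residual" %in% names(m)) {
    cols$residual_suboptimal <- as.integer(m$residual == "suboptimal")
  }
  if (!length(cols)) return(list(X = NULL, dropped = character(0)))
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  # drop covariates with a single observed level
  cc <- stats::complete.cases(X)
  keep <- apply(X[cc, , drop = FALSE], 2L, function(col) diff(range(col)) > 0)
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    warning("covariate(s) with a single observed level dropped: ",
            paste(dropped, collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  # drop aliased columns (e.g. complementary dummies when the reference
  # level is unobserved): rank via QR of the centered complete-case matrix
  if (ncol(X) > 1L) {
    Xc <- scale(X[stats::complete.cases(X), , drop = FALSE], center = TRUE,
                scale = FALSE)
    q <- qr(Xc)
    if (q$rank < ncol(X)) {
      alias <- colnames(X)[q$pivot[-seq_len(q$rank)]]
      warning("aliased covariate(s) dropped: ", paste(alias, collapse = ", "))
      dropped <- c(dropped, alias)
      X <- X[, setdiff(colnames(X), alias), drop = FALSE]
    }
  }
  list(X = X, dropped = dropped)
}

# map model-matrix columns back to their covariate family
term_family <- function(term) {
  sub("_(2_vs_1|3_vs_1|other|III|IV|suboptimal|high_vs_low|ge60)$", "", term)
}

#' Univariate and multivariable Cox analysis of score plus clinical factors
#'
#' Reproduces the standard prognostic-factor table: each covariate family
#' (score, age, grade, stage, residual disease) is fit alone (univariate)
#' and all together (multivariable). Categorical families expand against a
#' reference level: grade 1, stage I-II, optimal debulking. The score
#' enters either as the integer point total (`"continuous"`) or as the
#' high-vs-low group indicator (`"categorical"`).
#'
#' @param scores a `ros_scores` table (groups assigned when
#'   `score_form = "categorical"`).
#' @param clinical a `ros_clinical` table.
#' @param score_form `"continuous"` (default) or `"categorical"`.
#' @param covariates clinical covariate families to include alongside the
#'   score.
#' @param age_coding `"continuous"` (Table-2 style, default) or `"binary60"`
#'   (<=59 vs >=60, forest-plot style).
#' @param ties tie-handling method passed to [cox_fit()].
#' @return list of class `ros_cox_table`: `table` (term, univariate and
#'   multivariable HR/CI/p), `fit_multi` (the multivariable `ros_cox`),
#'   `fits_uni` (per-family `ros_cox`), `n_complete`.
#' @export
multivariable_cox <- function(scores, clinical,
                              score_form = c("continuous", "categorical"),
                              covariates = c("age", "grade", "stage", "residual"),
                              age_coding = c("continuous", "binary60"),
                              ties = c("efron", "breslow")) {
  score_form <- match.arg(score_form)
  age_coding <- match.arg(age_coding)
  ties <- match.arg(ties)
  m <- merge_scores_clinical(scores, clinical)
  terms <- c("score", covariates)
  bm <- build_covariate_matrix(m, terms, score_form, age_coding)
  X <- bm$X
  cc <- stats::complete.cases(X)
  n_complete <- sum(cc)
  if (n_complete < 10 * ncol(X)) {
    warning("complete cases (", n_complete, ") < 10 x parameters (",
            ncol(X), "); estimates may be unstable")
  }
  mc <- m[cc, , drop = FALSE]
  Xc <- X[cc, , drop = FALSE]
  fit_multi <- cox_fit(mc$os_years, mc$os_event, Xc, ties = ties)

  fams <- unique(term_family(colnames(Xc)))
  fits_uni <- lapply(fams, function(f) {
    sel <- term_family(colnames(Xc)) == f
    cox_fit(mc$os_years, mc$os_event, Xc[, sel, drop = FALSE], ties = ties)
  })
  names(fits_uni) <- fams

  uni <- do.call(rbind, lapply(fits_uni, function(f) f$table))
  multi <- fit_multi$table
  tab <- data.frame(
    term = multi$term,
    hr_uni = uni$hr[match(multi$term, uni$term)],
    ci_lower_uni = uni$ci_lower[match(multi$term, uni$term)],
    ci_upper_uni = uni$ci_upper[match(multi$term, uni$term)],
    p_uni = uni$p[match(multi$term, uni$term)],
    hr_multi = multi$hr, ci_lower_multi = multi$ci_lower,
    ci_upper_multi = multi$ci_upper, p_multi = multi$p
  )
  out <- list(table = tab, fit_multi = fit_multi, fits_uni = fits_uni,
              n_complete = n_complete, dropped = bm$dropped,
              score_form = score_form, age_coding = age_coding)
  class(out) <- "ros_cox_table"
  out
}

#' @export
print.ros_cox_table <- function(x, ...) {
  cat("Cox prognostic-factor table (score form: ", x$score_form, "), n = ",
      x$n_complete, " complete cases\n", sep = "")
  tab <- x$table
  fmt <- function(hr, lo, hi, p) {
    sprintf("%.3f (%.3f,%.3f) p=%s", hr, lo, hi, format.pval(p, digits = 2))
  }
  print(data.frame(
    term = tab$term,
    univariate = fmt(tab$hr_uni, tab$ci_lower_uni, tab$ci_upper_uni, tab$p_uni),
    multivariable = fmt(tab$hr_multi, tab$ci_lower_multi, tab$ci_upper_multi,
                        tab$p_multi)
  ), row.names = FALSE)
  invisible(x)
}

#' Correlation between score values and per-score median survival
#'
#' Groups patients by exact score value; every bin with at least
#' `min_bin_size` patients and an estimable Kaplan-Meier median contributes
#' one (score, median OS) pair. Pearson correlation is computed across the
#' pairs; excluded bins are listed with the reason.
#'
#' @param scores a `ros_scores` table.
#' @param clinical a `ros_clinical` table.
#' @param min_bin_size smallest bin analyzed (default 3).
#' @return list of class `ros_score_correlation`: `pairs` (score,
#'   median_os, n), `excluded` (score, n, reason), `r`, `p`.
#' @export
score_survival_correlation <- function(scores, clinical, min_bin_size = 3) {
  m <- merge_scores_clinical(scores, clinical)
  svals <- sort(unique(m$score))
  pairs <- list()
  excluded <- list()
  for (s in svals) {
    d <- m[m$score == s, ]
    if (nrow(d) < min_bin_size) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(score = s, n = nrow(d), reason = "fewer than min_bin_size")
      next
    }
    med <- km_median(km_estimate(d$os_years, d$os_event))
    if (is.na(med)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(score = s, n = nrow(d), reason = "KM median not reached")
      next
    }
    pairs[[length(pairs) + 1L]] <- data.frame(score = s, median_os = med,
                                              n = nrow(d))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(score = numeric(0), median_os = numeric(0), n = integer(0))
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(score = numeric(0), n = integer(0), reason = character(0))
  if (nrow(pairs) < 3L) {
    stop("fewer than 3 usable score bins for the correlation", call. = FALSE)
  }
  ct <- pearson_r(pairs$score, pairs$median_os)
  out <- list(pairs = pairs, excluded = excluded, r = ct$r, p = ct$p)
  class(out) <- "ros_score_correlation"
  out
}

#' @export
print.ros_score_correlation <- function(x, ...) {
  cat(sprintf("Score vs median OS: r = %.3f, p = %s over %d bins (%d excluded)\n",
              x$r, format.pval(x$p, digits = 3), nrow(x$pairs), nrow(x$excluded)))
  invisible(x)
}

#' ROC comparison of the score against clinical covariates
#'
#' Binarizes survival at the cohort's Kaplan-Meier median OS: "long"
#' survivors have observed or censored time at or above the median (their
#' follow-up already exceeds the threshold); "short" survivors died before
#' the median; patients censored before the median are excluded because
#' their class is unknown. Cox models are then fit on the included subset
#' for three covariate sets — clinical covariates only (age, grade, stage,
#' residual; "AGSR"), score only, and both — and each model's in-sample
#' linear predictor is scored by [auc_mann_whitney()] with short survival
#' as the positive class.
#'
#' @param scores a `ros_scores` table.
#' @param clinical a `ros_clinical` table.
#' @param covariates clinical covariate families for the AGSR set.
#' @param age_coding passed to the model matrix (default `"continuous"`).
#' @return list of class `ros_roc_comparison`: `auc` (named: `agsr`,
#'   `score`, `agsr_plus_score`), `roc` (the `ros_roc` objects), `median_os`,
#'   `n_included`, `n_excluded`, `excluded_ids`, `fits`.
#' @export
roc_comparison <- function(scores, clinical,
                           covariates = c("age", "grade", "stage", "residual"),
                           age_coding = "continuous") {
  m <- merge_scores_clinical(scores, clinical)
  med <- km_median(km_estimate(m$os_years, m$os_event))
  if (is.na(med)) {
    stop("cohort KM median OS undefined; ROC binarization impossible",
         call. = FALSE)
  }
  long <- m$os_years >= med
  short <- m$os_years < med & m$os_event == 1L
  excl <- m$os_years < med & m$os_event == 0L
  stopifnot(all(long + short + excl == 1L))
  inc <- m[!excl, , drop = FALSE]
  label <- as.integer(inc$os_years < med) # 1 = short survival (positive)
  if (all(label == 0L) || all(label == 1L)) {
    stop("one survival class is empty after exclusions", call. = FALSE)
  }

  sets <- list(
    agsr = covariates,
    score = "score",
    agsr_plus_score = c("score", covariates)
  )
  # one complete-case subset across all covariates so the three AUCs are
  # computed on the same patients
  Xall <- build_covariate_matrix(inc, c("score", covariates),
                                 score_form = "continuous",
                                 age_coding = age_coding)$X
  cc <- stats::complete.cases(Xall)
  inc2 <- inc[cc, , drop = FALSE]
  label2 <- label[cc]
  if (length(unique(label2)) < 2L) {
    stop("one survival class is empty after complete-case restriction",
         call. = FALSE)
  }
  fits <- list(); rocs <- list()
  auc <- stats::setNames(rep(NA_real_, length(sets)), names(sets))
  for (nm in names(sets)) {
    bm <- suppressWarnings(
      build_covariate_matrix(inc2, sets[[nm]], score_form = "continuous",
                             age_coding = age_coding))
    if (is.null(bm$X) || ncol(bm$X) == 0L) next # covariate set empty
    fit <- suppressWarnings(cox_fit(inc2$os_years, inc2$os_event, bm$X))
    lp <- drop(as.matrix(bm$X) %*% fit$table$coef)
    fits[[nm]] <- fit
    rocs[[nm]] <- auc_mann_whitney(lp, label2)
    auc[nm] <- rocs[[nm]]$auc
  }
  out <- list(
    auc = auc,
    roc = rocs, fits = fits, median_os = med,
    n_included = nrow(inc2), n_excluded = sum(excl) + sum(!cc),
    excluded_ids = c(m$sample_id[excl], inc$sample_id[!cc])
  )
  class(out) <- "ros_roc_comparison"
  out
}

#' @export
print.ros_roc_comparison <- function(x, ...) {
  cat(sprintf(paste0("Survival-threshold ROC (median OS = %.2f): AUC ",
                     "covariates = %.2f, score = %.2f, combined = %.2f\n"),
              x$median_os, x$auc[["agsr"]], x$auc[["score"]],
              x$auc[["agsr_plus_score"]]))
  cat(x$n_included, "patients included,", x$n_excluded, "excluded\n")
  invisible(x)
}

#' Per-stratum low/high group comparison
#'
#' Runs [compare_groups()] inside every level of a stratum column
#' (e.g. molecular subtype or treatment regimen); strata violating the
#' preconditions (an empty group, too few patients) are reported as skipped
#' rather than failing the whole analysis.
#'
#' @param scores a `ros_scores` table with groups assigned.
#' @param clinical a `ros_clinical` table containing `stratum_column`.
#' @param stratum_column name of the clinical column to stratify on.
#' @return list of class `ros_subgroups`: `strata` (named list of
#'   `ros_group_comparison`), `skipped` (stratum, reason).
#' @export
subgroup_analysis <- function(scores, clinical, stratum_column) {
  if (!stratum_column %in% names(clinical)) {
    stop("stratum column not found: ", stratum_column, call. = FALSE)
  }
  lev <- unique(as.character(clinical[[stratum_column]]))
  lev <- lev[!is.na(lev)]
  strata <- list()
  skipped <- list()
  for (s in lev) {
    clin_s <- clinical[!is.na(clinical[[stratum_column]]) &
                         clinical[[stratum_column]] == s, , drop = FALSE]
    res <- tryCatch(compare_groups(scores, clin_s), error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(stratum = s, reason = conditionMessage(res))
    } else {
      strata[[s]] <- res
    }
  }
  out <- list(
    strata = strata,
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(stratum = character(0), reason = character(0))
  )
  class(out) <- "ros_subgroups"
  out
}
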