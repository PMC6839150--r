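# reverse cumulative sum, by column for matrices
revcumsum <- function(x) {
  if (is.matrix(x)) {
    apply(x, 2L, function(col) rev(cumsum(rev(col))))
  } else {
    rev(cumsum(rev(x)))
  }
}

check_surv_input <- function(times, events) {
  if (length(times) != length(events)) {
    stop("`times` and `events` must have equal length", call. = FALSE)
  }
  if (length(times) < 1L) stop("need at least one observation", call. = FALSE)
  if (!all(is.finite(times)) || any(times <= 0)) {
    stop("all survival times must be finite and > 0", call. = FALSE)
  }
  events <- as.integer(events)
  if (!all(events %in% c(0L, 1L))) {
    stop("`events` must be coded 0 (censored) / 1 (event)", call. = FALSE)
  }
  events
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival estimate
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct
#' event times, with Greenwood standard errors
#' \eqn{\hat S(t)^2 \sum d_i / (n_i (n_i - d_i))}. Observations censored at
#' an event time are counted as at risk at that time (right-continuity
#' convention).
#'
#' @param times positive survival/censoring times.
#' @param events 0/1 event indicator (1 = death observed, 0 = right-censored).
#' @return An object of class `ros_km`: a list with `event_times` (distinct
#'   times at which at least one event occurred), `survival`, `at_risk`,
#'   `events` (deaths at each event time), `greenwood_se`, `median` (first
#'   event time with \eqn{S(t) \le 0.5}, `NA` if never reached), `n`, and
#'   `n_events`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events) {
  events <- check_surv_input(times, events)
  ord <- order(times)
  t_s <- times[ord]
  e_s <- events[ord]
  ut <- unique(t_s)
  time_id <- match(t_s, ut)
  n_at_risk_all <- revcumsum(tabulate(time_id, nbins = length(ut)))
  d_all <- as.vector(rowsum(e_s, time_id, reorder = TRUE))
  keep <- d_all > 0L
  if (!any(keep)) {
    out <- list(
      event_times = numeric(0), survival = numeric(0), at_risk = integer(0),
      events = integer(0), greenwood_se = numeric(0), median = NA_real_,
      n = length(times), n_events = 0L
    )
    class(out) <- "ros_km"
    return(out)
  }
  tt <- ut[keep]
  n_k <- n_at_risk_all[keep]
  d_k <- d_all[keep]
  surv <- cumprod(1 - d_k / n_k)
  gw_term <- ifelse(n_k > d_k, d_k / (n_k * (n_k - d_k)), Inf)
  se <- surv * sqrt(cumsum(gw_term))
  med_idx <- which(surv <= 0.5 + 1e-9)
  out <- list(
    event_times = tt, survival = surv, at_risk = as.integer(n_k),
    events = as.integer(d_k), greenwood_se = se,
    median = if (length(med_idx)) tt[min(med_idx)] else NA_real_,
    n = length(times), n_events = sum(d_k)
  )
  class(out) <- "ros_km"
  out
}

#' Censoring-aware median survival time
#'
#' First event time at which the Kaplan-Meier estimate drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5 (heavy censoring).
#'
#' @param curve a `ros_km` object from [km_estimate()].
#' @return the median survival time, or `NA_real_` when undefined.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "ros_km"))
  curve$median
}

#' @export
print.ros_km <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, ", events =", x$n_events, "\n")
  cat("Median survival:", if (is.na(x$median)) "not reached" else
    format(x$median, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.ros_km <- function(x, xlab = "Time", ylab = "Survival probability",
                        col = 1, add = FALSE, xmax = NULL, ...) {
  tt <- c(0, rep(x$event_times, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-2 * length(x$survival)])
  if (!is.null(xmax)) {
    tt <- c(tt, xmax)
    ss <- c(ss, ss[length(ss)])
  }
  if (add) {
    graphics::lines(tt, ss, col = col, ...)
  } else {
    graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab,
                   ylab = ylab, col = col, ...)
  }
  invisible(x)
}

#' Log-rank test for equality of survival curves
#'
#' Standard (unweighted) log-rank test. At every distinct event time the
#' observed deaths per group are compared with the expectation under the
#' hypergeometric distribution; the covariance of the observed-minus-expected
#' vector uses the hypergeometric variance with the multiple-death
#' correction factor \eqn{(n_t - d_t)/(n_t - 1)}.
#'
#' @param times positive survival/censoring times.
#' @param events 0/1 event indicator.
#' @param group group labels (coerced to factor); at least two non-empty
#'   groups required.
#' @return An object of class `ros_logrank`: `chi_square`, `df`
#'   (groups - 1), `p`, and a per-group table of `n`, `observed`, `expected`.
#' @export
logrank_test <- function(times, events, group) {
  events <- check_surv_input(times, events)
  group <- factor(group)
  group <- droplevels(group)
  K <- nlevels(group)
  if (K < 2L) stop("log-rank test needs at least 2 non-empty groups", call. = FALSE)
  if (any(table(group) == 0L)) stop("every group must be non-empty", call. = FALSE)

  ut <- sort(unique(times))
  time_id <- match(times, ut)
  M <- length(ut)
  g_idx <- as.integer(group)

  # per-group at-risk counts and deaths at each distinct time
  n_gt <- matrix(0, M, K)
  d_gt <- matrix(0, M, K)
  for (g in seq_len(K)) {
    sel <- g_idx == g
    n_gt[, g] <- revcumsum(tabulate(time_id[sel], nbins = M))
    d_gt[, g] <- tabulate(time_id[sel & events == 1L], nbins = M)
  }
  n_t <- rowSums(n_gt)
  d_t <- rowSums(d_gt)
  ev <- d_t > 0
  n_gt <- n_gt[ev, , drop = FALSE]
  d_gt <- d_gt[ev, , drop = FALSE]
  n_t <- n_t[ev]
  d_t <- d_t[ev]

  E <- n_gt * (d_t / n_t)
  O <- colSums(d_gt)
  Eg <- colSums(E)
  corr <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
  V <- matrix(0, K, K)
  for (g in seq_len(K)) {
    for (h in seq_len(g)) {
      vgh <- sum(corr * (((g == h) * n_gt[, g] / n_t) -
                           n_gt[, g] * n_gt[, h] / n_t^2))
      V[g, h] <- V[h, g] <- vgh
    }
  }
  z <- (O - Eg)[-K]
  Vk <- V[-K, -K, drop = FALSE]
  chi <- tryCatch(drop(t(z) %*% solve(Vk, z)), error = function(e) {
    sv <- svd(Vk)
    pos <- sv$d > max(sv$d) * 1e-10
    drop(t(z) %*% sv$v[, pos, drop = FALSE] %*%
           ((t(sv$u[, pos, drop = FALSE]) %*% z) / sv$d[pos]))
  })
  chi <- max(chi, 0)
  out <- list(
    chi_square = chi, df = K - 1L,
    p = stats::pchisq(chi, df = K - 1L, lower.tail = FALSE),
    table = data.frame(group = levels(group), n = as.vector(table(group)),
                       observed = O, expected = Eg)
  )
  class(out) <- "ros_logrank"
  out
}

#' @export
print.ros_logrank <- function(x, ...) {
  cat("Log-rank test: chi-square =", format(x$chi_square, digits = 4),
      "on", x$df, "df, p =", format.pval(x$p, digits = 3), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Efron / Breslow partial log-likelihood, gradient, and information at beta.
# Data must be pre-sorted by increasing time.
cox_loglik_parts <- function(beta, X, time_id, e_s, M, ties, want = "all") {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta) # numeric guard; cancels in all ratios
  w <- exp(eta)

  pair_i <- rep(seq_len(p), times = seq_len(p))
  pair_j <- unlist(lapply(seq_len(p), seq_len))
  XX <- X[, pair_i, drop = FALSE] * X[, pair_j, drop = FALSE]

  S0 <- revcumsum(as.vector(rowsum(w, time_id, reorder = TRUE)))
  S1 <- revcumsum(rowsum(w * X, time_id, reorder = TRUE))
  S2 <- revcumsum(rowsum(w * XX, time_id, reorder = TRUE))

  dsel <- e_s == 1L
  d_all <- tabulate(time_id[dsel], nbins = M)
  ev <- which(d_all > 0L)
  d_k <- d_all[ev]
  id_d <- time_id[dsel]
  S0D <- as.vector(rowsum(w[dsel], id_d, reorder = TRUE))
  S1D <- rowsum((w * X)[dsel, , drop = FALSE], id_d, reorder = TRUE)
  S2D <- rowsum((w * XX)[dsel, , drop = FALSE], id_d, reorder = TRUE)

  sum_eta_d <- sum(eta[dsel])
  sum_x_d <- colSums(X[dsel, , drop = FALSE])

  kk <- rep(seq_along(ev), d_k)
  frac <- if (ties == "efron") {
    (sequence(d_k) - 1) / rep(d_k, d_k)
  } else {
    rep(0, sum(d_k))
  }
  den <- S0[ev][kk] - frac * S0D[kk]
  ll <- sum_eta_d - sum(log(den))
  if (want == "loglik") return(list(loglik = ll))

  R1 <- (S1[ev, , drop = FALSE][kk, , drop = FALSE] -
           frac * S1D[kk, , drop = FALSE]) / den
  U <- sum_x_d - colSums(R1)
  R2 <- (S2[ev, , drop = FALSE][kk, , drop = FALSE] -
           frac * S2D[kk, , drop = FALSE]) / den
  info_vech <- colSums(R2) - colSums(R1[, pair_i, drop = FALSE] *
                                       R1[, pair_j, drop = FALSE])
  info <- matrix(0, p, p)
  info[cbind(pair_i, pair_j)] <- info_vech
  info[cbind(pair_j, pair_i)] <- info_vech
  list(loglik = ll, U = U, info = info)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with step-halving,
#' starting at \eqn{\beta = 0}; tied event times are handled by the Efron
#' correction (default) or Breslow approximation. Confidence intervals and
#' p-values are Wald-based: \eqn{\exp(\hat\beta \pm 1.96\,se)}.
#'
#' @param times positive survival/censoring times.
#' @param events 0/1 event indicator.
#' @param covariates numeric matrix or data.frame (n rows); rows with missing
#'   values are dropped (complete-case analysis) with a message.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton-Raphson controls: iteration cap and the
#'   convergence threshold on `max(abs(delta_beta))`.
#' @return An object of class `ros_cox` with a coefficient `table`
#'   (`term`, `coef`, `hr`, `se`, `ci_lower`, `ci_upper`, `z`, `p`),
#'   `loglik` at the optimum, `loglik_null`, `score_test` (the score
#'   chi-square at beta = 0, equal to the log-rank statistic for a single
#'   binary covariate with untied data), `converged`, `iter`, `ties`,
#'   `n`, `n_events`, and the variance matrix `var`.
#' @export
cox_fit <- function(times, events, covariates, ties = c("efron", "breslow"),
                    max_iter = 50L, tol = 1e-8) {
  ties <- match.arg(ties)
  events <- check_surv_input(times, events)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(times)) stop("covariate rows must match times", call. = FALSE)

  cc <- stats::complete.cases(X)
  if (!all(cc)) {
    message(sum(!cc), " incomplete rows dropped from Cox fit")
    X <- X[cc, , drop = FALSE]
    times <- times[cc]
    events <- events[cc]
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more observations than covariates", call. = FALSE)
  const <- apply(X, 2L, function(col) diff(range(col)) == 0)
  if (any(const)) {
    stop("constant covariate(s): ", paste(colnames(X)[const], collapse = ", "),
         call. = FALSE)
  }
  if (sum(events) == 0L) stop("no events observed; Cox fit undefined", call. = FALSE)

  # center/scale for numeric stability; back-transform at the end
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  ord <- order(times)
  t_s <- times[ord]
  e_s <- events[ord]
  Xs <- Xs[ord, , drop = FALSE]
  ut <- unique(t_s)
  time_id <- match(t_s, ut)
  M <- length(ut)

  beta <- rep(0, p)
  parts <- cox_loglik_parts(beta, Xs, time_id, e_s, M, ties)
  loglik_null <- parts$loglik
  score_stat <- tryCatch(
    drop(t(parts$U) %*% solve(parts$info, parts$U)),
    error = function(e) NA_real_
  )
  converged <- FALSE
  iter <- 0L
  ll <- parts$loglik
  while (iter < max_iter) {
    iter <- iter + 1L
    delta <- tryCatch(solve(parts$info, parts$U), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- cox_loglik_parts(beta_new, Xs, time_id, e_s, M, ties,
                                 want = "loglik")$loglik
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { beta_new <- beta; ll_new <- ll; break }
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- ll_new
    parts <- cox_loglik_parts(beta, Xs, time_id, e_s, M, ties)
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("Cox fit did not converge after ", iter,
            " iterations (possible monotone likelihood / separation)")
  }

  var_s <- tryCatch(solve(parts$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  # back-transform from scaled covariates
  beta_raw <- beta / scl
  var_raw <- var_s / tcrossprod(scl)
  se <- sqrt(diag(var_raw))
  z <- beta_raw / se
  tab <- data.frame(
    term = colnames(X), coef = beta_raw, hr = exp(beta_raw), se = se,
    ci_lower = exp(beta_raw - 1.96 * se), ci_upper = exp(beta_raw + 1.96 * se),
    z = z, p = 2 * stats::pnorm(-abs(z)), row.names = NULL
  )
  out <- list(
    table = tab, loglik = ll, loglik_null = loglik_null,
    score_test = score_stat, converged = converged, iter = iter, ties = ties,
    n = n, n_events = sum(events), var = var_raw
  )
  class(out) <- "ros_cox"
  out
}

#' @export
print.ros_cox <- function(x, digits = 4, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_events,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n", sep = "")
  tab <- x$table
  tab$ci <- sprintf("(%.*f, %.*f)", digits - 1, tab$ci_lower,
                    digits - 1, tab$ci_upper)
  print(data.frame(term = tab$term, HR = signif(tab$hr, digits),
                   `95% CI` = tab$ci, p = format.pval(tab$p, digits = 3),
                   check.names = FALSE), row.names = FALSE)
  invisible(x)
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y paired numeric vectors, length >= 3, neither constant.
#' @return list with `r` and two-sided `p` (t-distribution, n - 2 df), and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(min(r, 1), -1)
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' ROC curve and AUC by the Mann-Whitney statistic
#'
#' AUC is the concordance probability
#' \eqn{P(s_{pos} > s_{neg}) + \tfrac12 P(s_{pos} = s_{neg})}, computed via
#' midranks; operating points enumerate every distinct score threshold
#' (predict positive when score >= threshold).
#'
#' @param score numeric risk scores (higher = more likely positive).
#' @param label 0/1 class labels; 1 is the positive class.
#' @return An object of class `ros_roc`: `auc`, `points` data.frame
#'   (`threshold`, `sensitivity`, `specificity`), `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(score, label) {
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) stop("`label` must be 0/1", call. = FALSE)
  if (length(score) != length(label)) stop("inputs must be paired", call. = FALSE)
  keep <- is.finite(score)
  score <- score[keep]; label <- label[keep]
  n_pos <- sum(label == 1L)
  n_neg <- sum(label == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  rk <- rank(score, ties.method = "average")
  auc <- (sum(rk[label == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(score), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(score >= t & label == 1L) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(score < t & label == 0L) / n_neg, 0)
  points <- data.frame(
    threshold = c(Inf, thr), sensitivity = c(0, sens), specificity = c(1, spec)
  )
  out <- list(auc = auc, points = points, n_pos = n_pos, n_neg = n_neg)
  class(out) <- "ros_roc"
  out
}

#' @export
print.ros_roc <- function(x, ...) {
  cat("ROC: AUC =", format(x$auc, digits = 4), "(", x$n_pos, "positive /",
      x$n_neg, "negative )\n")
  invisible(x)
}

#' @export
plot.ros_roc <- function(x, col = 1, add = FALSE, ...) {
  fpr <- 1 - x$points$specificity
  tpr <- x$points$sensitivity
  ord <- order(fpr, tpr)
  if (add) {
    graphics::lines(fpr[ord], tpr[ord], col = col, ...)
  } else {
    graphics::plot(fpr[ord], tpr[ord], type = "l", xlim = c(0, 1),
                   ylim = c(0, 1), xlab = "1 - specificity",
                   ylab = "Sensitivity", col = col, ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}
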