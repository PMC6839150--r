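# Independent oracles used to validate the from-scratch survival statistics.
# Each is written as directly as possible from the defining construction and
# shares no code with the implementation under test.

# Kaplan-Meier via redistribute-to-the-right: each observation starts with
# mass 1/n; a censored observation passes its mass equally to all strictly
# later observations; S(t) = 1 - accumulated event mass.
oracle_km_redistribute <- function(times, events) {
  n <- length(times)
  ord <- order(times, -events) # events before censorings at tied times
  t_s <- times[ord]
  e_s <- events[ord]
  w <- rep(1 / n, n)
  for (i in seq_len(n)) {
    if (e_s[i] == 0) {
      # mass passes equally to everything to the right in sort order; for
      # the last observation it is simply lost (curve stays flat),
      # matching KM after trailing censorings
      if (i < n) {
        later <- (i + 1L):n
        w[later] <- w[later] + w[i] / length(later)
      }
      w[i] <- 0
    }
  }
  ut <- sort(unique(t_s[e_s == 1]))
  surv <- vapply(ut, function(t) 1 - sum(w[e_s == 1 & t_s <= t]), 0)
  list(event_times = ut, survival = surv)
}

# Log-rank statistic written independently (naive per-event-time loop).
oracle_logrank_chi2 <- function(times, events, g) {
  # g: 0/1 group membership
  ut <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n1 <- sum(at_risk & g == 1)
    n0 <- sum(at_risk & g == 0)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    nt <- n1 + n0
    o_minus_e <- o_minus_e + d1 - d * n1 / nt
    if (nt > 1) v <- v + d * (nt - d) / (nt - 1) * n1 * n0 / nt^2
  }
  o_minus_e^2 / v
}

# Permutation p-value for the two-group log-rank test: permute group labels,
# recompute the independently-coded statistic, compare to the observed one.
oracle_logrank_permutation_p <- function(times, events, g, n_perm = 20000) {
  obs <- oracle_logrank_chi2(times, events, g)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    gp <- sample(g)
    if (oracle_logrank_chi2(times, events, gp) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Cox partial log-likelihood (Efron ties) coded naively: explicit loops over
# distinct event times and risk sets. Single covariate.
oracle_cox_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    s0 <- sum(exp(beta * x[R]))
    s0d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(s0 - (l / d) * s0d)
    }
  }
  ll
}

# Maximize the oracle likelihood by fine grid + golden-section refinement.
oracle_cox_beta <- function(times, events, x, lower = -5, upper = 5) {
  grid <- seq(lower, upper, by = 0.01)
  ll <- vapply(grid, oracle_cox_loglik, 0, times = times, events = events, x = x)
  b0 <- grid[which.max(ll)]
  opt <- stats::optimize(oracle_cox_loglik, c(b0 - 0.02, b0 + 0.02),
                         times = times, events = events, x = x,
                         maximum = TRUE, tol = 1e-10)
  opt$maximum
}

# AUC by exhaustive enumeration of positive x negative pairs.
oracle_auc_pairs <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# small deterministic clinical table builder
make_clin <- function(times, events, ids = NULL, ...) {
  ids <- if (is.null(ids)) sprintf("P%03d", seq_along(times)) else ids
  ros_clinical(data.frame(sample_id = ids, os_years = times,
                          os_event = events, ..., stringsAsFactors = FALSE))
}

# expression object from a plain matrix
make_expr <- function(values, genes = NULL, samples = NULL) {
  genes <- if (is.null(genes)) sprintf("G%03d", seq_len(nrow(values))) else genes
  samples <- if (is.null(samples)) sprintf("P%03d", seq_len(ncol(values))) else samples
  ros_expression(values, genes, samples)
}
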