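# Stage 1: per-gene median dichotomization and survival-association
# screening. Each candidate gene is split at its cohort median; the high
# (above-median) and low groups are compared by the log-rank test, and the
# direction of effect comes from the sign of the univariate Cox hazard
# ratio of the high indicator. No multiple-testing correction is applied,
# mirroring the original procedure — the P < 0.15 screen is deliberately
# permissive and the panel must be validated on independent cohorts.

#' Split samples at the median of one gene's expression
#'
#' Samples strictly above the cohort median are labelled 1 ("high");
#' samples at or below the median (including exact ties) are labelled 0
#' ("low"). Because only ranks matter, the split is invariant under any
#' strictly monotone transform of the expression scale.
#'
#' @param x per-sample expression values for one gene (at least 4
#'   non-missing; not all equal).
#' @return integer 0/1 vector (`NA` where `x` is missing).
#' @export
dichotomize_by_median <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 4L) stop("need at least 4 non-missing values", call. = FALSE)
  if (diff(range(x[ok])) == 0) {
    stop("degenerate gene: constant expression", call. = FALSE)
  }
  med <- stats::median(x[ok])
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(x[ok] > med)
  n_tie <- sum(x[ok] == med)
  if (n_tie > 0.1 * sum(ok)) {
    message(sprintf("%.0f%% of samples tie the median (assigned to low group)",
                    100 * n_tie / sum(ok)))
  }
  out
}

#' Screen one gene for survival association
#'
#' Dichotomizes the gene at its cohort median, tests high vs low by the
#' log-rank test, and takes the direction of effect from the univariate Cox
#' hazard ratio of the high indicator: HR < 1 means above-median expression
#' is favorable (`high_good`).
#'
#' @param x per-sample expression values, aligned with `clinical`.
#' @param clinical `ros_clinical` table aligned with `x`.
#' @param gene_id label carried into the record.
#' @param threshold selection threshold on the log-rank p (strict `<`).
#' @return one-row data.frame: `gene`, `logrank_p`, `direction`,
#'   `hr_high_vs_low`, `selected`, `skipped`, `reason`.
#' @export
screen_gene <- function(x, clinical, gene_id = "gene", threshold = 0.15) {
  rec <- data.frame(gene = gene_id, logrank_p = NA_real_,
                    direction = NA_character_, hr_high_vs_low = NA_real_,
                    selected = FALSE, skipped = TRUE, reason = "",
                    stringsAsFactors = FALSE)
  if (anyNA(x)) {
    rec$reason <- "missing expression values"
    return(rec)
  }
  hi <- tryCatch(dichotomize_by_median(x), error = function(e) NULL)
  if (is.null(hi) || length(unique(hi)) < 2L) {
    rec$reason <- "degenerate dichotomization"
    return(rec)
  }
  lr <- logrank_test(clinical$os_years, clinical$os_event, hi)
  fit <- suppressWarnings(
    cox_fit(clinical$os_years, clinical$os_event,
            matrix(hi, ncol = 1, dimnames = list(NULL, "high")))
  )
  hr <- fit$table$hr[1]
  rec$logrank_p <- lr$p
  rec$hr_high_vs_low <- hr
  rec$direction <- if (hr < 1) "high_good" else "low_good"
  rec$skipped <- FALSE
  if (!is.finite(hr) || hr == 1) {
    # direction undeterminable: never selected
    rec$selected <- FALSE
    rec$reason <- if (!is.finite(hr)) "hr not estimable" else "hr exactly 1"
  } else {
    # selection is driven by the log-rank screen; a monotone-likelihood Cox
    # fit (extreme separation) still has a well-defined direction sign
    rec$selected <- lr$p < threshold
    if (!fit$converged) rec$reason <- "cox fit not converged (direction from sign)"
  }
  rec
}

#' Build a gene panel by screening candidate genes
#'
#' Runs [screen_gene()] on every candidate gene present in the matrix and
#' returns the panel of selected genes (p below `screen_threshold`, strict),
#' sorted by ascending p, together with the full audit trail of screen
#' records.
#'
#' @param expr `ros_expr` aligned with `clinical` (see [align_cohort()]).
#' @param clinical `ros_clinical`, same samples and order as `expr`.
#' @param candidate_genes character vector of candidate symbols
#'   (case-insensitive); absent genes are skipped with a warning.
#' @param screen_threshold strict selection threshold (default 0.15).
#' @return list of class `ros_screen_result`: `panel` ([ros_panel()]),
#'   `records` (one row per candidate).
#' @export
build_panel <- function(expr, clinical, candidate_genes,
                        screen_threshold = 0.15) {
  stopifnot(inherits(expr, "ros_expr"), inherits(clinical, "ros_clinical"))
  if (!identical(expr$samples, clinical$sample_id)) {
    stop("expression and clinical samples are not aligned; call align_cohort()",
         call. = FALSE)
  }
  candidate_genes <- toupper(as.character(candidate_genes))
  present <- candidate_genes %in% expr$genes
  if (!any(present)) stop("no candidate gene found in the matrix", call. = FALSE)
  if (any(!present)) {
    warning(sum(!present), " candidate gene(s) absent from the matrix: ",
            paste(utils::head(candidate_genes[!present], 5), collapse = ", "),
            if (sum(!present) > 5) ", ..." else "")
  }
  genes <- candidate_genes[present]
  records <- do.call(rbind, lapply(genes, function(g) {
    screen_gene(expr$values[g, ], clinical, gene_id = g,
                threshold = screen_threshold)
  }))
  if (any(records$skipped)) {
    warning(sum(records$skipped), " gene(s) skipped during screening (",
            paste(unique(records$reason[records$skipped]), collapse = "; "), ")")
  }
  sel <- records[records$selected, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("no gene passed the screen at threshold ", screen_threshold,
         "; review the threshold or candidate list", call. = FALSE)
  }
  sel <- sel[order(sel$logrank_p, sel$gene), , drop = FALSE]
  panel <- ros_panel(sel$gene, sel$direction, sel$logrank_p)
  out <- list(panel = panel, records = records,
              threshold = screen_threshold)
  class(out) <- "ros_screen_result"
  out
}

#' @export
print.ros_screen_result <- function(x, ...) {
  cat("Screening: ", nrow(x$records), " candidates, ",
      attr(x$panel, "K"), " selected at P < ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Write the full screening report to TSV
#' @param screen a `ros_screen_result`.
#' @param path output path.
#' @export
write_screen_report <- function(screen, path) {
  stopifnot(inherits(screen, "ros_screen_result"))
  utils::write.table(screen$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
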