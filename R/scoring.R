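# Stage 2: turn a gene panel into a per-patient integer score. Each panel
# gene contributes one point when the patient's expression lies on the
# gene's favorable side of the median; the score is the point total
# (0..K). Patients are then split into "low"/"high" categories by dividing
# the 0..K range into two equal halves (0-12 vs 13-25 for K = 25).

#' Compute per-patient scores from a gene panel
#'
#' For every panel gene available in the matrix, a patient earns one point
#' when expression is above the median and the gene is `high_good`, or at
#' or below the median and the gene is `low_good`. Medians default to the
#' scoring cohort's own per-gene medians; a frozen reference-median vector
#' may be supplied for prospective use on a fixed platform.
#'
#' @param expr `ros_expr` for the cohort to score.
#' @param panel a [ros_panel()].
#' @param medians optional named numeric vector of frozen per-gene medians;
#'   must cover every available panel gene. `NULL` (default) recomputes
#'   medians from this cohort.
#' @return data.frame of class `ros_scores` with columns `sample_id`,
#'   `score`, `n_genes_used`, `group` (`NA` until [assign_groups()]), and
#'   attributes `K` (full panel size), `genes_used`,
#'   `reference_medians`, `points` (sample x gene 0/1 audit matrix).
#' @export
compute_scores <- function(expr, panel, medians = NULL) {
  stopifnot(inherits(expr, "ros_expr"), inherits(panel, "ros_panel"))
  K <- attr(panel, "K")
  avail <- panel$gene %in% expr$genes
  if (!any(avail)) stop("no panel gene present in the matrix", call. = FALSE)
  # genes with missing values cannot be dichotomized for every sample
  has_na <- vapply(panel$gene[avail],
                   function(g) anyNA(expr$values[g, ]), TRUE)
  usable <- panel$gene[avail][!has_na]
  dropped <- setdiff(panel$gene, usable)
  if (length(dropped)) {
    warning(length(dropped), " of ", K, " panel gene(s) unavailable ",
            "(absent or with missing values): ",
            paste(dropped, collapse = ", "),
            "; the attainable maximum score is ", length(usable))
  }
  if (length(usable) == 0L) stop("no scorable panel gene", call. = FALSE)

  vals <- expr$values[usable, , drop = FALSE]
  if (is.null(medians)) {
    med <- apply(vals, 1L, stats::median)
  } else {
    if (!all(usable %in% names(medians))) {
      stop("frozen medians missing panel gene(s): ",
           paste(setdiff(usable, names(medians)), collapse = ", "),
           call. = FALSE)
    }
    med <- medians[usable]
  }
  high <- sweep(vals, 1L, med, ">")
  dir_high <- panel$direction[match(usable, panel$gene)] == "high_good"
  pts <- ifelse(sweep(high, 1L, dir_high, "=="), 1L, 0L)
  score <- colSums(pts)
  out <- data.frame(sample_id = expr$samples, score = as.integer(score),
                    n_genes_used = length(usable),
                    group = NA_character_, stringsAsFactors = FALSE)
  attr(out, "K") <- K
  attr(out, "genes_used") <- usable
  attr(out, "reference_medians") <- med
  attr(out, "points") <- t(pts)
  class(out) <- c("ros_scores", "data.frame")
  out
}

#' Assign low/high groups by equal score ranges
#'
#' The 0..K score range is divided into two equal halves: scores at or
#' below `floor(K/2)` are "low", the rest "high". For the published
#' 25-gene panel this reproduces the low 0-12 / high 13-25 split.
#'
#' @param scores a `ros_scores` table.
#' @param max_missing_frac refuse to assign groups when more than this
#'   fraction of panel genes was unavailable for scoring (default 0.2),
#'   since the boundary presumes the full panel size; raise to override.
#' @return `scores` with the `group` column filled.
#' @export
assign_groups <- function(scores, max_missing_frac = 0.2) {
  stopifnot(inherits(scores, "ros_scores"))
  K <- attr(scores, "K")
  used <- length(attr(scores, "genes_used"))
  if ((K - used) / K > max_missing_frac) {
    stop(sprintf(paste0("%d of %d panel genes unavailable (> %.0f%%); the ",
                        "equal-range boundary presumes the full panel -- ",
                        "raise max_missing_frac to override"),
                 K - used, K, 100 * max_missing_frac), call. = FALSE)
  }
  scores$group <- ifelse(scores$score > K / 2, "high", "low")
  if (length(unique(scores$group)) < 2L) {
    warning("all patients fall in the '", unique(scores$group),
            "' group; downstream group comparisons will fail")
  }
  scores
}

#' Write a score table (and optional point matrix) to TSV
#' @param scores a `ros_scores` table.
#' @param path output path for the score table.
#' @param points_path optional path for the sample x gene 0/1 point matrix.
#' @export
write_scores <- function(scores, path, points_path = NULL) {
  stopifnot(inherits(scores, "ros_scores"))
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(points_path)) {
    pts <- attr(scores, "points")
    utils::write.table(data.frame(sample_id = rownames(pts), pts,
                                  check.names = FALSE),
                       points_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
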