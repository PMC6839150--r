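# Readers, writers and validators for the three cohort artifacts:
# expression matrix, clinical table, gene panel.

#' Construct a validated expression matrix
#'
#' @param values numeric gene x sample matrix; `NA` marks missing values.
#' @param gene_ids,sample_ids identifiers; gene symbols are upper-cased and
#'   must be unique after case normalization.
#' @return object of class `ros_expr`: list with `genes`, `samples`,
#'   `values` (dimnamed matrix), `n_missing`.
#' @export
ros_expression <- function(values, gene_ids, sample_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- toupper(as.character(gene_ids))
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    stop("matrix dimensions do not match id lists", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty expression matrix", call. = FALSE)
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.infinite(values))) stop("non-finite expression values", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  out <- list(genes = gene_ids, samples = sample_ids, values = values,
              n_missing = sum(is.na(values)))
  class(out) <- "ros_expr"
  out
}

#' @export
print.ros_expr <- function(x, ...) {
  cat("Expression matrix:", length(x$genes), "genes x", length(x$samples),
      "samples;", x$n_missing, "missing values\n")
  invisible(x)
}

#' Read a gene x sample expression matrix from TSV/CSV
#'
#' First column must hold gene symbols, the header row sample ids, and the
#' body numeric values (`NA` marks missing). Gene symbols are upper-cased.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"csv"`; guessed from the extension
#'   when missing.
#' @return a validated [ros_expression()] object.
#' @export
read_expression <- function(path, format = c("tsv", "csv")) {
  if (missing(format) && grepl("\\.csv$", path, ignore.case = TRUE)) {
    format <- "csv"
  }
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty expression matrix", call. = FALSE)
  genes <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at gene '%s' (row %d), sample '%s': '%s'",
                 genes[bad[1, 1]], bad[1, 1], colnames(body)[bad[1, 2]],
                 body[bad[1, ]][1]), call. = FALSE)
  }
  em <- ros_expression(num, genes, colnames(body))
  if (em$n_missing > 0) {
    message(em$n_missing, " missing expression value(s) flagged")
  }
  em
}

#' Write an expression matrix to TSV
#' @param expr a `ros_expr` object.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "ros_expr"))
  df <- data.frame(gene = expr$genes, expr$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

normalize_event <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (all(x %in% c(0, 1) | is.na(x))) return(as.integer(x))
    stop("unmappable event coding: numeric values outside {0,1}", call. = FALSE)
  }
  lx <- tolower(trimws(as.character(x)))
  dead <- c("1", "dead", "deceased", "event", "death", "yes", "true")
  alive <- c("0", "alive", "living", "censored", "no", "false")
  out <- ifelse(lx %in% dead, 1L, ifelse(lx %in% alive, 0L, NA_integer_))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unmappable event coding: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

normalize_stage <- function(x) {
  lx <- toupper(trimws(as.character(x)))
  lx[lx %in% c("1", "I", "IA", "IB", "IC")] <- "I"
  lx[lx %in% c("2", "II", "IIA", "IIB", "IIC")] <- "II"
  lx[lx %in% c("3", "III", "IIIA", "IIIB", "IIIC")] <- "III"
  lx[lx %in% c("4", "IV", "IVA", "IVB")] <- "IV"
  lx[!lx %in% c("I", "II", "III", "IV")] <- NA
  factor(lx, levels = c("I", "II", "III", "IV"), ordered = TRUE)
}

normalize_grade <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  lx[lx %in% c("1", "g1", "grade 1")] <- "1"
  lx[lx %in% c("2", "g2", "grade 2")] <- "2"
  lx[lx %in% c("3", "g3", "grade 3", "4", "g4")] <- "3"
  lx[is.na(x)] <- NA
  lx[!is.na(lx) & !lx %in% c("1", "2", "3")] <- "other"
  factor(lx, levels = c("1", "2", "3", "other"))
}

#' Construct a validated clinical table
#'
#' Canonical columns: `sample_id`, `os_years` (> 0), `os_event` (0/1),
#' and optional `age`, `stage` (I-IV), `grade` (1/2/3/other),
#' `residual_mm` (numeric residual tumor, recoded to a `residual` factor
#' `optimal` (<= 10 mm) / `suboptimal` (>= 11 mm)). Any extra columns are
#' carried through as stratum labels.
#'
#' @param df data.frame holding at least `sample_id`, `os_years`, `os_event`.
#' @return data.frame of class `ros_clinical`.
#' @export
ros_clinical <- function(df) {
  req <- c("sample_id", "os_years", "os_event")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  df$os_years <- as.numeric(df$os_years)
  bad_t <- !is.na(df$os_years) & df$os_years <= 0
  if (any(bad_t)) {
    stop("non-positive survival time for sample(s): ",
         paste(df$sample_id[bad_t], collapse = ", "), call. = FALSE)
  }
  df$os_event <- normalize_event(df$os_event)
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  if ("stage" %in% names(df)) df$stage <- normalize_stage(df$stage)
  if ("grade" %in% names(df)) df$grade <- normalize_grade(df$grade)
  if ("residual_mm" %in% names(df)) {
    df$residual_mm <- as.numeric(df$residual_mm)
    df$residual <- factor(
      ifelse(is.na(df$residual_mm), NA,
             ifelse(df$residual_mm <= 10, "optimal", "suboptimal")),
      levels = c("optimal", "suboptimal")
    )
  }
  class(df) <- c("ros_clinical", "data.frame")
  df
}

#' Read a clinical table from TSV/CSV
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names to
#'   the file's headers, e.g. `c(sample_id = "patient", os_years = "OS.time")`.
#'   Unmapped canonical names are looked up verbatim.
#' @param format `"tsv"` or `"csv"`; guessed from the extension.
#' @return data.frame of class `ros_clinical`; residual disease is recoded
#'   to optimal/suboptimal at the 10 mm (= 1 cm) boundary.
#' @export
read_clinical <- function(path, column_map = NULL, format = c("tsv", "csv")) {
  if (missing(format) && grepl("\\.csv$", path, ignore.case = TRUE)) {
    format <- "csv"
  }
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("column_map source column not found: ", src, call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  ros_clinical(df)
}

#' Write a clinical table to TSV
#' @param clin a `ros_clinical` data.frame.
#' @param path output path.
#' @export
write_clinical <- function(clin, path) {
  stopifnot(inherits(clin, "ros_clinical"))
  out <- as.data.frame(clin)
  out$residual <- NULL # derived column; recomputed on read
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene panel
#'
#' @param gene gene symbols (upper-cased, unique).
#' @param direction `"high_good"` / `"low_good"` (or the file tokens
#'   `"high"` / `"low"`): whether above-median expression is the favorable
#'   side that earns a score point.
#' @param p screening p-values in `[0, 1]`.
#' @return data.frame of class `ros_panel` with attribute `K` (panel size).
#' @export
ros_panel <- function(gene, direction, p) {
  gene <- toupper(as.character(gene))
  direction <- as.character(direction)
  direction[direction == "high"] <- "high_good"
  direction[direction == "low"] <- "low_good"
  if (!all(direction %in% c("high_good", "low_good"))) {
    stop("unknown direction token(s): ",
         paste(unique(direction[!direction %in% c("high_good", "low_good")]),
               collapse = ", "), call. = FALSE)
  }
  p <- as.numeric(p)
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p must lie in [0,1]", call. = FALSE)
  if (length(gene) < 1L) stop("empty panel", call. = FALSE)
  if (anyDuplicated(gene)) {
    stop("duplicate panel gene(s): ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(gene = gene, direction = direction, p = p)
  attr(out, "K") <- nrow(out)
  class(out) <- c("ros_panel", "data.frame")
  out
}

#' Load a gene panel from file or builtin fixture
#'
#' The builtin fixture `"table1"` is the published 25-gene
#' reactive-oxygen-species panel: per-gene screening p-values and the
#' direction of effect ("high" = above-median expression associated with
#' better overall survival).
#'
#' @param source a file path to a TSV with columns `gene`, `direction`
#'   (high/low), `p` — or the builtin name `"table1"`.
#' @return a [ros_panel()] data.frame.
#' @export
load_panel <- function(source) {
  path <- if (identical(source, "table1")) {
    system.file("extdata", "table1_panel.tsv", package = "roscore",
                mustWork = TRUE)
  } else {
    source
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (nrow(df) == 0L) stop("empty panel file: ", path, call. = FALSE)
  req <- c("gene", "direction", "p")
  if (!all(req %in% names(df))) {
    stop("panel file must have columns gene, direction, p", call. = FALSE)
  }
  ros_panel(df$gene, df$direction, df$p)
}

#' Write a gene panel to TSV
#' @param panel a `ros_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "ros_panel"))
  out <- data.frame(gene = panel$gene,
                    direction = ifelse(panel$direction == "high_good",
                                       "high", "low"),
                    p = panel$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix and clinical table on shared samples
#'
#' Restricts both artifacts to the intersection of their sample ids, in the
#' expression matrix's order, and reports how many samples were dropped
#' from each side.
#'
#' @param expr a `ros_expr`.
#' @param clin a `ros_clinical`.
#' @return list with `expr`, `clinical` (same samples, same order),
#'   `dropped_expr`, `dropped_clinical`.
#' @export
align_cohort <- function(expr, clin) {
  stopifnot(inherits(expr, "ros_expr"), inherits(clin, "ros_clinical"))
  shared <- expr$samples[expr$samples %in% clin$sample_id]
  if (length(shared) < 2L) {
    stop("fewer than 2 shared samples between expression and clinical data",
         call. = FALSE)
  }
  d_expr <- length(expr$samples) - length(shared)
  d_clin <- nrow(clin) - length(shared)
  if (d_expr + d_clin > 0) {
    message(d_expr, " sample(s) dropped from expression, ", d_clin,
            " from clinical")
  }
  expr2 <- ros_expression(expr$values[, shared, drop = FALSE],
                          expr$genes, shared)
  clin2 <- clin[match(shared, clin$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expr = expr2, clinical = clin2,
       dropped_expr = d_expr, dropped_clinical = d_clin)
}
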