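# Orchestration: discovery (screen -> score -> evaluate), validation
# (frozen panel -> score -> evaluate), and simulation runs, driven by a
# single JSON config, with a manifest recording provenance.

default_config <- function() {
  list(
    mode = NULL,              # discover | validate | simulate
    expression = NULL,        # path to expression TSV/CSV
    clinical = NULL,          # path to clinical TSV/CSV
    column_map = NULL,        # clinical header mapping
    candidate_genes = NULL,   # path to one-symbol-per-line file (discover)
    panel = NULL,             # path or "table1" (validate)
    preset = NULL,            # simulate: tcga_like | tothill_like | tj_like
    screen_threshold = 0.15,
    min_bin_size = 3,
    covariates = c("age", "grade", "stage", "residual"),
    age_coding = "continuous",
    score_form = "continuous",
    stratum_column = NULL,
    plots = FALSE,
    seed = 1L,
    out = "ros_run"
  )
}

read_run_config <- function(config) {
  cfg <- if (is.character(config)) jsonlite::read_json(config, simplifyVector = TRUE)
         else config
  cfg <- utils::modifyList(default_config(), as.list(cfg))
  if (is.null(cfg$mode) || !cfg$mode %in% c("discover", "validate", "simulate")) {
    stop("config `mode` must be discover, validate, or simulate", call. = FALSE)
  }
  need <- switch(cfg$mode,
    discover = c("expression", "clinical", "candidate_genes"),
    validate = c("expression", "clinical", "panel"),
    simulate = "preset"
  )
  miss <- need[vapply(cfg[need], is.null, TRUE)]
  if (length(miss)) {
    stop("config missing required field(s) for mode '", cfg$mode, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cfg
}

file_md5 <- function(paths) {
  paths <- unlist(Filter(Negate(is.null), paths))
  paths <- as.character(paths)
  paths <- paths[nzchar(paths) & file.exists(paths)]
  if (!length(paths)) return(stats::setNames(list(), character(0)))
  as.list(tools::md5sum(paths))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

evaluation_report <- function(scores, clinical, cfg) {
  cmp <- compare_groups(scores, clinical)
  mc <- multivariable_cox(scores, clinical, score_form = cfg$score_form,
                          covariates = intersect(cfg$covariates, names(clinical)),
                          age_coding = cfg$age_coding)
  corr <- tryCatch(
    score_survival_correlation(scores, clinical, min_bin_size = cfg$min_bin_size),
    error = function(e) e
  )
  roc <- tryCatch(
    roc_comparison(scores, clinical,
                   covariates = intersect(cfg$covariates, names(clinical)),
                   age_coding = cfg$age_coding),
    error = function(e) e
  )
  sub <- if (!is.null(cfg$stratum_column)) {
    subgroup_analysis(scores, clinical, cfg$stratum_column)
  }
  list(comparison = cmp, cox_table = mc,
       correlation = if (!inherits(corr, "error")) corr else NULL,
       correlation_error = if (inherits(corr, "error")) conditionMessage(corr),
       roc = if (!inherits(roc, "error")) roc else NULL,
       roc_error = if (inherits(roc, "error")) conditionMessage(roc),
       subgroups = sub)
}

report_json <- function(ev) {
  j <- list(
    group_comparison = list(
      hr_high_vs_low = ev$comparison$hr,
      ci = ev$comparison$ci, cox_p = ev$comparison$p,
      median_os = as.list(ev$comparison$median_os),
      logrank_chi_square = ev$comparison$logrank$chi_square,
      logrank_p = ev$comparison$logrank$p,
      n = ev$comparison$n
    ),
    cox_table = ev$cox_table$table
  )
  if (!is.null(ev$correlation)) {
    j$score_correlation <- list(r = ev$correlation$r, p = ev$correlation$p,
                                pairs = ev$correlation$pairs,
                                excluded = ev$correlation$excluded)
  } else j$score_correlation_error <- ev$correlation_error
  if (!is.null(ev$roc)) {
    j$roc <- list(auc = as.list(ev$roc$auc), median_os = ev$roc$median_os,
                  n_included = ev$roc$n_included,
                  n_excluded = ev$roc$n_excluded)
  } else j$roc_error <- ev$roc_error
  if (!is.null(ev$subgroups)) {
    j$subgroups <- lapply(ev$subgroups$strata, function(s) {
      list(hr = s$hr, ci = s$ci, p = s$p, logrank_p = s$logrank$p)
    })
    j$subgroups_skipped <- ev$subgroups$skipped
  }
  j
}

emit_plots <- function(ev, out) {
  grDevices::png(file.path(out, "km_groups.png"), 700, 600)
  xmax <- max(unlist(lapply(ev$comparison$km, function(k) k$event_times)))
  plot(ev$comparison$km$low, col = "blue", xmax = xmax,
       main = "Overall survival by score group")
  plot(ev$comparison$km$high, col = "darkgreen", add = TRUE, xmax = xmax)
  graphics::legend("topright", c("high", "low"),
                   col = c("darkgreen", "blue"), lty = 1)
  grDevices::dev.off()
  if (!is.null(ev$roc)) {
    grDevices::png(file.path(out, "roc.png"), 650, 600)
    plot(ev$roc$roc$agsr, col = "grey40", main = "Survival-threshold ROC")
    plot(ev$roc$roc$score, col = "red", add = TRUE)
    plot(ev$roc$roc$agsr_plus_score, col = "purple", add = TRUE)
    graphics::legend("bottomright",
                     sprintf("%s (AUC %.2f)",
                             c("covariates", "score", "combined"), ev$roc$auc),
                     col = c("grey40", "red", "purple"), lty = 1)
    grDevices::dev.off()
  }
  if (!is.null(ev$correlation)) {
    grDevices::png(file.path(out, "score_vs_median_os.png"), 650, 600)
    graphics::plot(ev$correlation$pairs$score, ev$correlation$pairs$median_os,
                   xlab = "Score", ylab = "Median OS (years)",
                   main = sprintf("r = %.3f", ev$correlation$r), pch = 19)
    grDevices::dev.off()
  }
}

#' Run a full pipeline from a config
#'
#' Modes: `"discover"` screens the candidate genes on the cohort, builds
#' the panel, scores and evaluates; `"validate"` scores the cohort with a
#' frozen panel (file path or builtin `"table1"`) and evaluates;
#' `"simulate"` writes a synthetic cohort (expression + clinical TSV +
#' ground-truth JSON) from a preset. Every run writes a `manifest.json`
#' recording the config, its hash, input checksums, and package version.
#'
#' @param config path to a JSON config file, or an equivalent named list.
#'   See the package vignette for the schema.
#' @return invisibly, a list with the run outputs (mode-dependent).
#' @export
ros_run <- function(config) {
  cfg <- read_run_config(config)
  out <- cfg$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = cfg, config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("roscore")),
    inputs_md5 = file_md5(cfg[c("expression", "clinical", "candidate_genes",
                                "panel")]),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    complete = FALSE
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_manifest()

  if (cfg$mode == "simulate") {
    config_sim <- make_preset(cfg$preset, seed = cfg$seed)
    cohort <- simulate_cohort(config_sim)
    write_sim_cohort(cohort, out)
    manifest$complete <- TRUE
    write_manifest()
    return(invisible(list(cohort = cohort, out = out)))
  }

  expr <- read_expression(cfg$expression)
  clin <- read_clinical(cfg$clinical, column_map = cfg$column_map)
  al <- align_cohort(expr, clin)

  if (cfg$mode == "discover") {
    cand <- toupper(trimws(readLines(cfg$candidate_genes)))
    cand <- cand[nzchar(cand)]
    screen <- build_panel(al$expr, al$clinical, cand,
                          screen_threshold = cfg$screen_threshold)
    panel <- screen$panel
    write_screen_report(screen, file.path(out, "screening_report.tsv"))
    write_panel(panel, file.path(out, "panel.tsv"))
  } else {
    panel <- load_panel(cfg$panel)
    screen <- NULL
  }

  scores <- assign_groups(compute_scores(al$expr, panel))
  write_scores(scores, file.path(out, "scores.tsv"),
               points_path = file.path(out, "points.tsv"))
  ev <- evaluation_report(scores, al$clinical, cfg)
  jsonlite::write_json(report_json(ev), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(ev$cox_table$table, file.path(out, "cox_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (isTRUE(cfg$plots)) emit_plots(ev, out)
  manifest$dropped_samples <- list(expression = al$dropped_expr,
                                   clinical = al$dropped_clinical)
  manifest$complete <- TRUE
  write_manifest()
  invisible(list(panel = panel, screen = screen, scores = scores,
                 evaluation = ev, out = out))
}
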