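battery_dependents <- function() {
  list(
    tug = tug_phase_vars,
    walking_st = walking_vars_st,
    walking_dt = walking_vars_dt
  )
}

#' Normality-gated correlation battery
#'
#' Runs every cognitive predictor against every TUG phase time and walking
#' metric (3 x 19 = 57 pairs). Each pair uses Pearson or Spearman according
#' to the Shapiro-Wilk gate on both members; pairs are pairwise-complete and
#' per-pair failures are recorded as rows with NA estimates rather than
#' aborting the battery.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param config An [analysis_config()].
#'
#' @return Tibble of correlation rows with a `significant` flag at
#'   `config$alpha`.
#' @export
run_correlation_battery <- function(cohort, config = analysis_config()) {
  deps <- unlist(battery_dependents(), use.names = FALSE)
  deps <- intersect(deps, names(cohort))
  preds <- intersect(cognitive_vars, names(cohort))
  normality <- normality_table(cohort, c(preds, deps), config$alpha)
  flag <- setNames(normality$normal, normality$variable)
  purrr::map_dfr(preds, function(pv) {
    purrr::map_dfr(deps, function(dv) {
      method <- choose_method(isTRUE(flag[[pv]]), isTRUE(flag[[dv]]))
      res <- tryCatch(
        correlate(cohort[[pv]], cohort[[dv]], method,
                  predictor = pv, dependent = dv),
        error = function(e) {
          warn(sprintf("correlation %s ~ %s failed: %s", pv, dv,
                       conditionMessage(e)), class = "pdgait_log")
          tibble::tibble(predictor = pv, dependent = dv, method = method,
                         n = NA_integer_, r = NA_real_, p = NA_real_,
                         ci_lower = NA_real_, ci_upper = NA_real_)
        })
      res
    })
  }) |>
    dplyr::mutate(significant = !is.na(.data$p) & .data$p < config$alpha)
}

normality_table <- function(cohort, vars, alpha) {
  purrr::map_dfr(vars, function(v) {
    tryCatch(shapiro_wilk(cohort[[v]], variable = v, alpha = alpha),
             error = function(e) tibble::tibble(
               variable = v, n = sum(is.finite(cohort[[v]])),
               W = NA_real_, p = NA_real_, normal = NA))
  })
}

#' Full motor-cognitive statistical report
#'
#' The complete battery in the order of the source pipeline: Shapiro-Wilk
#' normality for every analysis variable; the 57-pair normality-gated
#' correlation battery; one multivariable OLS fit per dependent variable on
#' the three cognitive scores; a MANOVA (four multivariate statistics per
#' term) per response block (TUG phases, single-task metrics, dual-task
#' metrics); and the predictor VIF screen. Deterministic given cohort and
#' configuration.
#'
#' @param cohort A cohort tibble with the registry columns.
#' @param config An [analysis_config()].
#'
#' @return A `stat_report`: list of tibbles `normality`, `correlations`,
#'   `ols`, `manova`, `vif` plus a configuration echo.
#' @export
run_full_battery <- function(cohort, config = analysis_config()) {
  reg <- cohort_registry()
  vars <- intersect(reg$all, names(cohort))
  dropped <- vars[vapply(vars, function(v) all(!is.finite(cohort[[v]])), TRUE)]
  if (length(dropped)) {
    warn(paste0("Dropping all-missing column(s): ",
                paste(dropped, collapse = ", ")), class = "pdgait_log")
    vars <- setdiff(vars, dropped)
    cohort <- cohort[setdiff(names(cohort), dropped)]
  }
  preds <- intersect(reg$cognitive, vars)
  deps <- setdiff(vars, preds)

  normality <- normality_table(cohort, vars, config$alpha)
  correlations <- run_correlation_battery(cohort, config)

  ols_rows <- purrr::map(deps, function(dv) {
    fit <- ols_fit(cohort[preds], cohort[[dv]], dependent = dv)
    dplyr::mutate(tibble::as_tibble(fit),
                  r_squared = attr(fit, "r_squared"),
                  adj_r_squared = attr(fit, "adj_r_squared"),
                  n = attr(fit, "n"))
  })
  ols_table <- dplyr::bind_rows(ols_rows)

  manova_table <- purrr::imap_dfr(battery_dependents(), function(block_vars, block) {
    block_vars <- intersect(block_vars, deps)
    if (length(block_vars) < 1) return(NULL)
    X <- cohort[preds]
    Y <- cohort[block_vars]
    ok <- complete.cases(X) & complete.cases(Y)
    if (sum(ok) <= length(preds) + length(block_vars)) {
      warn(sprintf("MANOVA block '%s' skipped: insufficient complete rows.",
                   block), class = "pdgait_log")
      return(NULL)
    }
    dplyr::mutate(tibble::as_tibble(manova_battery(X, Y)),
                  block = block, .before = 1)
  })

  vif_table <- vif(cohort[preds][complete.cases(cohort[preds]), ])

  structure(
    list(
      normality = normality,
      correlations = correlations,
      ols = ols_table,
      manova = manova_table,
      vif = vif_table,
      config = config,
      n = nrow(cohort)
    ),
    class = "stat_report"
  )
}

#' @export
#' @method print stat_report
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> n = %d participants\n", x$n))
  cat(sprintf("  normality: %d variables (%d non-normal)\n",
              nrow(x$normality), sum(!x$normality$normal, na.rm = TRUE)))
  cat(sprintf("  correlations: %d pairs (%d significant at alpha = %g)\n",
              nrow(x$correlations), sum(x$correlations$significant),
              x$config$alpha))
  cat(sprintf("  OLS fits: %d dependents; MANOVA blocks: %d; max VIF: %.2f\n",
              length(unique(x$ols$dependent)),
              length(unique(x$manova$block)), max(x$vif$vif)))
  invisible(x)
}

fmt_table <- function(df, digits = 10) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- formatC(df[[j]], digits = digits,
                                                format = "g")
    if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  }
  df
}

write_tsv_stable <- function(df, path) {
  df <- fmt_table(df)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    lines <- do.call(paste, c(unname(df), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write a statistical report to disk
#'
#' Emits one TSV per table (mirroring the tabular layouts of the analysis:
#' correlations with r/p/CI, OLS with B/SE/t/p/CI/R2, MANOVA with the four
#' statistics) plus a single JSON bundle. Output is byte-stable for
#' identical inputs.
#'
#' @param report A `stat_report` from [run_full_battery()].
#' @param out_dir Output directory (created if absent).
#'
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", out_dir),
                   class = "pdgait_io_error")
  }
  if (file.access(out_dir, 2) != 0) {
    abort(sprintf("Output directory '%s' is not writable.", out_dir),
          class = "pdgait_io_error")
  }
  tables <- c("normality", "correlations", "ols", "manova", "vif")
  paths <- character(0)
  for (tb in tables) {
    p <- file.path(out_dir, paste0(tb, ".tsv"))
    write_tsv_stable(report[[tb]], p)
    paths <- c(paths, p)
  }
  json_path <- file.path(out_dir, "report.json")
  bundle <- list(
    n = report$n,
    config = report$config[setdiff(names(report$config), "seed")],
    seed = report$config$seed,
    tables = lapply(report[tables], function(df) {
      df <- as.data.frame(df)
      df[] <- lapply(df, function(col) if (is.factor(col)) as.character(col) else col)
      df
    })
  )
  json <- jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = 12,
                           null = "null", na = "null")
  con <- file(json_path, open = "wb")
  writeLines(json, con, sep = "\n")
  close(con)
  invisible(c(paths, json_path))
}
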