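# Trajectory file dialect: a block of "# key: value" metadata lines followed
# by a wide CSV, one row per frame, columns "<series>_<axis>" (com_x, ...)
# and "<series>_r11".."_r33" for rotation series. Declared units (ms -> s,
# mm -> m) are the only coercions applied.

parse_header <- function(lines) {
  meta <- list()
  for (ln in lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  meta
}

#' Read a trial recording from a trajectory CSV
#'
#' The file starts with `# key: value` metadata lines declaring at least
#' `rate_hz` and `condition`; optional keys are `trial_id`, `impaired_side`,
#' `time_units` (`s`/`ms`), `length_units` (`m`/`mm`) and `axis_order`
#' (a permutation of `xyz` mapping the file's axis suffixes onto the lab
#' convention x-forward / z-up).
#'
#' @param path Trajectory file path.
#' @param config An [analysis_config()] (reserved for reader options).
#'
#' @return A validated [trial_recording()].
#' @export
read_trial <- function(path, config = analysis_config()) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "pdgait_io_error")
  }
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  n_hdr <- if (any(!hdr)) which(!hdr)[1] - 1L else length(lines)
  meta <- parse_header(lines[seq_len(n_hdr)])
  for (key in c("rate_hz", "condition")) {
    if (is.null(meta[[key]])) {
      abort(sprintf("Header is missing mandatory key '%s'.", key),
            class = "pdgait_schema_error")
    }
  }
  dat <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"),
                         check.names = FALSE)
  dat <- tibble::as_tibble(dat)
  if (!"t" %in% names(dat)) {
    abort("Missing mandatory column: t", class = "pdgait_schema_error")
  }

  time_units <- meta$time_units %||% "s"
  if (time_units == "ms") dat$t <- dat$t / 1000
  else if (time_units != "s") {
    abort(sprintf("Unsupported time_units '%s' (use s or ms).", time_units),
          class = "pdgait_schema_error")
  }
  length_units <- meta$length_units %||% "m"
  pos_cols <- setdiff(names(dat)[!grepl("_r[1-3][1-3]$", names(dat))], "t")
  if (length_units == "mm") {
    dat[pos_cols] <- dat[pos_cols] / 1000
  } else if (length_units != "m") {
    abort(sprintf("Unsupported length_units '%s' (use m or mm).", length_units),
          class = "pdgait_schema_error")
  }

  axis_order <- meta$axis_order %||% "xyz"
  if (axis_order != "xyz") {
    ax <- strsplit(axis_order, "")[[1]]
    if (!setequal(ax, c("x", "y", "z"))) {
      abort(sprintf("axis_order '%s' is not a permutation of xyz.", axis_order),
            class = "pdgait_schema_error")
    }
    # file suffix ax[i] holds the lab axis c("x","y","z")[i]
    ren <- setNames(c("x", "y", "z"), ax)
    nm <- names(dat)
    suf <- sub("^.*_", "", nm)
    base <- sub("_[xyz]$", "", nm)
    swap <- suf %in% c("x", "y", "z") & nm != "t"
    names(dat)[swap] <- paste0(base[swap], "_", ren[suf[swap]])
  }

  trial_recording(
    dat,
    trial_id = meta$trial_id %||% basename(path),
    condition = meta$condition,
    rate_hz = as.numeric(meta$rate_hz),
    impaired_side = meta$impaired_side %||% "none"
  )
}

#' Write a trial recording to a trajectory CSV
#'
#' Numeric values are written with 15 significant digits so a write/read
#' round trip reproduces every series to well under 1e-9 relative error.
#'
#' @param trial A [trial_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trial <- function(trial, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# trial_id: %s", trial$trial_id),
    sprintf("# condition: %s", trial$condition),
    sprintf("# rate_hz: %.10g", trial$rate_hz),
    sprintf("# impaired_side: %s", trial$impaired_side),
    "# time_units: s",
    "# length_units: m",
    "# axis_order: xyz"
  ), con, sep = "\n")
  df <- fmt_table(trial$data, digits = 15)
  writeLines(paste(names(df), collapse = ","), con, sep = "\n")
  writeLines(do.call(paste, c(unname(df), sep = ",")), con, sep = "\n")
  invisible(path)
}

#' Read a cohort table
#'
#' A delimited table (TSV or CSV, sniffed from the header line) with one row
#' per participant. `participant_id` is mandatory and must be unique;
#' registry columns (see [cohort_registry()]) are typed numeric; unknown
#' columns are preserved but ignored by the battery. Missing cells are
#' permitted and reported.
#'
#' @param path Cohort file path.
#' @return A tibble of participants.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "pdgait_io_error")
  }
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  dat <- tibble::as_tibble(utils::read.delim(path, sep = sep,
                                             check.names = FALSE))
  if (!"participant_id" %in% names(dat)) {
    abort("Cohort table must contain a participant_id column.",
          class = "pdgait_schema_error")
  }
  dup <- unique(dat$participant_id[duplicated(dat$participant_id)])
  if (length(dup)) {
    abort(paste0("Duplicate participant_id value(s): ",
                 paste(dup, collapse = ", ")),
          class = "pdgait_schema_error")
  }
  reg <- intersect(cohort_registry()$all, names(dat))
  # registry columns are numeric; unparseable cells become missing values
  dat[reg] <- lapply(dat[reg], function(col) suppressWarnings(as.numeric(col)))
  n_miss <- sum(!complete.cases(dat[reg]))
  if (n_miss > 0) {
    inform(sprintf("%d participant row(s) have missing analysis values.",
                   n_miss), class = "pdgait_log")
  }
  dat
}

#' Write a cohort table as TSV
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  write_tsv_stable(fmt_table(cohort, digits = 15), path)
}
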