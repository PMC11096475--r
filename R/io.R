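# Readers and writers for the CSV interchange schemas and the JSON/
# Markdown run report.

# Supplementary tables copied out of PDFs often carry the typographic
# minus sign (U+2212); normalize before numeric conversion.
.normalize_minus <- function(x) gsub("−", "-", x)

.as_num <- function(x, col, what) {
  out <- suppressWarnings(as.numeric(.normalize_minus(as.character(x))))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    stop(what, " row ", bad[1L], ": column '", col,
         "' is not numeric ('", x[bad[1L]], "')", call. = FALSE)
  }
  out
}

#' Read a trial table
#'
#' Reads the trial-level arm-summary CSV. Two schemas are supported, both
#' with key columns `trial_id`, `comparison_id`, `outcome_id`:
#' \itemize{
#'   \item continuous: `n_t, mean_t, sd_t, n_c, mean_c, sd_c`, optionally a
#'     `value_kind` column (`"sd"` or `"se"`); rows carrying standard
#'     errors are converted with `sd = se * sqrt(n)` and flagged in the
#'     logical `se_converted` column of the result;
#'   \item dichotomous: `events_t, total_t, events_c, total_c`.
#' }
#' Typographic minus signs are accepted. Rows failing arm validation (n <
#' 2, sd <= 0, events > total) raise an error naming the row and field.
#'
#' @param path CSV file path.
#' @return validated data frame; attribute `schema` is `"continuous"` or
#'   `"dichotomous"`.
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  key <- c("trial_id", "comparison_id", "outcome_id")
  miss <- setdiff(key, names(raw))
  if (length(miss)) {
    stop("trial file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cont <- c("n_t", "mean_t", "sd_t", "n_c", "mean_c", "sd_c")
  dich <- c("events_t", "total_t", "events_c", "total_c")
  if (all(cont %in% names(raw))) {
    schema <- "continuous"
    out <- raw[key]
    for (col in cont) out[[col]] <- .as_num(raw[[col]], col, "trial file")
    out$se_converted <- FALSE
    if ("value_kind" %in% names(raw)) {
      kind <- tolower(trimws(raw$value_kind))
      bad <- which(!kind %in% c("sd", "se"))
      if (length(bad)) {
        stop("trial file row ", bad[1L],
             ": value_kind must be 'sd' or 'se'", call. = FALSE)
      }
      se_rows <- kind == "se"
      out$sd_t[se_rows] <- out$sd_t[se_rows] * sqrt(out$n_t[se_rows])
      out$sd_c[se_rows] <- out$sd_c[se_rows] * sqrt(out$n_c[se_rows])
      out$se_converted <- se_rows
    }
    for (i in seq_len(nrow(out))) {
      r <- out[i, ]
      if (any(is.na(c(r$n_t, r$mean_t, r$sd_t, r$n_c, r$mean_c, r$sd_c)))) {
        stop("trial file row ", i, ": missing arm summary value",
             call. = FALSE)
      }
      if (r$n_t < 2 || r$n_c < 2) {
        stop("trial file row ", i, ": arm n must be >= 2", call. = FALSE)
      }
      if (r$sd_t <= 0 || r$sd_c <= 0) {
        stop("trial file row ", i, ": arm sd must be > 0", call. = FALSE)
      }
    }
  } else if (all(dich %in% names(raw))) {
    schema <- "dichotomous"
    out <- raw[key]
    for (col in dich) out[[col]] <- .as_num(raw[[col]], col, "trial file")
    for (i in seq_len(nrow(out))) {
      r <- out[i, ]
      if (any(is.na(c(r$events_t, r$total_t, r$events_c, r$total_c)))) {
        stop("trial file row ", i, ": missing cell count", call. = FALSE)
      }
      if (r$total_t <= 0 || r$total_c <= 0 ||
          r$events_t < 0 || r$events_c < 0 ||
          r$events_t > r$total_t || r$events_c > r$total_c) {
        stop("trial file row ", i, ": events must lie in [0, total]",
             call. = FALSE)
      }
    }
  } else {
    stop("trial file matches neither the continuous (",
         paste(cont, collapse = ", "), ") nor the dichotomous (",
         paste(dich, collapse = ", "), ") schema", call. = FALSE)
  }
  extra <- setdiff(names(raw), c(key, cont, dich, "value_kind"))
  if (length(extra)) {
    warning("trial file: ignoring unknown column(s) ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  if (any(out$trial_id == "" | out$comparison_id == "" |
          out$outcome_id == "")) {
    stop("trial file: empty identifier", call. = FALSE)
  }
  attr(out, "schema") <- schema
  out
}

#' Read an appraisal table
#'
#' Reads the per-trial appraisal CSV (columns `trial_id`, `cqs_c1` ...
#' `cqs_c4`, `rob2_overall`), scores every row with [score_cqs()] and
#' canonicalizes the RoB 2 labels with [parse_rob2()]. Duplicate trial ids
#' and non-binary criterion scores are rejected.
#'
#' @param path CSV file path.
#' @return scored appraisal data frame (see [score_cqs_table()]); an empty
#'   file yields an empty table with a warning.
#' @export
read_appraisals <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(raw)) {
    warning("appraisal file is empty", call. = FALSE)
    return(data.frame(trial_id = character(0), cqs_c1 = integer(0),
                      cqs_c2 = integer(0), cqs_c3 = integer(0),
                      cqs_c4 = integer(0), rob2_overall = character(0),
                      overall = integer(0), c_level = integer(0),
                      stringsAsFactors = FALSE))
  }
  score_cqs_table(raw)
}

# Flatten a run report into plain lists for lossless JSON round-tripping.
.report_as_list <- function(run) {
  stopifnot(inherits(run, "cqs_run"))
  list(
    config = unclass(run$config),
    inputs = run$inputs,
    seed = run$seed,
    exclusions = run$exclusions,
    stratification = run$stratification,
    second_stage = lapply(run$second_stage, unclass),
    wald = unclass(run$wald),
    conclusions = run$conclusions,
    log = run$log
  )
}

#' Write a run report
#'
#' Serializes a pipeline run. JSON is always written; optional outputs are
#' a Markdown summary whose conclusion table mirrors the qualitative
#' comparison layout (one row per comparison x outcome, one conclusion
#' column per tool) and a forest-plot CSV holding one row per trial
#' estimate in each stratum plus one pooled row per stratum.
#'
#' @param run a `"cqs_run"` from [run_pipeline()].
#' @param path output path without extension; `<path>.json`, `<path>.md`
#'   and `<path>_forest.csv` are created as requested.
#' @param formats subset of `c("json", "md", "forest")`.
#' @return invisibly, the named vector of files written.
#' @export
write_report <- function(run, path, formats = c("json", "md", "forest")) {
  formats <- match.arg(formats, several.ok = TRUE)
  written <- character(0)
  if ("json" %in% formats) {
    f <- paste0(path, ".json")
    jsonlite::write_json(.report_as_list(run), f, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    written["json"] <- f
  }
  if ("md" %in% formats) {
    f <- paste0(path, ".md")
    writeLines(.report_markdown(run), f)
    written["md"] <- f
  }
  if ("forest" %in% formats) {
    f <- paste0(path, "_forest.csv")
    utils::write.csv(forest_table(run), f, row.names = FALSE)
    written["forest"] <- f
  }
  invisible(written)
}

#' Read back a JSON run report
#'
#' @param path path to a `.json` file written by [write_report()].
#' @return the report as a plain list (data frames restored for tabular
#'   sections).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Forest-plot table for a run
#'
#' One row per trial estimate within each (tool, comparison, outcome,
#' level) stratum, followed by that stratum's pooled row (`row_type`
#' distinguishes them).
#'
#' @param run a `"cqs_run"`.
#' @return data frame ready for plotting or export.
#' @export
forest_table <- function(run) {
  fs <- run$stratification
  st <- run$strata
  rows <- list()
  for (i in seq_len(nrow(fs))) {
    s <- fs[i, ]
    in_stratum <- st$tool == s$tool &
      st$comparison_id == s$comparison_id &
      st$outcome_id == s$outcome_id & st$level == s$level
    g <- st[in_stratum, ]
    rows[[length(rows) + 1L]] <- data.frame(
      tool = s$tool, comparison_id = s$comparison_id,
      outcome_id = s$outcome_id, level = s$level,
      row_type = c(rep("trial", nrow(g)), "pooled"),
      trial_id = c(g$trial_id, NA_character_),
      theta = c(g$theta, s$theta), se = c(g$se, s$se),
      ci_low = c(g$ci_low, s$ci_low), ci_high = c(g$ci_high, s$ci_high),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.report_markdown <- function(run) {
  lines <- c("# Appraisal-comparison run report", "",
             sprintf("- measure: %s; CI level: %g; alpha: %g; seed: %d",
                     run$config$measure, run$config$ci_level,
                     run$config$alpha, run$seed),
             sprintf("- trial records: %d (%d trials)",
                     run$inputs$n_trial_records, run$inputs$n_trials), "")
  if (nrow(run$exclusions)) {
    lines <- c(lines, "## Excluded comparisons", "",
               sprintf("- %s: %d trials (%s)",
                       run$exclusions$comparison_id,
                       run$exclusions$n_trials, run$exclusions$reason), "")
  }
  lines <- c(lines, "## Second-stage pooled estimates", "")
  for (tool in names(run$second_stage)) {
    r <- run$second_stage[[tool]]
    lines <- c(lines, sprintf(
      "- %s: %.4f, %g%% CI [%.4f, %.4f], I^2 = %.1f%%, k = %d",
      tool, r$theta_pooled, 100 * r$ci_level, r$ci_low, r$ci_high,
      r$i2, r$k))
  }
  lines <- c(lines, "",
             sprintf("Wald comparison: z = %.4f, p = %.4g", run$wald$z,
                     run$wald$p), "",
             "## Qualitative comparison", "",
             "| Comparison | Outcome | RoB 2 | CQS-2B |",
             "|---|---|---|---|")
  cells <- unique(run$conclusions[c("comparison_id", "outcome_id")])
  for (i in seq_len(nrow(cells))) {
    sub <- run$conclusions[
      run$conclusions$comparison_id == cells$comparison_id[i] &
      run$conclusions$outcome_id == cells$outcome_id[i], ]
    pick <- function(tool) {
      t <- sub$text[sub$tool == tool]
      if (length(t)) t[1L] else "(no selected stratum)"
    }
    lines <- c(lines, sprintf("| %s | %s | %s | %s |",
                              cells$comparison_id[i], cells$outcome_id[i],
                              pick("rob2"), pick("cqs2b")))
  }
  lines
}
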