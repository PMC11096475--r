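# Two-stage stratified pooling pipeline: stratify by appraisal tool,
# select the stratum each tool licenses, pool in two stages, compare the
# tools' pooled estimates, and map results to qualitative conclusions.

#' Pipeline run configuration
#'
#' @param measure effect measure for continuous records: `"SMD_hedges"`
#'   (default; unitless, coherent across outcomes), `"MD"` or `"logOR"`.
#' @param ci_level two-sided confidence level (default 0.95).
#' @param alpha significance level for the Wald comparison (default 0.05).
#' @param min_trials_per_comparison comparisons with fewer distinct trials
#'   are excluded before pooling (default 5).
#' @param beneficial_direction named character vector mapping each
#'   `outcome_id` to `"negative"` (lower is better, e.g. LDL cholesterol)
#'   or `"positive"` (higher is better, e.g. HDL cholesterol). An entry
#'   named `".default"` covers unlisted outcomes.
#' @param seed integer seed recorded in the run report.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(measure = "SMD_hedges", ci_level = 0.95, alpha = 0.05,
                       min_trials_per_comparison = 5,
                       beneficial_direction = c(.default = "negative"),
                       seed = 1L) {
  measure <- match.arg(measure, .effect_measures)
  stopifnot(ci_level > 0, ci_level < 1, alpha > 0, alpha < 1,
            min_trials_per_comparison >= 1)
  if (!all(beneficial_direction %in% c("negative", "positive"))) {
    stop("beneficial_direction values must be 'negative' or 'positive'",
         call. = FALSE)
  }
  structure(list(measure = measure, ci_level = ci_level, alpha = alpha,
                 min_trials_per_comparison = as.integer(min_trials_per_comparison),
                 beneficial_direction = beneficial_direction,
                 seed = as.integer(seed)),
            class = "run_config")
}

.direction_for <- function(config, outcome_id) {
  bd <- config$beneficial_direction
  if (outcome_id %in% names(bd)) return(unname(bd[[outcome_id]]))
  if (".default" %in% names(bd)) return(unname(bd[[".default"]]))
  stop("no beneficial_direction configured for outcome '", outcome_id, "'",
       call. = FALSE)
}

#' Drop comparisons with too few trials
#'
#' Removes every comparison whose number of distinct trials falls below
#' `config$min_trials_per_comparison`; exclusions are recorded in the
#' `"exclusions"` attribute of the result.
#'
#' @param records trial record data frame (columns `trial_id`,
#'   `comparison_id`, ...).
#' @param config a [run_config()].
#' @return the filtered data frame, with attribute `exclusions`: a data
#'   frame of dropped comparisons and their trial counts.
#' @export
filter_comparisons <- function(records, config = run_config()) {
  counts <- tapply(records$trial_id, records$comparison_id,
                   function(x) length(unique(x)))
  drop <- names(counts)[counts < config$min_trials_per_comparison]
  out <- records[!(records$comparison_id %in% drop), , drop = FALSE]
  attr(out, "exclusions") <- data.frame(
    comparison_id = drop,
    n_trials = as.integer(counts[drop]),
    reason = if (length(drop)) {
      sprintf("fewer than %d trials", config$min_trials_per_comparison)
    } else character(0),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!nrow(out) && nrow(records)) {
    warning("all comparisons fell below the minimum trial count",
            call. = FALSE)
  }
  out
}

#' Stratify trial records by both appraisal tools
#'
#' Assigns every trial record its RoB 2 overall rating stratum and its
#' CQS-2B corroboration-level stratum. Within each comparison x outcome
#' cell the strata of each tool partition the records.
#'
#' @param records trial record data frame (`trial_id`, `comparison_id`,
#'   `outcome_id`, plus effect columns if already computed).
#' @param appraisals scored appraisal table from [score_cqs_table()] (or a
#'   raw appraisal table, which is scored on the fly).
#' @return a data frame with one row per record x tool: the record columns
#'   plus `tool` (`"rob2"` or `"cqs2b"`) and `level` (rating label or
#'   C-level as character).
#' @export
stratify <- function(records, appraisals) {
  if (!all(c("c_level", "overall") %in% names(appraisals))) {
    appraisals <- score_cqs_table(appraisals)
  }
  missing_ids <- setdiff(records$trial_id, appraisals$trial_id)
  if (length(missing_ids)) {
    stop("no appraisal for trial '", missing_ids[1L], "'", call. = FALSE)
  }
  idx <- match(records$trial_id, appraisals$trial_id)
  rob2 <- records
  rob2$tool <- "rob2"
  rob2$level <- appraisals$rob2_overall[idx]
  cqs <- records
  cqs$tool <- "cqs2b"
  cqs$level <- as.character(appraisals$c_level[idx])
  rbind(rob2, cqs)
}

#' Select the stratum each tool licenses for one comparison x outcome cell
#'
#' RoB 2 conclusions rest on the `"low"` overall-risk stratum only; if no
#' trial in the cell is low risk, nothing is selected (`NA`). The CQS-2B
#' uses the highest corroboration level attained by at least one trial,
#' regardless of how many trials sit there.
#'
#' @param strata stratified records (from [stratify()]) restricted to one
#'   comparison x outcome cell.
#' @param tool `"rob2"` or `"cqs2b"`.
#' @return the selected level as a character scalar, or `NA_character_`
#'   when the tool selects nothing in this cell.
#' @export
select_stratum <- function(strata, tool = c("rob2", "cqs2b")) {
  tool <- match.arg(tool)
  levels_present <- unique(strata$level[strata$tool == tool])
  if (!length(levels_present)) {
    stop("no strata for tool '", tool, "' in this cell", call. = FALSE)
  }
  if (tool == "rob2") {
    if ("low" %in% levels_present) "low" else NA_character_
  } else {
    as.character(max(as.integer(levels_present)))
  }
}

# Pool one group of records that already carry theta/variance columns.
.pool_stratum <- function(records, config) {
  if (config$measure == "logOR" &&
      all(c("events_t", "total_t") %in% names(records))) {
    pool_mantel_haenszel(records, ci_level = config$ci_level)
  } else {
    pool_dl(records, ci_level = config$ci_level)
  }
}

#' First-stage pooling of every stratum
#'
#' Pools each (tool, comparison, outcome, level) stratum with
#' DerSimonian-Laird random effects (Mantel-Haenszel for dichotomous data).
#' All strata are pooled for transparency; the `selected` column marks the
#' stratum each tool carries into the second stage.
#'
#' @param strata stratified records with effect columns (output of
#'   [stratify()] applied to [compute_effects()] output).
#' @param config a [run_config()].
#' @return a data frame with one row per stratum: keys, `k`, pooled effect
#'   columns, heterogeneity columns and the logical `selected`.
#' @export
first_stage_pool <- function(strata, config = run_config()) {
  key <- interaction(strata$tool, strata$comparison_id, strata$outcome_id,
                     strata$level, drop = TRUE)
  groups <- split(strata, key)
  rows <- lapply(groups, function(g) {
    res <- .pool_stratum(g, config)
    data.frame(tool = g$tool[1L], comparison_id = g$comparison_id[1L],
               outcome_id = g$outcome_id[1L], level = g$level[1L],
               k = res$k, theta = res$theta_pooled, se = res$se,
               ci_low = res$ci_low, ci_high = res$ci_high,
               Q = res$Q, df = res$df, p_Q = res$p_Q,
               tau2 = res$tau2, i2 = res$i2, method = res$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$tool, out$comparison_id, out$outcome_id, out$level), ]
  rownames(out) <- NULL
  # mark selected strata per cell
  out$selected <- FALSE
  cells <- unique(out[c("tool", "comparison_id", "outcome_id")])
  for (i in seq_len(nrow(cells))) {
    in_cell <- strata$tool == cells$tool[i] &
      strata$comparison_id == cells$comparison_id[i] &
      strata$outcome_id == cells$outcome_id[i]
    sel <- select_stratum(strata[in_cell, , drop = FALSE], cells$tool[i])
    if (!is.na(sel)) {
      out$selected[out$tool == cells$tool[i] &
                   out$comparison_id == cells$comparison_id[i] &
                   out$outcome_id == cells$outcome_id[i] &
                   out$level == sel] <- TRUE
    }
  }
  out
}

#' Second-stage pooling across comparisons and outcomes
#'
#' Pools the selected first-stage results of one tool with
#' DerSimonian-Laird random effects, treating each first-stage pooled
#' estimate (theta, se^2) as a single input estimate.
#'
#' @param first_stage first-stage table from [first_stage_pool()],
#'   restricted to one tool's selected rows (rows of other tools or
#'   unselected strata are ignored if a `selected`/`tool` column is
#'   present and `tool`/`selected_only` are supplied).
#' @param tool optional tool filter applied when the table carries a
#'   `tool` column.
#' @param config a [run_config()].
#' @param selected_only keep only rows flagged `selected` (default TRUE
#'   when the column is present).
#' @return a `"meta_result"` for the tool's overall pooled estimate.
#' @export
second_stage_pool <- function(first_stage, tool = NULL,
                              config = run_config(),
                              selected_only = TRUE) {
  fs <- first_stage
  if (!is.null(tool) && "tool" %in% names(fs)) fs <- fs[fs$tool == tool, ]
  if (selected_only && "selected" %in% names(fs)) fs <- fs[fs$selected, ]
  if (!nrow(fs)) stop("no first-stage results to pool", call. = FALSE)
  pool_dl(data.frame(theta = fs$theta, variance = fs$se^2),
          ci_level = config$ci_level)
}

#' Wald comparison of the two tools' second-stage estimates
#'
#' @param rob2_pooled,cqs_pooled `"meta_result"` objects from
#'   [second_stage_pool()].
#' @param config a [run_config()]; supplies `alpha`.
#' @return a `"wald_comparison"`.
#' @export
compare_tools <- function(rob2_pooled, cqs_pooled, config = run_config()) {
  wald_compare(rob2_pooled, cqs_pooled, alpha = config$alpha)
}

#' Qualitative conclusion for one comparison x outcome cell
#'
#' RoB 2 cells conclude `"beneficial"` when the pooled CI excludes zero on
#' the outcome's beneficial side, else `"no_benefit"`. CQS-2B cells whose
#' selected corroboration level is below 4 yield `"no_conclusion"`: the
#' first unmet criterion names a bias mechanism with empirical evidence of
#' effect overestimation, so the estimate cannot support a clinical claim.
#' A (hypothetical) fully corroborated C4 stratum is judged by the same CI
#' rule as RoB 2.
#'
#' @param tool `"rob2"` or `"cqs2b"`.
#' @param pooled the cell's first-stage `"meta_result"` (or a row of the
#'   first-stage table coerced with `as.list`); required unless the CQS
#'   C-level rule short-circuits.
#' @param c_level the selected corroboration level (CQS-2B only).
#' @param comparison_id,outcome_id cell identifiers.
#' @param config a [run_config()]; supplies the beneficial direction map.
#' @return list of class `"conclusion"` with `verdict` (`"beneficial"`,
#'   `"no_benefit"` or `"no_conclusion"`), `reason` and display `text`.
#' @export
conclude <- function(tool = c("rob2", "cqs2b"), pooled = NULL,
                     c_level = NULL, comparison_id, outcome_id,
                     config = run_config()) {
  tool <- match.arg(tool)
  if (tool == "cqs2b") {
    if (is.null(c_level)) stop("cqs2b conclusion needs the selected C-level",
                               call. = FALSE)
    if (c_level < 4) {
      mech <- bias_mechanism(c_level + 1L)
      reason <- sprintf(
        "There is a high risk that the established effect estimate is overestimated due to %s.",
        mech)
      return(structure(
        list(comparison_id = comparison_id, outcome_id = outcome_id,
             tool = tool, verdict = "no_conclusion", reason = reason,
             text = paste("No conclusion.", reason)),
        class = "conclusion"))
    }
  }
  if (is.null(pooled)) stop("CI-based conclusion needs a pooled result",
                            call. = FALSE)
  dir <- .direction_for(config, outcome_id)
  beneficial <- if (dir == "negative") {
    pooled$ci_high < 0
  } else {
    pooled$ci_low > 0
  }
  verdict <- if (beneficial) "beneficial" else "no_benefit"
  structure(
    list(comparison_id = comparison_id, outcome_id = outcome_id,
         tool = tool, verdict = verdict,
         reason = sprintf("pooled CI [%.3f, %.3f] %s zero in the %s direction",
                          pooled$ci_low, pooled$ci_high,
                          if (beneficial) "excludes" else "does not exclude",
                          dir),
         text = if (beneficial) "Has beneficial effect"
                else "Has no beneficial effect"),
    class = "conclusion")
}

#' Run the full appraisal-comparison pipeline
#'
#' Orchestrates the complete procedure: validate and score the appraisal
#' table, exclude undersized comparisons, compute per-trial effects,
#' stratify by both tools, pool every stratum (first stage), pool each
#' tool's selected strata across comparisons and outcomes (second stage),
#' compare the two pooled estimates with a Wald test, and derive the
#' qualitative conclusion each tool licenses per comparison x outcome.
#' Fully deterministic given its inputs.
#'
#' @param trials trial table (see [read_trials()] for the schema).
#' @param appraisals appraisal table (see [read_appraisals()]).
#' @param config a [run_config()].
#' @return list of class `"cqs_run"` with elements `config`, `inputs`
#'   (dimensions), `exclusions`, `stratification` (per-stratum counts and
#'   pooled results), `second_stage` (per tool), `wald`, `conclusions`
#'   (data frame, one row per comparison x outcome x tool) and `log`.
#' @export
run_pipeline <- function(trials, appraisals, config = run_config()) {
  if (!is.data.frame(trials) || !nrow(trials)) {
    stop("pipeline input: empty trial table", call. = FALSE)
  }
  log <- character(0)
  appraisals <- score_cqs_table(appraisals)

  filtered <- filter_comparisons(trials, config)
  exclusions <- attr(filtered, "exclusions")
  if (nrow(exclusions)) {
    log <- c(log, sprintf("excluded comparison '%s' (%d trials < %d)",
                          exclusions$comparison_id, exclusions$n_trials,
                          config$min_trials_per_comparison))
  }
  if (!nrow(filtered)) stop("pipeline: no comparisons left after filtering",
                            call. = FALSE)

  effects <- compute_effects(filtered, measure = config$measure,
                             ci_level = config$ci_level)
  strata <- stratify(effects, appraisals)
  first_stage <- first_stage_pool(strata, config)

  # log cells RoB 2 cannot serve
  cells <- unique(first_stage[c("tool", "comparison_id", "outcome_id")])
  for (i in which(cells$tool == "rob2")) {
    sel <- first_stage$selected[first_stage$tool == "rob2" &
      first_stage$comparison_id == cells$comparison_id[i] &
      first_stage$outcome_id == cells$outcome_id[i]]
    if (!any(sel)) {
      log <- c(log, sprintf(
        "no 'low risk' trials for %s / %s: cell skipped for RoB 2",
        cells$comparison_id[i], cells$outcome_id[i]))
    }
  }

  second_stage <- list(
    rob2  = second_stage_pool(first_stage, tool = "rob2", config = config),
    cqs2b = second_stage_pool(first_stage, tool = "cqs2b", config = config)
  )
  wald <- compare_tools(second_stage$rob2, second_stage$cqs2b, config)

  sel_rows <- first_stage[first_stage$selected, ]
  conclusions <- do.call(rbind, lapply(seq_len(nrow(sel_rows)), function(i) {
    r <- sel_rows[i, ]
    cl <- conclude(tool = r$tool, pooled = as.list(r),
                   c_level = if (r$tool == "cqs2b") as.integer(r$level) else NULL,
                   comparison_id = r$comparison_id, outcome_id = r$outcome_id,
                   config = config)
    data.frame(comparison_id = cl$comparison_id, outcome_id = cl$outcome_id,
               tool = cl$tool, level = r$level, k = r$k,
               verdict = cl$verdict, text = cl$text, reason = cl$reason,
               stringsAsFactors = FALSE)
  }))
  conclusions <- conclusions[order(conclusions$comparison_id,
                                   conclusions$outcome_id,
                                   conclusions$tool), ]
  rownames(conclusions) <- NULL

  structure(
    list(config = config,
         inputs = list(n_trial_records = nrow(trials),
                       n_trials = length(unique(trials$trial_id)),
                       n_appraisals = nrow(appraisals)),
         exclusions = exclusions,
         stratification = first_stage,
         second_stage = second_stage,
         wald = wald,
         conclusions = conclusions,
         estimates = effects,
         strata = strata,
         log = log,
         seed = config$seed),
    class = "cqs_run")
}

#' @export
print.cqs_run <- function(x, ...) {
  cat("Appraisal-comparison run\n")
  cat(sprintf("  %d trial records, %d trials, measure %s\n",
              x$inputs$n_trial_records, x$inputs$n_trials, x$config$measure))
  if (nrow(x$exclusions)) {
    cat(sprintf("  excluded comparisons: %s\n",
                paste(x$exclusions$comparison_id, collapse = ", ")))
  }
  cat("  second-stage pooled estimates:\n")
  for (tool in names(x$second_stage)) {
    r <- x$second_stage[[tool]]
    cat(sprintf("    %-6s %7.4f, %g%% CI [%7.4f, %7.4f], I^2 = %.1f%% (k = %d)\n",
                tool, r$theta_pooled, 100 * r$ci_level, r$ci_low, r$ci_high,
                r$i2, r$k))
  }
  cat(sprintf("  Wald comparison: z = %.3f, p = %.3g\n", x$wald$z, x$wald$p))
  invisible(x)
}
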