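# Per-trial effect estimates from arm-level summary statistics.

#' Arm summary for a continuous outcome
#'
#' @param n number of subjects (>= 2).
#' @param mean arm mean, in outcome units.
#' @param sd arm standard deviation (> 0), in outcome units.
#' @return list of class `"arm_summary"`.
#' @export
arm_summary <- function(n, mean, sd) {
  if (is.na(n) || n < 2) stop("arm n must be >= 2", call. = FALSE)
  if (is.na(sd) || sd <= 0) stop("arm sd must be > 0", call. = FALSE)
  if (is.na(mean)) stop("arm mean must be finite", call. = FALSE)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "arm_summary")
}

#' Arm summary for a dichotomous outcome
#'
#' @param events number of events (>= 0).
#' @param total number of subjects (> 0, >= events).
#' @return list of class `"dichotomous_arm"`.
#' @export
dichotomous_arm <- function(events, total) {
  if (is.na(total) || total <= 0) stop("arm total must be > 0", call. = FALSE)
  if (is.na(events) || events < 0 || events > total) {
    stop("events must lie in [0, total]", call. = FALSE)
  }
  structure(list(events = as.integer(events), total = as.integer(total)),
            class = "dichotomous_arm")
}

.effect_measures <- c("MD", "SMD_hedges", "logOR")

new_effect_estimate <- function(theta, variance, measure, ci_level) {
  if (!is.finite(variance) || variance <= 0) {
    stop("effect variance must be positive and finite", call. = FALSE)
  }
  se <- sqrt(variance)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(theta = theta, variance = variance, se = se,
         ci_low = theta - z * se, ci_high = theta + z * se,
         measure = measure, ci_level = ci_level),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s = %.*f (SE %.*f), %g%% CI [%.*f, %.*f]\n",
              x$measure, digits, x$theta, digits, x$se,
              100 * x$ci_level, digits, x$ci_low, digits, x$ci_high))
  invisible(x)
}

#' Raw mean difference between two arms
#'
#' Computes the between-arm difference in means with sampling variance
#' `sd_t^2/n_t + sd_c^2/n_c`. Only meaningful when all pooled trials report
#' the outcome in the same units.
#'
#' @param test,control `"arm_summary"` objects (see [arm_summary()]).
#' @param ci_level two-sided confidence level (default 0.95).
#' @return an `"effect_estimate"` with `measure = "MD"`.
#' @examples
#' mean_difference(arm_summary(100, 3.2, 1), arm_summary(100, 3.0, 1))
#' @export
mean_difference <- function(test, control, ci_level = 0.95) {
  stopifnot(inherits(test, "arm_summary"), inherits(control, "arm_summary"))
  theta <- test$mean - control$mean
  v <- test$sd^2 / test$n + control$sd^2 / control$n
  new_effect_estimate(theta, v, "MD", ci_level)
}

#' Standardized mean difference (Hedges' g)
#'
#' Cohen's d standardized by the pooled within-arm SD, with the small-sample
#' bias correction `J = 1 - 3 / (4 * (n_t + n_c - 2) - 1)`:
#' `g = J * (mean_t - mean_c) / s_p`, where
#' `s_p^2 = ((n_t - 1) sd_t^2 + (n_c - 1) sd_c^2) / (n_t + n_c - 2)`.
#' Sampling variance is
#' `J^2 * ((n_t + n_c) / (n_t n_c) + d^2 / (2 (n_t + n_c - 2)))`.
#' Being unitless, the SMD is the default measure when pooling across
#' outcomes measured on different scales.
#'
#' @inheritParams mean_difference
#' @return an `"effect_estimate"` with `measure = "SMD_hedges"`.
#' @export
hedges_g <- function(test, control, ci_level = 0.95) {
  stopifnot(inherits(test, "arm_summary"), inherits(control, "arm_summary"))
  nt <- test$n; nc <- control$n
  df <- nt + nc - 2
  sp2 <- ((nt - 1) * test$sd^2 + (nc - 1) * control$sd^2) / df
  if (sp2 <= 0) stop("degenerate arms: pooled SD is zero", call. = FALSE)
  d <- (test$mean - control$mean) / sqrt(sp2)
  J <- 1 - 3 / (4 * df - 1)
  v <- J^2 * ((nt + nc) / (nt * nc) + d^2 / (2 * df))
  new_effect_estimate(J * d, v, "SMD_hedges", ci_level)
}

#' Log odds ratio from a 2x2 table
#'
#' `log((a d) / (b c))` with variance `1/a + 1/b + 1/c + 1/d`. When any cell
#' of the table is zero, 0.5 is added to all four cells (continuity
#' correction). A table in which both arms have no events, or both arms are
#' all events, carries no information about the odds ratio and raises an
#' error.
#'
#' @param test,control `"dichotomous_arm"` objects.
#' @inheritParams mean_difference
#' @return an `"effect_estimate"` with `measure = "logOR"`.
#' @export
log_odds_ratio <- function(test, control, ci_level = 0.95) {
  stopifnot(inherits(test, "dichotomous_arm"),
            inherits(control, "dichotomous_arm"))
  a <- test$events;    b <- test$total - test$events
  c_ <- control$events; d <- control$total - control$events
  if ((a == 0 && c_ == 0) || (b == 0 && d == 0)) {
    stop("odds ratio undefined: no variation in events across both arms",
         call. = FALSE)
  }
  if (min(a, b, c_, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  theta <- log((a * d) / (b * c_))
  v <- 1 / a + 1 / b + 1 / c_ + 1 / d
  new_effect_estimate(theta, v, "logOR", ci_level)
}

#' Compute per-trial effect estimates for a trial table
#'
#' Applies the chosen effect measure row-wise to a trial table in the
#' package's interchange schema (see [read_trials()]).
#'
#' @param trials data frame of trial records; continuous schema columns
#'   `n_t, mean_t, sd_t, n_c, mean_c, sd_c`, or dichotomous schema columns
#'   `events_t, total_t, events_c, total_c`, plus `trial_id`,
#'   `comparison_id`, `outcome_id`.
#' @param measure `"MD"`, `"SMD_hedges"` or `"logOR"`.
#' @param ci_level two-sided confidence level.
#' @return the input data frame with added columns `theta`, `variance`,
#'   `se`, `ci_low`, `ci_high` and `measure`.
#' @export
compute_effects <- function(trials, measure = "SMD_hedges", ci_level = 0.95) {
  measure <- match.arg(measure, .effect_measures)
  if (!nrow(trials)) stop("empty trial table", call. = FALSE)
  dich <- measure == "logOR"
  need <- if (dich) c("events_t", "total_t", "events_c", "total_c")
          else c("n_t", "mean_t", "sd_t", "n_c", "mean_c", "sd_c")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table lacks column(s) required for measure ", measure, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  est <- lapply(seq_len(nrow(trials)), function(i) {
    r <- trials[i, ]
    tryCatch({
      if (dich) {
        log_odds_ratio(dichotomous_arm(r$events_t, r$total_t),
                       dichotomous_arm(r$events_c, r$total_c), ci_level)
      } else if (measure == "MD") {
        mean_difference(arm_summary(r$n_t, r$mean_t, r$sd_t),
                        arm_summary(r$n_c, r$mean_c, r$sd_c), ci_level)
      } else {
        hedges_g(arm_summary(r$n_t, r$mean_t, r$sd_t),
                 arm_summary(r$n_c, r$mean_c, r$sd_c), ci_level)
      }
    }, error = function(e) {
      stop("trial '", r$trial_id, "' (row ", i, "): ", conditionMessage(e),
           call. = FALSE)
    })
  })
  trials$theta    <- vapply(est, `[[`, numeric(1), "theta")
  trials$variance <- vapply(est, `[[`, numeric(1), "variance")
  trials$se       <- vapply(est, `[[`, numeric(1), "se")
  trials$ci_low   <- vapply(est, `[[`, numeric(1), "ci_low")
  trials$ci_high  <- vapply(est, `[[`, numeric(1), "ci_high")
  trials$measure  <- measure
  trials
}
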