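# Fixed-effect and DerSimonian-Laird random-effects pooling, heterogeneity,
# Mantel-Haenszel pooling for 2x2 tables, and the Wald comparison of two
# pooled estimates.

# Normalize pooling input to a list(theta=, v=, measure=).
.theta_v <- function(estimates) {
  if (is.data.frame(estimates)) {
    if (!all(c("theta", "variance") %in% names(estimates))) {
      stop("estimate table needs columns 'theta' and 'variance'",
           call. = FALSE)
    }
    measure <- if ("measure" %in% names(estimates)) {
      unique(estimates$measure)
    } else NA_character_
    out <- list(theta = estimates$theta, v = estimates$variance,
                measure = measure)
  } else if (is.list(estimates) &&
             all(vapply(estimates, inherits, logical(1), "effect_estimate"))) {
    out <- list(theta = vapply(estimates, `[[`, numeric(1), "theta"),
                v = vapply(estimates, `[[`, numeric(1), "variance"),
                measure = unique(vapply(estimates, `[[`, character(1),
                                        "measure")))
  } else {
    stop("estimates must be a data frame with theta/variance columns or a ",
         "list of effect_estimate objects", call. = FALSE)
  }
  if (!length(out$theta)) stop("no estimates to pool", call. = FALSE)
  if (length(out$measure) > 1L) {
    stop("cannot pool estimates on mixed measures: ",
         paste(out$measure, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(out$v) | out$v <= 0)) {
    stop("all sampling variances must be positive and finite", call. = FALSE)
  }
  out
}

new_meta_result <- function(k, theta, se, Q, tau2, method, measure, ci_level) {
  df <- k - 1L
  i2 <- if (k > 1L && Q > 0) max(0, (Q - df) / Q) * 100 else 0
  p_Q <- if (k > 1L) stats::pchisq(Q, df, lower.tail = FALSE) else 1
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(k = as.integer(k), theta_pooled = theta, se = se,
         ci_low = theta - z * se, ci_high = theta + z * se,
         Q = Q, df = as.integer(df), p_Q = p_Q, tau2 = tau2, i2 = i2,
         method = method, measure = measure, ci_level = ci_level),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "%s pooling of k = %d estimates%s\n  pooled %.*f (SE %.*f), %g%% CI [%.*f, %.*f]\n  Q = %.*f (df %d, p = %.4g), tau^2 = %.*f, I^2 = %.1f%%\n",
    x$method, x$k,
    if (is.na(x$measure)) "" else paste0(" (", x$measure, ")"),
    digits, x$theta_pooled, digits, x$se, 100 * x$ci_level,
    digits, x$ci_low, digits, x$ci_high,
    digits, x$Q, x$df, x$p_Q, digits, x$tau2, x$i2))
  invisible(x)
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Weights each estimate by the reciprocal of its sampling variance:
#' `theta_F = sum(w_i theta_i) / sum(w_i)` with `w_i = 1/v_i`, and computes
#' Cochran's heterogeneity statistic `Q = sum(w_i (theta_i - theta_F)^2)`.
#' For a single estimate `Q = 0`, `df = 0` and `p_Q = 1`.
#'
#' @param estimates a data frame with columns `theta` and `variance` (e.g.
#'   from [compute_effects()]), or a list of `"effect_estimate"` objects.
#'   All estimates must share one effect measure.
#' @param ci_level two-sided confidence level for the pooled CI.
#' @return an object of class `"meta_result"`.
#' @export
pool_fixed <- function(estimates, ci_level = 0.95) {
  e <- .theta_v(estimates)
  w <- 1 / e$v
  theta_f <- sum(w * e$theta) / sum(w)
  Q <- sum(w * (e$theta - theta_f)^2)
  new_meta_result(length(e$theta), theta_f, 1 / sqrt(sum(w)), Q, 0,
                  "fixed", e$measure, ci_level)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments estimate of the between-study variance:
#' `tau^2 = max(0, (Q - df) / C)` with `C = sum(w_i) - sum(w_i^2)/sum(w_i)`
#' and fixed-effect weights `w_i = 1/v_i`; estimates are then re-weighted by
#' `w*_i = 1/(v_i + tau^2)`. Heterogeneity is summarized by `I^2 =
#' max(0, (Q - df)/Q) * 100` and the chi-square upper-tail p-value of `Q`.
#' A single estimate passes through unchanged with `tau^2 = 0`, `I^2 = 0`.
#'
#' @inheritParams pool_fixed
#' @return an object of class `"meta_result"` with `method = "dl_random"`.
#' @examples
#' est <- data.frame(theta = c(0.1, 0.3), variance = c(0.01, 0.01))
#' pool_dl(est)  # pooled 0.2, tau^2 = 0.01, I^2 = 50%
#' @export
pool_dl <- function(estimates, ci_level = 0.95) {
  e <- .theta_v(estimates)
  k <- length(e$theta)
  w <- 1 / e$v
  theta_f <- sum(w * e$theta) / sum(w)
  Q <- sum(w * (e$theta - theta_f)^2)
  tau2 <- 0
  if (k > 1L) {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
  }
  ws <- 1 / (e$v + tau2)
  theta_r <- sum(ws * e$theta) / sum(ws)
  new_meta_result(k, theta_r, 1 / sqrt(sum(ws)), Q, tau2,
                  "dl_random", e$measure, ci_level)
}

#' Mantel-Haenszel pooled odds ratio
#'
#' Pools 2x2 tables with Mantel-Haenszel weights on the odds-ratio scale and
#' reports the result as a log odds ratio with the Robins-Breslow-Greenland
#' variance. The heterogeneity statistic Q is computed from the per-table
#' inverse-variance log odds ratios (continuity-corrected where a table has
#' a zero cell, see [log_odds_ratio()]) around the MH pooled estimate.
#'
#' @param records data frame in the dichotomous trial schema (columns
#'   `events_t, total_t, events_c, total_c`, one row per table).
#' @param ci_level two-sided confidence level.
#' @return an object of class `"meta_result"` with
#'   `method = "mantel_haenszel"` and `measure = "logOR"`.
#' @export
pool_mantel_haenszel <- function(records, ci_level = 0.95) {
  need <- c("events_t", "total_t", "events_c", "total_c")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("records must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!nrow(records)) stop("no tables to pool", call. = FALSE)
  a <- records$events_t; b <- records$total_t - records$events_t
  cc <- records$events_c; d <- records$total_c - records$events_c
  n <- records$total_t + records$total_c
  R <- a * d / n
  S <- b * cc / n
  if (sum(R) == 0 || sum(S) == 0) {
    stop("Mantel-Haenszel odds ratio undefined: zero margin across all ",
         "tables", call. = FALSE)
  }
  theta <- log(sum(R) / sum(S))
  # Robins-Breslow-Greenland variance of the MH log odds ratio
  P <- (a + d) / n
  Qf <- (b + cc) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
       sum(P * S + Qf * R) / (2 * sum(R) * sum(S)) +
       sum(Qf * S) / (2 * sum(S)^2)
  # heterogeneity from inverse-variance per-table log ORs
  k <- nrow(records)
  Q <- 0
  if (k > 1L) {
    tab <- records[need]
    tab$trial_id <- seq_len(k)
    iv <- compute_effects(tab, measure = "logOR", ci_level = ci_level)
    wi <- 1 / iv$variance
    Q <- sum(wi * (iv$theta - theta)^2)
  }
  new_meta_result(k, theta, sqrt(v), Q, NA_real_,
                  "mantel_haenszel", "logOR", ci_level)
}

#' Wald test for the difference between two pooled estimates
#'
#' Tests the null hypothesis that two (independent) pooled effect estimates
#' do not differ: `z = (theta_a - theta_b) / sqrt(se_a^2 + se_b^2)`, with a
#' two-sided normal p-value.
#'
#' @param a,b `"meta_result"` objects (or any lists with elements
#'   `theta_pooled` and `se`).
#' @param alpha significance level for the rejection flag (default 0.05).
#' @return An object of class `"wald_comparison"`: list with `theta_a`,
#'   `theta_b`, `se_a`, `se_b`, `z`, `p`, `alpha` and `reject_null`.
#' @export
wald_compare <- function(a, b, alpha = 0.05) {
  for (x in list(a, b)) {
    if (is.null(x$theta_pooled) || is.null(x$se) || x$se <= 0) {
      stop("wald_compare needs two pooled results with positive SE",
           call. = FALSE)
    }
  }
  z <- (a$theta_pooled - b$theta_pooled) / sqrt(a$se^2 + b$se^2)
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(theta_a = a$theta_pooled, theta_b = b$theta_pooled,
         se_a = a$se, se_b = b$se, z = z, p = p, alpha = alpha,
         reject_null = p < alpha),
    class = "wald_comparison"
  )
}

#' @export
print.wald_comparison <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Wald test: %.*f vs %.*f -> z = %.*f, p = %.4g (%s at alpha = %g)\n",
    digits, x$theta_a, digits, x$theta_b, digits, x$z, x$p,
    if (x$reject_null) "difference significant" else "no significant difference",
    x$alpha))
  invisible(x)
}
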