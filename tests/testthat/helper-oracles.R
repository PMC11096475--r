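# Independent brute-force oracles, kept deliberately naive so they cannot
# share a defect with the implementation.

# count of consecutive satisfied criteria from the first, stopping at the
# first failure
leading_ones_oracle <- function(scores) {
  n <- 0L
  for (s in scores) {
    if (s == 1) n <- n + 1L else break
  }
  n
}

# straight-line DerSimonian-Laird computation with explicit loops
dl_oracle <- function(theta, v) {
  k <- length(theta)
  w <- numeric(k); for (i in seq_len(k)) w[i] <- 1 / v[i]
  sw <- 0; swt <- 0
  for (i in seq_len(k)) { sw <- sw + w[i]; swt <- swt + w[i] * theta[i] }
  tf <- swt / sw
  Q <- 0; for (i in seq_len(k)) Q <- Q + w[i] * (theta[i] - tf)^2
  tau2 <- 0
  if (k > 1) {
    sw2 <- 0; for (i in seq_len(k)) sw2 <- sw2 + w[i]^2
    C <- sw - sw2 / sw
    tau2 <- max(0, (Q - (k - 1)) / C)
  }
  ws <- numeric(k); for (i in seq_len(k)) ws[i] <- 1 / (v[i] + tau2)
  ssw <- 0; sswt <- 0
  for (i in seq_len(k)) { ssw <- ssw + ws[i]; sswt <- sswt + ws[i] * theta[i] }
  list(theta = sswt / ssw, se = 1 / sqrt(ssw), Q = Q, tau2 = tau2,
       i2 = if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0)
}

# random estimate tables for property loops
random_estimates <- function(k) {
  data.frame(theta = stats::rnorm(k, 0, 1),
             variance = stats::runif(k, 0.005, 0.5))
}

# a small three-comparison corpus engineered so that the highest
# corroboration level with data is, per comparison, the given c_level
make_engineered_corpus <- function(c_levels = c(2, 3, 1),
                                   n_per_comparison = 6, seed = 42) {
  set.seed(seed)
  trials <- list(); appraisals <- list()
  scores_for_level <- function(lv) {
    s <- c(rep(1L, lv), rep(0L, 4 - lv))
    s[1:4]
  }
  for (ci in seq_along(c_levels)) {
    cmp <- paste0("cmp", ci)
    for (ti in seq_len(n_per_comparison)) {
      id <- sprintf("%s_t%d", cmp, ti)
      # one trial per comparison carries the target (maximal) level,
      # the rest sit at level min(target, 1)
      lv <- if (ti == 1) c_levels[ci] else min(c_levels[ci], 1L)
      s <- scores_for_level(lv)
      appraisals[[id]] <- data.frame(
        trial_id = id, cqs_c1 = s[1], cqs_c2 = s[2], cqs_c3 = s[3],
        cqs_c4 = s[4],
        rob2_overall = if (ti <= 2) "low" else "some concerns",
        stringsAsFactors = FALSE)
      n <- 40
      trials[[id]] <- data.frame(
        trial_id = id, comparison_id = cmp, outcome_id = "ldl_c",
        n_t = n, mean_t = rnorm(1, -0.2, 0.15), sd_t = runif(1, 0.8, 1.2),
        n_c = n, mean_c = rnorm(1, 0, 0.15), sd_c = runif(1, 0.8, 1.2),
        stringsAsFactors = FALSE)
    }
  }
  list(trials = do.call(rbind, c(trials, list(make.row.names = FALSE))),
       appraisals = do.call(rbind, c(appraisals,
                                     list(make.row.names = FALSE))))
}
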