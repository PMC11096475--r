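test_that("the same seed reproduces the corpus exactly", {
  cfg <- corpus_config(seed = 99)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$appraisals, b$appraisals)
  expect_identical(a$truth, b$truth)

  c <- generate_corpus(corpus_config(seed = 100))
  expect_false(identical(a$trials, c$trials))
})

test_that("CQS scores are a deterministic function of flags and per-arm n", {
  cfg <- corpus_config(n_trials = 60, rob2_noise = 0.5, seed = 5,
                       comparisons = "c1", comparison_sizes = 60,
                       n_per_arm = c(50, 150))
  corp <- generate_corpus(cfg)
  th <- corp$truth[match(corp$appraisals$trial_id, corp$truth$trial_id), ]
  expect_equal(corp$appraisals$cqs_c1, as.integer(th$randomized))
  expect_equal(corp$appraisals$cqs_c2, as.integer(th$concealed))
  expect_equal(corp$appraisals$cqs_c3, as.integer(th$blinded))
  expect_equal(corp$appraisals$cqs_c4, as.integer(th$n_per_arm >= 100))
  # rating noise touches only the RoB 2 column
  expect_gt(sum(corp$appraisals$rob2_overall != th$rob2_derived), 0)
})

test_that("the bias-free limit yields C4 trials, low RoB 2 and no bias term", {
  cfg <- corpus_config(n_trials = 30, true_smd = 0.3, tau2_gen = 0,
                       flag_prevalences = c(randomized = 1, concealed = 1,
                                            blinded = 1),
                       n_per_arm = 120, comparisons = "c1",
                       comparison_sizes = 30, seed = 21)
  corp <- generate_corpus(cfg)
  scored <- score_cqs_table(corp$appraisals)
  expect_true(all(scored$c_level == 4))
  expect_true(all(scored$overall == 1))
  expect_true(all(corp$appraisals$rob2_overall == "low"))
  expect_true(all(corp$truth$delta_applied == corp$truth$delta_base))
})

test_that("a zeroed bias model leaves every flag stratum estimating delta", {
  cfg <- corpus_config(n_trials = 600, true_smd = 0.4, tau2_gen = 0,
                       flag_prevalences = c(randomized = 0.5,
                                            concealed = 0.5, blinded = 0.5),
                       n_per_arm = c(50, 150), comparisons = "c1",
                       comparison_sizes = 600, seed = 31)
  zero <- bias_model(additive_smd_no_concealment = 0,
                     relative_pct_no_blinding = 0, relative_pct_small_n = 0)
  corp <- generate_corpus(cfg, zero)
  expect_true(all(corp$truth$delta_applied == corp$truth$delta_base))
  rec <- recover_bias(corp)
  conc <- rec[rec$mechanism == "concealment", ]
  expect_lt(abs(conc$estimate), 3 * conc$mc_se)
  smn <- rec[rec$mechanism == "small_n", ]
  expect_lt(abs(smn$estimate), 3 * smn$mc_se)
})

test_that("bias terms compose additively then multiplicatively in the stated order", {
  cfg <- corpus_config(n_trials = 8, true_smd = 0.2, tau2_gen = 0,
                       flag_prevalences = c(randomized = 1, concealed = 0,
                                            blinded = 0),
                       n_per_arm = 40, comparisons = "c1",
                       comparison_sizes = 8, seed = 41)
  bm <- bias_model()  # 0.15 additive, 11% blinding, 33% small n
  corp <- generate_corpus(cfg, bm)
  expected <- (0.2 + 0.15) * 1.11 * 1.33
  expect_equal(corp$truth$delta_applied, rep(expected, 8))
})

test_that("generated sample variances are unbiased for the population variance", {
  cfg <- corpus_config(n_trials = 10000, true_smd = 0, tau2_gen = 0,
                       n_per_arm = 30, control_sd = 2,
                       comparisons = "c1", comparison_sizes = 10000,
                       seed = 51)
  corp <- generate_corpus(cfg, bias_model(additive_smd_no_concealment = 0,
                                          relative_pct_no_blinding = 0,
                                          relative_pct_small_n = 0))
  # E[s^2] = sigma^2 = 4; MC SE of the mean of 10^4 scaled chi^2 draws
  # is sigma^2 * sqrt(2/(n-1)) / 100 ~ 0.0105
  expect_lt(abs(mean(corp$trials$sd_c^2) - 4), 4 * 0.011)
  expect_lt(abs(mean(corp$trials$sd_t^2) - 4), 4 * 0.011)
})

test_that("with no bias and no heterogeneity the pooled estimate recovers delta", {
  delta <- 0.25
  cfg <- corpus_config(n_trials = 400, true_smd = delta, tau2_gen = 0,
                       flag_prevalences = c(randomized = 1, concealed = 1,
                                            blinded = 1),
                       n_per_arm = 100, comparisons = "c1",
                       comparison_sizes = 400, seed = 61)
  corp <- generate_corpus(cfg, bias_model(additive_smd_no_concealment = 0,
                                          relative_pct_no_blinding = 0,
                                          relative_pct_small_n = 0))
  run <- run_pipeline(corp$trials, corp$appraisals,
                      run_config(min_trials_per_comparison = 1))
  pooled <- run$second_stage$cqs2b
  expect_lt(abs(pooled$theta_pooled - delta), 3 * pooled$se)
})

test_that("combining corpora keeps trial ids unique and stacks all tables", {
  a <- generate_corpus(corpus_config(n_trials = 10, comparisons = "c1",
                                     comparison_sizes = 10, seed = 71))
  b <- generate_corpus(corpus_config(n_trials = 12, comparisons = "c1",
                                     comparison_sizes = 12, seed = 72))
  ab <- combine_corpora(a, b)
  expect_equal(nrow(ab$truth), 22)
  expect_false(anyDuplicated(ab$truth$trial_id) > 0)
  expect_equal(nrow(ab$trials), nrow(a$trials) + nrow(b$trials))
})

test_that("recover_bias errors when a flag stratum is empty", {
  corp <- generate_corpus(corpus_config(
    n_trials = 20, flag_prevalences = c(randomized = 1, concealed = 1,
                                        blinded = 1),
    n_per_arm = 120, comparisons = "c1", comparison_sizes = 20, seed = 81))
  expect_error(recover_bias(corp, mechanisms = "concealment"), "empty")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(corpus_config(flag_prevalences = c(randomized = 1.5,
                                                  concealed = 0.5,
                                                  blinded = 0.5)),
               "flag_prevalences")
  expect_error(corpus_config(tau2_gen = -1))
  expect_error(corpus_config(comparison_sizes = c(1, 1)), "length")
  expect_error(bias_model(small_n_threshold = 0))
})
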