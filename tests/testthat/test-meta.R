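test_that("fixed-effect pooling matches hand computation and k=1 conventions", {
  one <- pool_fixed(data.frame(theta = 0.3, variance = 0.04))
  expect_equal(one$theta_pooled, 0.3)
  expect_equal(one$se, 0.2)
  expect_equal(one$Q, 0)
  expect_equal(one$df, 0L)
  expect_equal(one$p_Q, 1)
  expect_equal(one$i2, 0)

  two <- pool_fixed(data.frame(theta = c(0.1, 0.3), variance = c(0.01, 0.01)))
  expect_equal(two$theta_pooled, 0.2)
  expect_equal(two$Q, 2)

  same <- pool_fixed(data.frame(theta = rep(0.42, 5), variance = runif(5, .01, .1)))
  expect_equal(same$theta_pooled, 0.42)
  expect_equal(same$Q, 0)
})

test_that("DL pooling reproduces the hand-computed two-study example", {
  r <- pool_dl(data.frame(theta = c(0.1, 0.3), variance = c(0.01, 0.01)))
  expect_equal(r$Q, 2)
  expect_equal(r$tau2, 0.01)
  expect_equal(r$theta_pooled, 0.2)
  expect_equal(r$se, 0.1)
  expect_equal(r$i2, 50)
})

test_that("DL agrees with the brute-force oracle on random instances", {
  set.seed(404)
  for (i in 1:250) {
    est <- random_estimates(sample(1:10, 1))
    r <- pool_dl(est)
    o <- dl_oracle(est$theta, est$variance)
    expect_equal(r$theta_pooled, o$theta, tolerance = 1e-12)
    expect_equal(r$se, o$se, tolerance = 1e-12)
    expect_equal(r$tau2, o$tau2, tolerance = 1e-12)
    expect_equal(r$Q, o$Q, tolerance = 1e-12)
    expect_equal(r$i2, o$i2, tolerance = 1e-12)
  }
})

test_that("DL matches metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(505)
  for (i in 1:10) {
    est <- random_estimates(sample(3:12, 1))
    r <- pool_dl(est)
    m <- metafor::rma(yi = est$theta, vi = est$variance, method = "DL")
    expect_equal(r$theta_pooled, as.numeric(m$beta), tolerance = 1e-8)
    expect_equal(r$se, m$se, tolerance = 1e-8)
    expect_equal(r$tau2, m$tau2, tolerance = 1e-8)
    expect_equal(r$Q, m$QE, tolerance = 1e-8)
  }
})

test_that("homogeneous inputs truncate tau2 at zero and reduce DL to fixed", {
  est <- data.frame(theta = c(0.2, 0.201, 0.199),
                    variance = c(0.05, 0.05, 0.05))
  dl <- pool_dl(est); fe <- pool_fixed(est)
  expect_equal(dl$tau2, 0)
  expect_equal(dl$theta_pooled, fe$theta_pooled)
  expect_equal(dl$se, fe$se)
})

test_that("random-effects SE is never below fixed-effect SE", {
  set.seed(606)
  for (i in 1:50) {
    est <- random_estimates(sample(2:12, 1))
    expect_gte(pool_dl(est)$se, pool_fixed(est)$se - 1e-14)
  }
})

test_that("adding a constant shifts the pooled estimate and preserves heterogeneity", {
  set.seed(707)
  est <- random_estimates(8)
  shifted <- est; shifted$theta <- est$theta + 1.7
  a <- pool_dl(est); b <- pool_dl(shifted)
  expect_equal(b$theta_pooled, a$theta_pooled + 1.7)
  expect_equal(b$Q, a$Q)
  expect_equal(b$tau2, a$tau2)
  expect_equal(b$i2, a$i2)
})

test_that("pooling rejects empty input and mixed measures", {
  expect_error(pool_dl(data.frame(theta = numeric(0),
                                  variance = numeric(0))), "no estimates")
  mixed <- data.frame(theta = c(0.1, 0.2), variance = c(0.01, 0.01),
                      measure = c("MD", "SMD_hedges"))
  expect_error(pool_dl(mixed), "mixed measures")
  expect_error(pool_fixed(data.frame(theta = 1, variance = 0)), "positive")
})

test_that("DL recovers a known tau2 at large k", {
  set.seed(808)
  tau2_true <- 0.04
  est <- lapply(1:20, function(r) {
    v <- runif(200, 0.01, 0.05)
    # theta_i = 0.3 + N(0, tau2) + N(0, v_i)
    data.frame(theta = 0.3 + rnorm(200, 0, sqrt(tau2_true)) +
                 rnorm(200, 0, sqrt(v)),
               variance = v)
  })
  tau2_hat <- mean(vapply(est, function(e) pool_dl(e)$tau2, numeric(1)))
  expect_lt(abs(tau2_hat - tau2_true) / tau2_true, 0.2)
})

test_that("Mantel-Haenszel pooling matches single-table and symmetric oracles", {
  tab1 <- data.frame(events_t = 15, total_t = 20, events_c = 5, total_c = 20)
  r1 <- pool_mantel_haenszel(tab1)
  expect_equal(r1$theta_pooled, log(9))

  two <- rbind(tab1, tab1)
  r2 <- pool_mantel_haenszel(two)
  expect_equal(r2$theta_pooled, log(9))
  expect_equal(r2$Q, 0)

  opposite <- data.frame(events_t = c(15, 5), total_t = c(20, 20),
                         events_c = c(5, 15), total_c = c(20, 20))
  expect_equal(pool_mantel_haenszel(opposite)$theta_pooled, 0)

  allzero <- data.frame(events_t = 0, total_t = 20, events_c = 0,
                        total_c = 20)
  expect_error(pool_mantel_haenszel(allzero), "undefined")
})

test_that("Mantel-Haenszel estimate and RBG variance match metafor", {
  skip_if_not_installed("metafor")
  set.seed(909)
  for (i in 1:5) {
    k <- sample(3:8, 1)
    tabs <- data.frame(events_t = sample(3:17, k, TRUE), total_t = 20,
                       events_c = sample(3:17, k, TRUE), total_c = 20)
    r <- pool_mantel_haenszel(tabs)
    m <- metafor::rma.mh(ai = tabs$events_t,
                         bi = tabs$total_t - tabs$events_t,
                         ci = tabs$events_c,
                         di = tabs$total_c - tabs$events_c,
                         measure = "OR", add = 0, to = "none")
    expect_equal(r$theta_pooled, as.numeric(m$beta), tolerance = 1e-8)
    expect_equal(r$se, m$se, tolerance = 1e-8)
  }
})

test_that("Wald comparison matches the normal-tail oracle and is symmetric", {
  a <- pool_fixed(data.frame(theta = 0.2, variance = 0.01))
  w0 <- wald_compare(a, a)
  expect_equal(w0$z, 0)
  expect_equal(w0$p, 1)
  expect_false(w0$reject_null)

  b1 <- list(theta_pooled = 0.0, se = 0.1)
  b2 <- list(theta_pooled = 0.28, se = 0.1)
  w <- wald_compare(b1, b2)
  expect_equal(w$z, -0.28 / sqrt(0.02))
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))
  expect_lt(w$p, 0.05)
  expect_true(w$reject_null)

  wr <- wald_compare(b2, b1)
  expect_equal(wr$z, -w$z)
  expect_equal(wr$p, w$p)
})
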