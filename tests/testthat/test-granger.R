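test_that("F statistic matches the explicit two-OLS normal-equation oracle", {
  # the printed construction: x_t = 0.5 x_{t-1} + d_{t-1}, impulse at t = 10
  d <- numeric(30); d[10] <- 1
  x <- numeric(30)
  for (t in 2:30) x[t] <- 0.5 * x[t - 1] + d[t - 1]
  x <- x + sin(1:30 / 3) * 0.01          # break exact collinearity
  g <- granger_f_test(x, d, m = 2)
  orc <- oracle_granger_f(x, d, m = 2)
  expect_equal(g$f_stat, orc$f, tolerance = 1e-8)
  expect_equal(g$p_value, orc$p, tolerance = 1e-8)
  expect_equal(g$ssr_restricted, orc$ssr_r, tolerance = 1e-8)
  expect_equal(g$ssr_unrestricted, orc$ssr_ur, tolerance = 1e-8)

  # random instances, several lags, against the oracle and lmtest
  set.seed(31)
  for (i in 1:10) {
    n <- sample(40:80, 1)
    m <- sample(1:4, 1)
    d <- rbinom(n, 1, 0.2) * 25
    x <- as.numeric(stats::filter(0.1 * d + rnorm(n), 0.4,
                                  method = "recursive"))
    g <- granger_f_test(x, d, m = m)
    orc <- oracle_granger_f(x, d, m = m)
    expect_equal(g$f_stat, orc$f, tolerance = 1e-8)
    expect_gte(g$ssr_restricted, g$ssr_unrestricted)
    lm_ref <- lmtest::grangertest(x = d, y = x, order = m)
    expect_equal(g$f_stat, lm_ref$F[2], tolerance = 1e-6)
    expect_equal(g$p_value, lm_ref$`Pr(>F)`[2], tolerance = 1e-6)
  }
})

test_that("degenerate and invariance behaviour of the F test", {
  set.seed(32)
  x <- rnorm(50)
  g0 <- granger_f_test(x, rep(0, 50), m = 3)
  expect_equal(g0$f_stat, 0)
  expect_equal(g0$p_value, 1)

  d <- rbinom(50, 1, .3) * 25
  g1 <- granger_f_test(x, d, m = 3)
  g2 <- granger_f_test(1000 * x, d, m = 3)   # F is scale-free
  expect_equal(g1$f_stat, g2$f_stat, tolerance = 1e-9)

  expect_error(granger_f_test(x[1:6], d[1:6], m = 3), "short")
  # a constant duplicated regressor makes the design rank-deficient
  expect_error(granger_f_test(rep(c(1, 2), 25), rep(1, 50), m = 2,
                              intercept = TRUE), "rank")
})

test_that("component selection finds a planted signal and reports all candidates", {
  set.seed(33)
  n <- 256
  tmpl <- monitored_series(rnorm(n), dt = 1)
  sched <- generate_event_schedule(20, 12, 25, seed = 33, horizon = n - 1)
  d <- dose_mark_series(sched, tmpl)
  # plant a drug-driven component in a synthetic decomposition; the
  # response must act through lagged doses for Granger causality to exist
  dlag <- c(0, d$values[-n])
  planted <- as.numeric(stats::filter(0.8 * dlag, 0.6,
                                      method = "recursive")) + rnorm(n, sd = .2)
  W <- haar_modwt(monitored_series(rnorm(n)), J = 2)
  W$scale[[2]] <- planted
  sel <- select_target_variable(W, d, m = 3)
  expect_equal(sel$label, "s2")
  expect_equal(nrow(sel$table), 4)           # 2J candidates
  expect_true(all(c("p_value", "p_bonferroni") %in% names(sel$table)))
  expect_equal(sel$table$p_value[sel$table$label == "s2"],
               min(sel$table$p_value))

  # selection is a pure function of its inputs
  sel2 <- select_target_variable(W, d, m = 3)
  expect_identical(sel$table, sel2$table)

  # with no events nothing is significant, but something is still returned
  d0 <- dose_mark_series(event_schedule(), tmpl)
  expect_warning(sel0 <- select_target_variable(W, d0, m = 3), "alpha")
  expect_true(sel0$label %in% c("s1", "s2", "d1", "d2"))
})
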