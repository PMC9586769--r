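test_that("loss equals a term-by-term evaluation and is zero at the truth", {
  # tiny instance: 5 points, 1 event, both residual conventions
  x <- monitored_series(c(70, 72, 71, 74, 73), t0 = 0, dt = 1)
  sched <- event_schedule(1.5, 25)
  for (mode in c("level", "increment")) {
    hand <- 0
    tt <- series_times(x)
    y <- if (mode == "level") x$values else diff(x$values)
    te <- if (mode == "level") tt else tt[-1]
    for (i in seq_along(y)) {
      lam <- 70 + 5 * sin(te[i] + 2) +
        (if (te[i] > 1.5) oracle_kernel(te[i] - 1.5, 25, truth) else 0)
      hand <- hand + (y[i] - lam)^2
    }
    expect_equal(hawkes_loss(truth, x, sched, mode = mode), hand,
                 tolerance = 1e-10)
  }

  ms <- make_sim(seed = 1, n_steps = 300, normalized = FALSE)
  expect_equal(hawkes_loss(truth, ms$sim$clean, ms$sched), 0,
               tolerance = 1e-18)
  expect_gte(hawkes_loss(draw_params(), ms$sim$clean, ms$sched), 0)
})

test_that("R-squared and Pearson match direct-sum oracles on random vectors", {
  set.seed(41)
  for (i in 1:10) {
    y <- rnorm(10); yh <- y + rnorm(10, sd = .5)
    sst <- sum((y - mean(y))^2); sse <- sum((y - yh)^2)
    expect_equal(r_squared(y, yh), (sst - sse) / sst, tolerance = 1e-12)
    r_hand <- sum((y - mean(y)) * (yh - mean(yh))) /
      sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
    pc <- pearson_corr(y, yh)
    expect_equal(pc$corr, r_hand, tolerance = 1e-12)
    tstat <- r_hand * sqrt(8 / (1 - r_hand^2))
    expect_equal(pc$p_value, 2 * pt(-abs(tstat), 8), tolerance = 1e-10)
  }
  y <- rnorm(10)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 10)), 0)
  expect_equal(pearson_corr(y, y)$corr, 1)
  expect_equal(pearson_corr(y, 3 + 2 * y)$corr, 1)   # affine invariance
  expect_error(r_squared(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "constant")
})

test_that("fit started at the truth stays there on noiseless data", {
  ms <- make_sim(seed = 2, n_steps = 400, normalized = TRUE)
  fit <- hawkes_fit(ms$sim$clean, ms$sched, normalized = TRUE, n_starts = 1,
                    start = unclass(truth), seed = 2)
  expect_lt(fit$sse, 1e-8)
  expect_gt(fit$r_squared, 1 - 1e-9)
  expect_equal(unclass(coef(fit)), unclass(truth), tolerance = 1e-3)
})

test_that("curve recovery from data-blind starts reaches R^2 >= 0.999", {
  for (sd in c(101, 202)) {
    ms <- make_sim(seed = sd, normalized = (sd == 101))
    fit <- hawkes_fit(ms$sim$noisy, ms$sched, normalized = (sd == 101),
                      n_starts = 3, seed = sd, max_iter = 200)
    expect_gt(fit$r_squared, 0.999)
  }
})

test_that("fit is deterministic and more starts never worsen the best loss", {
  ms <- make_sim(seed = 7, n_steps = 300, noise_variance = 2)
  f1 <- hawkes_fit(ms$sim$noisy, ms$sched, normalized = TRUE, n_starts = 2,
                   seed = 7, max_iter = 60)
  f2 <- hawkes_fit(ms$sim$noisy, ms$sched, normalized = TRUE, n_starts = 2,
                   seed = 7, max_iter = 60)
  expect_identical(unclass(coef(f1)), unclass(coef(f2)))
  expect_identical(f1$r_squared, f2$r_squared)
  f3 <- hawkes_fit(ms$sim$noisy, ms$sched, normalized = TRUE, n_starts = 4,
                   seed = 7, max_iter = 60)
  expect_lte(f3$sse, f1$sse + 1e-9)
  expect_equal(f1$n_starts_used, 2)
  expect_true(f1$best_start_index %in% 1:2)
})

test_that("fit object supports the standard modelling verbs", {
  ms <- make_sim(seed = 9, n_steps = 250, noise_variance = 1)
  fit <- hawkes_fit(ms$sim$noisy, ms$sched, normalized = TRUE, n_starts = 1,
                    seed = 9, max_iter = 80)
  expect_s3_class(coef(fit), "hawkes_params")
  expect_equal(deviance(fit), fit$sse)
  expect_equal(length(fitted(fit)), 250)
  expect_equal(fitted(fit) + residuals(fit), fit$target)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  pr <- predict(fit, times = c(10.5, 20.5))
  expect_equal(length(pr), 2)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(length(sims), 2)
  expect_equal(length(sims[[1]]$values), 250)
  expect_output(print(fit), "R-squared")
  expect_output(summary(fit), "Optimizer")
  # r_squared consistency invariant: (sst - sse)/sst
  expect_equal(fit$r_squared, (fit$sst - fit$sse) / fit$sst)
  expect_error(hawkes_fit(ms$sim$noisy, ms$sched,
                          bounds = reference_bounds()[, 2:1]), "bound")
})
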