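test_that("baseline is the printed sinusoid, periodic, strict about positivity", {
  p <- truth
  expect_equal(baseline_mu(0, p), 74.54648713412841)   # 70 + 5 sin(2)
  # amplitude zero -> constant a0
  p0 <- as_hawkes_params(c(70, 0, 1, 2, 1, 1, .3, -20, 3, 5, .4))
  expect_equal(baseline_mu(c(0, 17, 123.5), p0), rep(70, 3))
  # periodicity in 2*pi/alpha0
  tt <- c(0, 1.3, 7.77)
  expect_equal(baseline_mu(tt, p), baseline_mu(tt + 2 * pi / 1, p))
  expect_error(baseline_mu(Inf, p), "finite")
  neg <- as_hawkes_params(c(1, 10, 1, 2, 1, 1, .3, -20, 3, 5, .4))
  expect_warning(baseline_mu(seq(0, 10, .5), neg), "positive")
  expect_error(baseline_mu(seq(0, 10, .5), neg, strict = TRUE), "positive")
})

test_that("excitation kernel matches its printed formula and limit behaviour", {
  # frozen direct evaluation at lag 2, dose 25, canonical truth
  expect_equal(excitation_kernel(2, 25, truth), 28.93178467227876)
  expect_equal(excitation_kernel(0, 25, truth), 0)       # kappa2 > 1
  expect_lt(excitation_kernel(1e4, 25, truth), 1e-300)   # decay dominates
  expect_error(excitation_kernel(-1, 25, truth), "causal")

  # oracle equivalence and non-negativity across random draws from the box
  set.seed(11)
  for (i in 1:25) {
    th <- draw_params()
    lag <- runif(7, 0, 60); dose <- runif(1, 0.5, 50)
    expect_equal(excitation_kernel(lag, dose, th),
                 oracle_kernel(lag, dose, th), tolerance = 1e-12)
    expect_true(all(excitation_kernel(lag, dose, th) >= 0))
    expect_equal(excitation_kernel(lag, dose, th, normalized = TRUE),
                 oracle_kernel(lag, dose, th, normalized = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("unit-mass variant integrates to the sigmoid; sigmoid is monotone in dose", {
  th <- truth
  lag <- seq(0, 400, by = 0.01)
  mass <- sum(excitation_kernel(lag, 25, th, normalized = TRUE)) * 0.01
  sig <- 1 / (1 + exp(-0.3 * 5 * 3))
  expect_equal(mass, sig, tolerance = 1e-4)
  # dose response: non-decreasing, bounded in (0, 1/a1]
  set.seed(3)
  for (i in 1:10) {
    th <- draw_params()
    doses <- sort(runif(20, 0.1, 80))
    v <- excitation_kernel(5, doses, th)
    if (unclass(th)["kappa1"] * unclass(th)["a2"] > 0)
      expect_true(all(diff(v) >= -1e-12))
    expect_true(all(v <= excitation_kernel(5, 1e9, th) + 1e-12))
  }
})

test_that("intensity is causal, additive over events, and matches the brute-force sum", {
  tt <- seq(0, 120, by = 1)
  empty <- event_schedule()
  expect_equal(intensity(tt, empty, truth), baseline_mu(tt, truth))

  s1 <- event_schedule(10, 25)
  s2 <- event_schedule(40, 30)
  s12 <- event_schedule(c(10, 40), c(25, 30))
  base <- baseline_mu(tt, truth)
  expect_equal(intensity(tt, s12, truth) - base,
               (intensity(tt, s1, truth) - base) +
                 (intensity(tt, s2, truth) - base))

  # events at or after t contribute nothing
  expect_equal(intensity(50, event_schedule(c(10, 50, 60), 25), truth),
               intensity(50, event_schedule(10, 25), truth))

  set.seed(21)
  sched <- generate_event_schedule(15, 8, 25, seed = 21)
  th <- draw_params()
  expect_equal(suppressWarnings(intensity(tt, sched, th)),
               suppressWarnings(oracle_intensity(tt, sched, th)),
               tolerance = 1e-10)
})

test_that("worked-example parameter vector reproduces its printed intensity", {
  th_hat <- as_hawkes_params(c(75, 1.21, 0.13, 1.39, 0.30, 2.08, 0.80,
                               -0.47, 0.0022, 2.77, 0.12))
  one <- event_schedule(0, 25)
  # frozen independent evaluation of the printed expression at t = 10
  expect_equal(intensity(10, one, th_hat), 1757.214220933103)
})

test_that("cumulative effect curve decomposes into unimodal per-event components", {
  grid <- seq(0, 200, by = 0.5)
  sched <- event_schedule(c(20, 60, 90), 25)
  ec <- cumulative_effect_curve(grid, sched, truth)
  expect_equal(ec$total, rowSums(ec$components))
  expect_equal(cumulative_effect_curve(grid, event_schedule(), truth)$total,
               rep(0, length(grid)))
  # single-event component rises then decays; dense-grid argmax at (k2-1)/b2
  comp <- ec$components[, 1]
  peak_lag <- grid[which.max(comp)] - 20
  expect_equal(peak_lag, (5 - 1) / 0.4, tolerance = 0.5 / 10)
  rising <- comp[grid > 20 & grid <= 20 + peak_lag]
  falling <- comp[grid >= 20 + peak_lag]
  expect_true(all(diff(rising) >= 0))
  expect_true(all(diff(falling) <= 0))
  expect_error(cumulative_effect_curve(c(0, 1, 3), sched, truth), "uniform")
})

test_that("parameter vectors validate, keep canonical order, and round-trip JSON", {
  expect_error(hawkes_params(70, 5, 0, 2, 1, 1, .3, -20, 3, 5, .4), "alpha0")
  expect_error(hawkes_params(70, 5, 1, 2, 0, 1, .3, -20, 3, 5, .4), "a1")
  expect_error(hawkes_params(70, 5, 1, 2, 1, 1, .3, -20, 3, 1, .4), "kappa2")
  expect_error(hawkes_params(70, 5, 1, 2, 1, 1, .3, -20, 3, 5, 0), "b2")
  expect_equal(names(truth),
               c("a0", "b0", "alpha0", "beta0", "a1", "b1", "kappa1", "m1",
                 "a2", "kappa2", "b2"))
  f <- withr::local_tempfile(fileext = ".json")
  params_to_json(truth, f)
  expect_equal(params_from_json(f), truth)
  # named JSON survives field reordering
  js <- '{"b2":0.4,"a0":70,"b0":5,"alpha0":1,"beta0":2,"a1":1,"b1":1,
          "kappa1":0.3,"m1":-20,"a2":3,"kappa2":5}'
  expect_equal(params_from_json(js), truth)
})
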