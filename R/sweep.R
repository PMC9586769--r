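#' Single- or two-parameter R-squared sweep
#'
#' Simulates a series from a "true" parameter vector, then substitutes one
#' parameter (or a pair) with each value of a grid — all other parameters
#' held at truth by default — and records the \eqn{R^2} between the
#' perturbed model curve and the simulated data.  With a noiseless
#' simulation the truth scores exactly 1, so the curve isolates how sharply
#' the data constrain that parameter; flat curves are the signature of weak
#' identifiability.  `refit = TRUE` instead re-estimates the remaining
#' parameters at every grid point (much slower).
#'
#' The sweep, like the package's other simulation-study helpers, defaults to
#' unit-mass excitation kernels (see the methods vignette).
#'
#' @param name parameter name, or a character vector of two names for a
#'   joint sweep.
#' @param grid numeric vector of values, or (joint sweep) a list of two
#'   vectors crossed into a grid.
#' @param truth true [hawkes_params()] (default [reference_params()]).
#' @param schedule administration schedule; default ~60 dose-25 events with
#'   exponential gaps.
#' @param n_steps,dt simulation grid (default 800 one-minute samples).
#' @param noise_variance simulation noise (default 0: noiseless).
#' @param seed integer seed (schedule and noise).
#' @param mode residual convention, `"level"` or `"increment"`.
#' @param normalized unit-mass kernels (default TRUE).
#' @param refit re-estimate the other parameters at each grid value.
#' @param fit_args list of arguments passed to [hawkes_fit()] when
#'   refitting.
#' @return A data.frame with the swept value(s) and `r_squared`, of class
#'   `"hawkes_sweep"`; `attr(, "argmax")` holds the grid row with maximal
#'   \eqn{R^2}.
#' @examples
#' \donttest{
#' sw <- parameter_sweep("kappa1", seq(0.05, 1, by = 0.05), n_steps = 300)
#' attr(sw, "argmax")
#' }
#' @export
parameter_sweep <- function(name, grid, truth = reference_params(),
                            schedule = NULL, n_steps = 800, dt = 1,
                            noise_variance = 0, seed = 1,
                            mode = c("level", "increment"),
                            normalized = TRUE, refit = FALSE,
                            fit_args = list()) {
  mode <- match.arg(mode)
  truth <- as_hawkes_params(truth)
  if (!all(name %in% param_names()))
    stop("unknown parameter name(s): ",
         paste(setdiff(name, param_names()), collapse = ", "), call. = FALSE)
  if (length(name) > 2) stop("sweep at most two parameters", call. = FALSE)
  if (is.null(schedule))
    schedule <- generate_event_schedule(60, mean_gap = 13, dose = 25,
                                        seed = seed, horizon = (n_steps - 1) * dt)
  sim <- simulate_series(truth, schedule, n_steps = n_steps, dt = dt,
                         noise_variance = noise_variance, seed = seed,
                         mode = mode, normalized = normalized)
  x <- sim$noisy
  md <- loss_data(x, schedule, mode)
  sst <- sum((md$y - mean(md$y))^2)

  gtab <- if (length(name) == 2) {
    stopifnot(is.list(grid), length(grid) == 2)
    g <- expand.grid(grid[[1]], grid[[2]])
    names(g) <- name
    g
  } else {
    stats::setNames(data.frame(as.numeric(grid)), name)
  }

  r2 <- vapply(seq_len(nrow(gtab)), function(i) {
    th <- unclass(truth)
    th[name] <- as.numeric(gtab[i, ])
    if (refit) {
      b <- reference_bounds()
      # pin the swept parameter(s) with a negligible band
      b[name, 1] <- th[name] - 1e-9
      b[name, 2] <- th[name] + 1e-9
      fa <- utils::modifyList(list(x = x, events = schedule, mode = mode,
                                   normalized = normalized, bounds = b),
                              fit_args)
      fit <- tryCatch(do.call(hawkes_fit, fa), error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      return(fit$r_squared)
    }
    1 - loss_value(th, md, normalized) / sst
  }, 0)

  out <- cbind(gtab, r_squared = r2)
  attr(out, "argmax") <- out[which.max(out$r_squared), , drop = FALSE]
  class(out) <- c("hawkes_sweep", "data.frame")
  out
}

#' @export
plot.hawkes_sweep <- function(x, ...) {
  nm <- setdiff(names(x), "r_squared")
  if (length(nm) == 1) {
    graphics::plot(x[[nm]], x$r_squared, type = "l", xlab = nm,
                   ylab = expression(R^2), ...)
  } else {
    v1 <- sort(unique(x[[nm[1]]])); v2 <- sort(unique(x[[nm[2]]]))
    z <- matrix(x$r_squared[order(x[[nm[2]]], x[[nm[1]]])],
                length(v1), length(v2))
    graphics::filled.contour(v1, v2, z, xlab = nm[1], ylab = nm[2], ...)
  }
  invisible(x)
}

#' Best attainable R-squared under increasing noise
#'
#' For each Gaussian noise variance, simulates fresh replicate series from
#' the truth (fresh sub-seeds per replicate), fits the full 11-parameter
#' model to each, and records the best \eqn{R^2} across replicates — the
#' "best possible" fit quality at that noise level.  The resulting curve is
#' non-increasing in the noise variance up to Monte-Carlo wiggle.
#'
#' @param levels numeric vector of noise variances (>= 0).
#' @param truth true [hawkes_params()].
#' @param schedule administration schedule; default ~60 dose-25 events.
#' @param n_steps,dt simulation grid (default 800 one-minute samples).
#' @param replicates replicate simulations/fits per level (default 20).
#' @param seed master seed; all replicate sub-seeds derive from it.
#' @param mode,normalized as in [parameter_sweep()].
#' @param fit_args arguments passed on to [hawkes_fit()]; the default uses
#'   3 starts and a 100-iteration cap per replicate (see the vignette on
#'   problem sizes).
#' @return A data.frame of class `"hawkes_noise_curve"` with columns
#'   `level`, `best_r2`, `mean_r2`.
#' @export
noise_robustness <- function(levels, truth = reference_params(),
                             schedule = NULL, n_steps = 800, dt = 1,
                             replicates = 20, seed = 1,
                             mode = c("level", "increment"),
                             normalized = TRUE,
                             fit_args = list(n_starts = 3, max_iter = 100)) {
  mode <- match.arg(mode)
  stopifnot(all(levels >= 0), replicates >= 1)
  truth <- as_hawkes_params(truth)
  if (is.null(schedule))
    schedule <- generate_event_schedule(60, mean_gap = 13, dose = 25,
                                        seed = seed, horizon = (n_steps - 1) * dt)
  subseeds <- with_seed(seed,
                        matrix(sample.int(2^31 - 2, length(levels) * replicates),
                               nrow = length(levels)))
  res <- lapply(seq_along(levels), function(li) {
    r2 <- vapply(seq_len(replicates), function(r) {
      s <- subseeds[li, r]
      sim <- simulate_series(truth, schedule, n_steps = n_steps, dt = dt,
                             noise_variance = levels[li], seed = s,
                             mode = mode, normalized = normalized)
      fa <- utils::modifyList(list(x = sim$noisy, events = schedule,
                                   mode = mode, normalized = normalized,
                                   seed = s),
                              fit_args)
      fit <- tryCatch(do.call(hawkes_fit, fa), error = function(e) NULL)
      if (is.null(fit)) NA_real_ else fit$r_squared
    }, 0)
    data.frame(level = levels[li], best_r2 = max(r2, na.rm = TRUE),
               mean_r2 = mean(r2, na.rm = TRUE))
  })
  out <- do.call(rbind, res)
  class(out) <- c("hawkes_noise_curve", "data.frame")
  out
}

#' @export
plot.hawkes_noise_curve <- function(x, ...) {
  graphics::plot(x$level, x$best_r2, type = "b", xlab = "noise variance",
                 ylab = expression("best " * R^2), ylim = range(0, 1, x$best_r2),
                 ...)
  invisible(x)
}
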