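#' @export
print.hawkes_fit <- function(x, digits = 4, ...) {
  cat("Drug-effect model fit (", x$mode, " mode",
      if (x$normalized) ", unit-mass kernel", ")\n", sep = "")
  cat("  series: n =", length(x$target), " events =", nrow(x$events), "\n")
  cat("  R-squared =", format(x$r_squared, digits = digits),
      "  Pearson corr =", format(x$pearson$corr, digits = digits),
      "(p =", format(x$pearson$p_value, digits = 3), ")\n")
  cat("  coefficients:\n")
  print(round(unclass(x$coefficients), digits))
  invisible(x)
}

#' Summary of a fitted drug-effect model
#'
#' @param object a [hawkes_fit()] result.
#' @param ... unused.
#' @return The object, invisibly, after printing coefficients (with bound
#'   activity flags), sums of squares, \eqn{R^2}, the Pearson correlation
#'   with its p-value, \eqn{\sqrt{\max(R^2,0)}}, and optimizer diagnostics.
#' @export
summary.hawkes_fit <- function(object, ...) {
  x <- object
  th <- unclass(x$coefficients)
  at_bound <- ifelse(abs(th - x$bounds[, 1]) < 1e-8, "at lower",
                     ifelse(abs(th - x$bounds[, 2]) < 1e-8, "at upper", ""))
  cat("Drug-effect model fit —", x$mode, "mode\n\n")
  print(data.frame(estimate = round(th, 5), lower = x$bounds[, 1],
                   upper = x$bounds[, 2], note = at_bound))
  cat("\nSSE =", format(x$sse, digits = 6),
      "  SST =", format(x$sst, digits = 6),
      "  R-squared =", format(x$r_squared, digits = 6), "\n")
  cat("Pearson corr =", format(x$pearson$corr, digits = 4),
      " (p =", format(x$pearson$p_value, digits = 4), ");",
      " sqrt(max(R^2, 0)) =", format(x$corr_from_r2, digits = 4), "\n")
  cat("Optimizer: best of", x$n_starts_used, "starts (start",
      x$best_start_index, "won);",
      if (x$converged) "converged" else "iteration cap reached", "\n")
  invisible(x)
}

#' @export
coef.hawkes_fit <- function(object, ...) object$coefficients

#' @export
deviance.hawkes_fit <- function(object, ...) object$sse

#' @export
fitted.hawkes_fit <- function(object, ...) object$fitted_values

#' @export
residuals.hawkes_fit <- function(object, ...) {
  object$target - object$fitted_values
}

#' Predict the model intensity at new times or for a new schedule
#'
#' @param object a [hawkes_fit()] result.
#' @param times evaluation times (default: the fitted grid).
#' @param events administration schedule (default: the fitted one).
#' @param ... unused.
#' @return Numeric vector of intensities under the fitted parameters.
#' @export
predict.hawkes_fit <- function(object, times = NULL, events = NULL, ...) {
  if (is.null(times)) {
    times <- series_times(object$x)
    if (object$mode == "increment") times <- times[-1]
  }
  if (is.null(events)) events <- object$events
  intensity(times, events, object$coefficients,
            normalized = object$normalized)
}

#' @export
plot.hawkes_fit <- function(x, show_events = TRUE, ...) {
  tt <- series_times(x$x)
  if (x$mode == "increment") tt <- tt[-1]
  graphics::plot(tt, x$target, type = "l", col = "grey40",
                 xlab = "time (min)",
                 ylab = if (x$mode == "level") "monitored variable"
                        else "increment", ...)
  graphics::lines(tt, x$fitted_values, col = "red3", lwd = 2)
  if (show_events && nrow(x$events))
    graphics::abline(v = x$events$time, col = "steelblue", lty = 3)
  graphics::legend("topright", legend = c("observed", "fitted"),
                   col = c("grey40", "red3"), lwd = c(1, 2), bty = "n")
  invisible(x)
}

#' Simulate new series from a fitted model
#'
#' Draws `nsim` noisy series from the fitted parameters on the fitted grid
#' and schedule; the noise variance defaults to the residual variance of the
#' fit (a parametric-bootstrap style resample).
#'
#' @param object a [hawkes_fit()] result.
#' @param nsim number of series.
#' @param seed integer seed.
#' @param noise_variance noise variance; default the fit's residual
#'   variance.
#' @param ... unused.
#' @return A list of `nsim` [monitored_series()].
#' @export
simulate.hawkes_fit <- function(object, nsim = 1, seed = 1,
                                noise_variance = NULL, ...) {
  if (is.null(noise_variance))
    noise_variance <- object$sse / length(object$target)
  lapply(seq_len(nsim), function(i) {
    simulate_series(object$coefficients, object$events,
                    n_steps = length(object$x$values), dt = object$x$dt,
                    t0 = object$x$t0, noise_variance = noise_variance,
                    seed = seed + i - 1L, mode = object$mode,
                    normalized = object$normalized)$noisy
  })
}
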