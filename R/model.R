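#' Sinusoidal baseline of the monitored variable
#'
#' Evaluates \eqn{\mu_t = a_0 + b_0 \sin(\alpha_0 t + \beta_0)}, the periodic
#' base level around which the self-exciting drug term operates.  The model
#' requires a strictly positive base level; because some admissible parameter
#' boxes allow violations, positivity is checked lazily at evaluation:
#' `strict = TRUE` raises an error, the default warns once.
#'
#' @param t time(s) in minutes; any finite numeric vector.
#' @param params a [hawkes_params()] vector (only the baseline entries are
#'   used).
#' @param strict raise an error (instead of a warning) when the evaluated
#'   baseline is not strictly positive.
#' @return Numeric vector of baseline values.
#' @examples
#' baseline_mu(0:5, reference_params())
#' @export
baseline_mu <- function(t, params, strict = FALSE) {
  if (any(!is.finite(t))) stop("'t' must be finite", call. = FALSE)
  th <- as_hawkes_params(params)
  mu <- th[["a0"]] + th[["b0"]] * sin(th[["alpha0"]] * t + th[["beta0"]])
  if (any(mu <= 0)) {
    msg <- "baseline mu(t) is not strictly positive for some t"
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  mu
}

#' Dose-dependent excitation kernel
#'
#' The contribution of one administration of dose \eqn{d} at lag
#' \eqn{u = t - t_i \ge 0}:
#' \deqn{\gamma(u, d) = \frac{1}{a_1 + b_1 e^{-\kappa_1 (m_1 + d) a_2}}
#'   \cdot \frac{u^{\kappa_2 - 1} e^{-b_2 u}}{b_2^{\kappa_2}
#'   \Gamma(\kappa_2)}.}
#' The first factor is a dose sigmoid, bounded in \eqn{(0, 1/a_1]} and
#' non-decreasing in the dose whenever \eqn{\kappa_1 a_2 > 0}; the second is
#' a Gamma-shaped lag profile that is zero at lag 0 (for \eqn{\kappa_2 > 1}),
#' rises to a single mode at \eqn{(\kappa_2 - 1)/b_2} minutes and then decays.
#'
#' Note the lag factor above divides by \eqn{b_2^{\kappa_2}\Gamma(\kappa_2)}
#' while decaying as \eqn{e^{-b_2 u}}: it is not a normalized density in
#' either the rate or the scale parameterization, and its total mass is
#' \eqn{b_2^{-2\kappa_2}} per unit sigmoid.  `normalized = TRUE` substitutes
#' the proper rate-parameterized Gamma density
#' \eqn{b_2^{\kappa_2} u^{\kappa_2-1} e^{-b_2 u}/\Gamma(\kappa_2)}, giving
#' unit-mass kernels; the package's simulation-study helpers use that form
#' (see the methods vignette for the scale analysis behind this choice).
#' Log-gamma arithmetic is used internally so large shapes (\eqn{\kappa_2}
#' near 22) do not overflow.
#'
#' @param lag lag(s) since administration, minutes, >= 0.
#' @param dose dose(s), recycled against `lag`.
#' @param params a [hawkes_params()] vector (only kernel entries are used).
#' @param normalized use the unit-mass rate-parameterized Gamma lag profile
#'   instead of the default unnormalized form.
#' @return Numeric vector of kernel values (always >= 0).
#' @examples
#' excitation_kernel(0:30, dose = 25, params = reference_params())
#' @export
excitation_kernel <- function(lag, dose, params, normalized = FALSE) {
  if (any(lag < 0)) stop("'lag' must be >= 0 (the kernel is causal)",
                         call. = FALSE)
  th <- as_hawkes_params(params)
  sig <- dose_sigmoid(dose, th)
  sig * gamma_lag_profile(lag, th, normalized)
}

dose_sigmoid <- function(dose, th) {
  1 / (th[["a1"]] + th[["b1"]] *
         exp(-th[["kappa1"]] * (th[["m1"]] + dose) * th[["a2"]]))
}

# log normalizing constant of the lag profile
gamma_log_norm <- function(th, normalized) {
  k2 <- th[["kappa2"]]; b2 <- th[["b2"]]
  if (normalized) lgamma(k2) - k2 * log(b2) else lgamma(k2) + k2 * log(b2)
}

gamma_lag_profile <- function(lag, th, normalized = FALSE) {
  k2 <- th[["kappa2"]]; b2 <- th[["b2"]]
  out <- numeric(length(lag))
  pos <- lag > 0
  out[pos] <- exp((k2 - 1) * log(lag[pos]) - b2 * lag[pos] -
                    gamma_log_norm(th, normalized))
  out
}

#' Conditional intensity of the drug-effect model
#'
#' \eqn{\lambda_t = \mu_t + \sum_{t_i < t} \gamma(t - t_i, d_i)}: the
#' baseline plus the summed excitation of all strictly earlier
#' administrations.  Events at or after `t` contribute nothing (causality);
#' with an empty schedule the intensity equals the baseline exactly.
#'
#' @param t evaluation time(s), minutes.
#' @param schedule an [event_schedule()].
#' @param params a [hawkes_params()] vector.
#' @inheritParams excitation_kernel
#' @inheritParams baseline_mu
#' @return Numeric vector of intensity values.
#' @examples
#' sched <- event_schedule(c(10, 30), 25)
#' intensity(0:60, sched, reference_params())
#' @export
intensity <- function(t, schedule, params, normalized = FALSE,
                      strict = FALSE) {
  th <- as_hawkes_params(params)
  schedule <- as_event_schedule(schedule)
  mu <- baseline_mu(t, th, strict = strict)
  mu + excitation_sum(t, schedule, th, normalized)
}

excitation_sum <- function(t, schedule, th, normalized = FALSE) {
  if (!nrow(schedule)) return(numeric(length(t)))
  sig <- dose_sigmoid(schedule$dose, th)
  lag <- outer(t, schedule$time, "-")     # n x e
  k2 <- th[["kappa2"]]; b2 <- th[["b2"]]
  g <- matrix(0, nrow(lag), ncol(lag))
  pos <- lag > 0
  g[pos] <- exp((k2 - 1) * log(lag[pos]) - b2 * lag[pos] -
                  gamma_log_norm(th, normalized))
  as.numeric(g %*% sig)
}

#' Cumulative drug-effect curve and its per-event components
#'
#' Evaluates, on a uniform time grid, the summed excitation
#' \eqn{\sum_{t_i < t} \gamma(t - t_i, d_i)} (the intensity minus its
#' baseline) together with the individual contribution curve of every
#' administration.
#'
#' @param grid numeric vector of uniformly spaced times, or a
#'   [monitored_series()] whose grid is used.
#' @inheritParams intensity
#' @return A list of class `"effect_curve"` with elements `grid`, `total`
#'   (numeric vector) and `components` (matrix, one column per event).
#' @examples
#' ec <- cumulative_effect_curve(0:120, event_schedule(c(10, 40, 70), 25),
#'                               reference_params())
#' stopifnot(all.equal(ec$total, rowSums(ec$components)))
#' @export
cumulative_effect_curve <- function(grid, schedule, params,
                                    normalized = FALSE) {
  if (inherits(grid, "monitored_series")) grid <- series_times(grid)
  if (length(grid) > 1) {
    d <- diff(grid)
    if (max(d) - min(d) > 1e-8 * max(abs(d)))
      stop("'grid' must be uniformly spaced", call. = FALSE)
  }
  th <- as_hawkes_params(params)
  schedule <- as_event_schedule(schedule)
  if (!nrow(schedule)) {
    comp <- matrix(0, length(grid), 0)
  } else {
    sig <- dose_sigmoid(schedule$dose, th)
    lag <- outer(grid, schedule$time, "-")
    comp <- matrix(0, nrow(lag), ncol(lag))
    pos <- lag > 0
    comp[pos] <- exp((th[["kappa2"]] - 1) * log(lag[pos]) -
                       th[["b2"]] * lag[pos] -
                       gamma_log_norm(th, normalized))
    comp <- sweep(comp, 2, sig, "*")
  }
  structure(list(grid = grid, total = rowSums(comp), components = comp),
            class = "effect_curve")
}

#' @export
print.effect_curve <- function(x, ...) {
  cat("Cumulative drug-effect curve:", length(x$grid), "grid points,",
      ncol(x$components), "events; peak", format(max(x$total), digits = 5),
      "\n")
  invisible(x)
}

#' @export
plot.effect_curve <- function(x, ...) {
  graphics::matplot(x$grid, x$components, type = "l", lty = 2, col = "grey50",
                    xlab = "time (min)", ylab = "drug effect", ...)
  graphics::lines(x$grid, x$total, lwd = 2)
  invisible(x)
}

# --- fast path used by the fitting / simulation engine --------------------
#
# Precomputes the lag matrix (and its log) of a grid/schedule pair once; the
# objective then costs a single large exp() per evaluation.

make_model_data <- function(times, schedule) {
  schedule <- as_event_schedule(schedule)
  if (!nrow(schedule)) {
    return(list(times = times, e = 0L, doses = numeric()))
  }
  lag <- outer(times, schedule$time, "-")
  pos <- lag > 0
  loglag <- matrix(-Inf, nrow(lag), ncol(lag))
  loglag[pos] <- log(lag[pos])
  list(times = times, e = nrow(schedule), doses = schedule$dose,
       lag = lag, loglag = loglag, pos = pos)
}

eval_intensity <- function(md, th, normalized = FALSE) {
  mu <- th[["a0"]] + th[["b0"]] * sin(th[["alpha0"]] * md$times + th[["beta0"]])
  if (md$e == 0L) return(mu)
  sig <- dose_sigmoid(md$doses, th)
  lg <- (th[["kappa2"]] - 1) * md$loglag - th[["b2"]] * md$lag -
    gamma_log_norm(th, normalized)
  g <- exp(lg)
  g[!md$pos] <- 0
  mu + as.numeric(g %*% sig)
}
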