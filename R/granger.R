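#' Granger-causality F-test of the dosing record on a series
#'
#' Tests whether the lagged drug series improves the linear prediction of a
#' candidate series beyond its own lags.  Two autoregressions are fitted by
#' ordinary least squares on the common estimable sample:
#' the unrestricted model
#' \eqn{x_t = c + \sum_{i=1}^m \alpha_i d_{t-i} + \sum_{i=1}^m \beta_i
#' x_{t-i} + \varepsilon_t} and the restricted model without the drug lags.
#' The statistic is
#' \eqn{F = \frac{(SSR_r - SSR_{ur})/m}{SSR_{ur}/(n - k)}}
#' with `k` the number of parameters of the unrestricted model (2m lags plus
#' the intercept when enabled), referred to the F(m, n - k) distribution;
#' rejection means the dosing record Granger-causes the candidate.
#'
#' Degenerate convention: when every drug lag is identically zero the two
#' models coincide and the test returns `f_stat = 0`, `p_value = 1`.  Any
#' other rank deficiency of the unrestricted design is an error.
#'
#' @param x candidate series ([monitored_series()] or numeric).
#' @param d drug regressor on the same grid, typically a
#'   [dose_mark_series()].
#' @param m number of lags (default 4 minutes on a one-minute grid).
#' @param intercept include an intercept in both regressions (default TRUE).
#' @return An object of class `"granger_test"`: `f_stat`, `df1`, `df2`,
#'   `p_value`, `ssr_restricted`, `ssr_unrestricted`, `lag`.
#' @examples
#' set.seed(1)
#' d <- c(rep(0, 10), 25, rep(0, 19))
#' x <- stats::filter(0.4 * d, 0.5, method = "recursive") + rnorm(30, sd = .1)
#' granger_f_test(as.numeric(x), d, m = 2)
#' @export
granger_f_test <- function(x, d, m = 4, intercept = TRUE) {
  xv <- series_values(x)
  dv <- series_values(d)
  check_common_grid(x, d)
  if (length(xv) != length(dv))
    stop("'x' and 'd' must have the same length", call. = FALSE)
  n_all <- length(xv)
  if (m < 1) stop("'m' must be >= 1", call. = FALSE)
  if (n_all <= 2 * m + 1)
    stop("series too short for m = ", m, " lags", call. = FALSE)

  rows <- (m + 1):n_all
  lagmat <- function(v) sapply(seq_len(m), function(i) v[rows - i])
  Xd <- lagmat(dv)
  Xx <- lagmat(xv)
  y <- xv[rows]
  ic <- if (intercept) matrix(1, length(rows), 1) else NULL

  if (all(Xd == 0)) {
    fit_r <- ols_ssr(cbind(ic, Xx), y)
    res <- granger_result(0, m, length(y) - ncol(cbind(ic, Xx)) - m,
                          fit_r, fit_r, m)
    return(res)
  }

  X_ur <- cbind(ic, Xd, Xx)
  X_r <- cbind(ic, Xx)
  k <- ncol(X_ur)
  df2 <- length(y) - k
  if (df2 < 1) stop("not enough observations for the unrestricted model",
                    call. = FALSE)
  ssr_ur <- ols_ssr(X_ur, y, check_rank = TRUE)
  ssr_r <- ols_ssr(X_r, y, check_rank = TRUE)
  f <- max(0, (ssr_r - ssr_ur) / m) / (ssr_ur / df2)
  granger_result(f, m, df2, ssr_r, ssr_ur, m)
}

granger_result <- function(f, df1, df2, ssr_r, ssr_ur, lag) {
  structure(list(f_stat = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 ssr_restricted = ssr_r, ssr_unrestricted = ssr_ur,
                 lag = lag),
            class = "granger_test")
}

ols_ssr <- function(X, y, check_rank = FALSE) {
  qrx <- qr(X)
  if (check_rank && qrx$rank < ncol(X))
    stop("rank-deficient lag design in Granger regression", call. = FALSE)
  sum(qr.resid(qrx, y)^2)
}

check_common_grid <- function(x, d) {
  if (inherits(x, "monitored_series") && inherits(d, "monitored_series")) {
    if (abs(x$dt - d$dt) > 1e-9 || abs(x$t0 - d$t0) > 1e-9)
      stop("'x' and 'd' are not on the same grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.granger_test <- function(x, ...) {
  cat(sprintf("Granger F-test (m = %d lags): F = %.4g on (%d, %d) df, p = %.4g\n",
              x$lag, x$f_stat, x$df1, x$df2, x$p_value))
  invisible(x)
}

#' Select the wavelet component most predictable from the dosing record
#'
#' Runs [granger_f_test()] for each of the 2J coefficient series of a
#' decomposition (scale and detail, levels 1..J) against the drug regressor
#' and selects the component with the smallest p-value as the modelling
#' target.  Ties are broken deterministically: scale before detail, then the
#' lower level.  No multiple-testing correction is applied to the selection
#' itself, but the report table carries a Bonferroni-adjusted column for
#' transparency.  If no component reaches `alpha`, the smallest-p component
#' is still returned, with a warning.
#'
#' @param W a [haar_modwt()] decomposition.
#' @param d drug regressor on the decomposition grid (see
#'   [dose_mark_series()]).
#' @param m Granger lag count.
#' @param alpha significance level used only for the warning (default 0.05).
#' @param intercept passed to [granger_f_test()].
#' @return An object of class `"granger_selection"`: the selected `series`
#'   ([monitored_series()]), its `label`, and the full result `table`
#'   (data.frame: label, kind, level, f_stat, df1, df2, p_value,
#'   p_bonferroni).
#' @export
select_target_variable <- function(W, d, m = 4, alpha = 0.05,
                                   intercept = TRUE) {
  stopifnot(inherits(W, "wavelet_decomposition"))
  # candidate order implements the tie-break: scale first, low level first
  cand <- rbind(data.frame(kind = "scale", level = seq_len(W$levels)),
                data.frame(kind = "detail", level = seq_len(W$levels)))
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    comp <- get_component(W, cand$kind[i], cand$level[i])
    g <- granger_f_test(comp, d, m = m, intercept = intercept)
    data.frame(label = comp$label, kind = cand$kind[i], level = cand$level[i],
               f_stat = g$f_stat, df1 = g$df1, df2 = g$df2,
               p_value = g$p_value,
               p_bonferroni = min(1, g$p_value * nrow(cand)))
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$p_value)   # first minimum = tie-break order
  if (tab$p_value[best] >= alpha)
    warning("no component is Granger-caused by the dosing record at alpha = ",
            alpha, "; returning the smallest-p component", call. = FALSE)
  sel <- get_component(W, tab$kind[best], tab$level[best])
  structure(list(series = sel, label = tab$label[best], table = tab),
            class = "granger_selection")
}

#' @export
print.granger_selection <- function(x, digits = 4, ...) {
  cat("Granger target selection: selected component '", x$label, "'\n\n",
      sep = "")
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}
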