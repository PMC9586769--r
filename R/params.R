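#' Parameter vector of the drug-effect model
#'
#' Bundles the four baseline parameters of the sinusoidal base level
#' \eqn{\mu_t = a_0 + b_0 \sin(\alpha_0 t + \beta_0)} with the seven kernel
#' parameters of the dose-sigmoid times Gamma-lag excitation kernel (see
#' [excitation_kernel()]).  The flat ordering is fixed as
#' `(a0, b0, alpha0, beta0, a1, b1, kappa1, m1, a2, kappa2, b2)` for every
#' vector interface in the package (bounds, optimizer, JSON).
#'
#' @param a0 baseline level offset, in units of the monitored variable.
#' @param b0 baseline oscillation amplitude, same units.
#' @param alpha0 baseline angular frequency in radians per minute; must be
#'   strictly positive (a zero frequency degenerates the sinusoid).
#' @param beta0 baseline phase in radians.
#' @param a1 sigmoid floor parameter (dimensionless, > 0 so the sigmoid
#'   denominator can never vanish for `b1 >= 0`).
#' @param b1 sigmoid scale (dimensionless, >= 0).
#' @param kappa1 sigmoid steepness, per dose unit.
#' @param m1 dose offset, in dose units.
#' @param a2 dose scaling (dimensionless).
#' @param kappa2 Gamma shape; must exceed 1 so the kernel vanishes at lag 0
#'   and is unimodal (rise then decay).
#' @param b2 Gamma rate parameter, per minute; must be strictly positive.
#'
#' @return A named numeric vector of length 11 with class `"hawkes_params"`.
#' @seealso [reference_params()], [reference_bounds()], [intensity()]
#' @examples
#' p <- reference_params()
#' p["kappa2"]
#' @export
hawkes_params <- function(a0, b0, alpha0, beta0, a1, b1, kappa1, m1,
                          a2, kappa2, b2) {
  th <- c(a0 = a0, b0 = b0, alpha0 = alpha0, beta0 = beta0,
          a1 = a1, b1 = b1, kappa1 = kappa1, m1 = m1,
          a2 = a2, kappa2 = kappa2, b2 = b2)
  validate_params(th)
  structure(th, class = "hawkes_params")
}

#' @rdname hawkes_params
#' @param x object to convert / print.
#' @param ... unused.
#' @export
as_hawkes_params <- function(x, ...) {
  if (inherits(x, "hawkes_params")) return(x)
  x <- as.numeric(x)
  if (length(x) != 11L)
    stop("a parameter vector must have exactly 11 elements", call. = FALSE)
  do.call(hawkes_params, as.list(x))
}

param_names <- function() {
  c("a0", "b0", "alpha0", "beta0", "a1", "b1", "kappa1", "m1",
    "a2", "kappa2", "b2")
}

validate_params <- function(th) {
  if (!all(is.finite(th)))
    stop("all model parameters must be finite", call. = FALSE)
  if (th[["alpha0"]] <= 0)
    stop("'alpha0' must be > 0", call. = FALSE)
  if (th[["a1"]] <= 0)
    stop("'a1' must be > 0", call. = FALSE)
  if (th[["b1"]] < 0)
    stop("'b1' must be >= 0", call. = FALSE)
  if (th[["kappa2"]] <= 1)
    stop("'kappa2' must be > 1 (lag-0 kernel value would not vanish)",
         call. = FALSE)
  if (th[["b2"]] <= 0)
    stop("'b2' must be > 0", call. = FALSE)
  invisible(th)
}

#' @export
print.hawkes_params <- function(x, digits = 4, ...) {
  cat("Drug-effect model parameters\n")
  cat("  baseline: a0 =", format(x[["a0"]], digits = digits),
      " b0 =", format(x[["b0"]], digits = digits),
      " alpha0 =", format(x[["alpha0"]], digits = digits),
      " beta0 =", format(x[["beta0"]], digits = digits), "\n")
  cat("  kernel:   a1 =", format(x[["a1"]], digits = digits),
      " b1 =", format(x[["b1"]], digits = digits),
      " kappa1 =", format(x[["kappa1"]], digits = digits),
      " m1 =", format(x[["m1"]], digits = digits), "\n")
  cat("           a2 =", format(x[["a2"]], digits = digits),
      " kappa2 =", format(x[["kappa2"]], digits = digits),
      " b2 =", format(x[["b2"]], digits = digits), "\n")
  invisible(x)
}

#' Reference simulation parameters and fitting box
#'
#' `reference_params()` returns the canonical "true" parameter set used by the
#' package's simulation studies: a heart-rate-scale baseline (level 70,
#' amplitude 5) with a kernel whose Gamma lag profile peaks ten minutes after
#' each administration.  `reference_bounds()` returns the matching box
#' constraints used as the default search region of [hawkes_fit()].
#'
#' @return `reference_params()`: a [hawkes_params()] vector.
#'   `reference_bounds()`: a 2-column matrix with rows named by parameter and
#'   columns `lower`, `upper`.
#' @examples
#' reference_params()
#' reference_bounds()["kappa2", ]
#' @export
reference_params <- function() {
  hawkes_params(a0 = 70, b0 = 5, alpha0 = 1, beta0 = 2,
                a1 = 1, b1 = 1, kappa1 = 0.3, m1 = -20,
                a2 = 3, kappa2 = 5, b2 = 0.4)
}

#' @rdname reference_params
#' @export
reference_bounds <- function() {
  m <- rbind(a0     = c(1,    100),
             b0     = c(0.1,  10),
             alpha0 = c(0.1,  10),
             beta0  = c(0.1,  10),
             a1     = c(0.1,  50),
             b1     = c(0.01, 10),
             kappa1 = c(0.01, 1),
             m1     = c(-100, 98),
             a2     = c(0.01, 10),
             kappa2 = c(2.1,  22),
             b2     = c(0.01, 2))
  colnames(m) <- c("lower", "upper")
  m
}

#' Serialize / deserialize a parameter vector as JSON
#'
#' Parameters are written with explicit field names (never positionally), so
#' files remain readable and robust to reordering.
#'
#' @param params a [hawkes_params()] vector.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `params_to_json()`: the JSON string (invisibly, when written to a
#'   file); `params_from_json()`: a [hawkes_params()] vector.
#' @export
params_to_json <- function(params, path = NULL) {
  params <- as_hawkes_params(params)
  js <- jsonlite::toJSON(as.list(unclass(params)), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname params_to_json
#' @param input a JSON string or a path to a JSON file.
#' @export
params_from_json <- function(input) {
  obj <- jsonlite::fromJSON(input)
  miss <- setdiff(param_names(), names(obj))
  if (length(miss))
    stop("missing parameter fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  do.call(hawkes_params, obj[param_names()])
}
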