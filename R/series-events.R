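#' Regularly sampled monitored series
#'
#' A light container for a monitored physiological variable on a uniform time
#' grid.  Only the start time `t0`, the sampling interval `dt` (minutes) and
#' the values are stored; the grid itself is implicit.
#'
#' @param values numeric vector of observations, length >= 2.
#' @param t0 start time in minutes (default 0).
#' @param dt sampling interval in minutes, > 0 (default 1, the resolution of
#'   one-minute bedside monitoring).
#' @param label optional short name for the series (e.g. a wavelet component
#'   label such as `"s4"`).
#' @return An object of class `"monitored_series"`.
#' @examples
#' x <- monitored_series(70 + 5 * sin(0:99))
#' series_times(x)[1:5]
#' @export
monitored_series <- function(values, t0 = 0, dt = 1, label = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a series needs at least 2 values", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  if (!is.finite(t0)) stop("'t0' must be finite", call. = FALSE)
  structure(list(t0 = as.numeric(t0), dt = as.numeric(dt), values = values,
                 label = label),
            class = "monitored_series")
}

#' @rdname monitored_series
#' @param x a `monitored_series`.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "monitored_series"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @export
length.monitored_series <- function(x) length(x$values)

#' @export
print.monitored_series <- function(x, ...) {
  cat("Monitored series", if (!is.null(x$label)) paste0("'", x$label, "'"),
      "\n  n =", length(x$values), " dt =", x$dt, "min  t0 =", x$t0, "\n")
  cat("  values: ", paste(format(utils::head(x$values, 5), digits = 5),
                          collapse = ", "),
      if (length(x$values) > 5) "...", "\n")
  invisible(x)
}

#' @export
as.numeric.monitored_series <- function(x, ...) x$values

series_values <- function(x) {
  if (inherits(x, "monitored_series")) x$values else as.numeric(x)
}

#' Drug administration schedule
#'
#' An ordered table of drug administrations, each a `(time, dose)` pair: the
#' marked point process that drives the self-exciting term of the model.
#' Doses must be strictly positive and times non-decreasing; identical times
#' are rejected by default because the excitation kernel sums over events, so
#' silently merging duplicates would hide data errors.  With
#' `merge_duplicates = TRUE` co-timed doses are summed instead.
#'
#' @param time numeric vector of administration times (minutes, >= 0).
#' @param dose numeric vector of doses (arbitrary dose units, > 0); recycled
#'   if scalar.
#' @param merge_duplicates merge events sharing a time by summing doses
#'   (default `FALSE`: duplicates are an error).
#' @return A `data.frame` with columns `time` and `dose` and class
#'   `"event_schedule"`, sorted by time.
#' @examples
#' event_schedule(c(5, 30, 55), 25)
#' @export
event_schedule <- function(time = numeric(), dose = numeric(),
                           merge_duplicates = FALSE) {
  time <- as.numeric(time)
  dose <- as.numeric(dose)
  if (length(dose) == 1L && length(time) > 1L) dose <- rep(dose, length(time))
  if (length(time) != length(dose))
    stop("'time' and 'dose' must have the same length", call. = FALSE)
  if (length(time)) {
    if (any(!is.finite(time)) || any(!is.finite(dose)))
      stop("event times and doses must be finite", call. = FALSE)
    if (any(time < 0)) stop("event times must be >= 0", call. = FALSE)
    if (any(dose <= 0)) stop("doses must be > 0", call. = FALSE)
    o <- order(time)
    time <- time[o]; dose <- dose[o]
    if (anyDuplicated(time)) {
      if (merge_duplicates) {
        dose <- as.numeric(tapply(dose, time, sum))
        time <- sort(unique(time))
      } else {
        stop("duplicate event times; use merge_duplicates = TRUE to sum doses",
             call. = FALSE)
      }
    }
  }
  structure(data.frame(time = time, dose = dose),
            class = c("event_schedule", "data.frame"))
}

n_events <- function(schedule) nrow(schedule)

as_event_schedule <- function(x, ...) {
  if (inherits(x, "event_schedule")) return(x)
  if (is.data.frame(x)) return(event_schedule(x$time, x$dose, ...))
  stop("cannot interpret object as an event schedule", call. = FALSE)
}

#' Generate a synthetic administration schedule
#'
#' Event times are cumulative sums of i.i.d. exponential gaps with the given
#' mean, optionally truncated to a horizon; all doses are constant.  The
#' result is a pure function of its arguments (the RNG state of the session
#' is saved and restored), which makes schedules reproducible fixtures.
#'
#' @param n_events number of gaps drawn (>= 0).
#' @param mean_gap mean inter-administration gap in minutes (> 0).
#' @param dose constant dose per administration (> 0).
#' @param seed integer seed.
#' @param horizon optional upper time limit; events at or beyond it are
#'   dropped.
#' @return An [event_schedule()].
#' @examples
#' generate_event_schedule(5, mean_gap = 13, dose = 25, seed = 1)
#' @export
generate_event_schedule <- function(n_events, mean_gap, dose, seed,
                                    horizon = NULL) {
  stopifnot(n_events >= 0, mean_gap > 0, dose > 0)
  if (n_events == 0) return(event_schedule())
  times <- with_seed(seed, cumsum(stats::rexp(n_events, rate = 1 / mean_gap)))
  if (!is.null(horizon)) times <- times[times < horizon]
  event_schedule(times, rep(dose, length(times)))
}

# Evaluate `expr` under a temporary RNG seed, restoring session RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read and write series / event CSV files
#'
#' The on-disk formats are plain comma-separated files with a header row:
#' `time,value` for a monitored series and `time,dose` for an administration
#' schedule.  A series file must describe a uniform grid; missing rows or
#' missing values are forward-filled (then back-filled for a missing head),
#' and a file that is not uniform even after gap-filling is a format error.
#'
#' @param path file path.
#' @param time_col,value_col column names in the series file.
#' @param fill_missing forward/back-fill missing values (default `TRUE`;
#'   `FALSE` turns any missing value into an error).
#' @return `read_series_csv()`: a [monitored_series()];
#'   `read_events_csv()`: an [event_schedule()].
#' @export
read_series_csv <- function(path, time_col = "time", value_col = "value",
                            fill_missing = TRUE) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("empty series file: ", path, call. = FALSE)
  for (cl in c(time_col, value_col))
    if (!cl %in% names(df))
      stop("series file lacks column '", cl, "'", call. = FALSE)
  tt <- as.numeric(df[[time_col]])
  vv <- as.numeric(df[[value_col]])
  o <- order(tt); tt <- tt[o]; vv <- vv[o]
  if (length(tt) < 2) stop("a series needs at least 2 rows", call. = FALSE)
  dt <- min(diff(tt))
  if (!is.finite(dt) || dt <= 0)
    stop("series times must be strictly increasing", call. = FALSE)
  grid <- seq(tt[1], tt[length(tt)], by = dt)
  idx <- round((tt - tt[1]) / dt) + 1
  if (max(abs(tt - grid[idx])) > 1e-6 * dt)
    stop("series is not on a uniform grid (after gap-filling)", call. = FALSE)
  values <- rep(NA_real_, length(grid))
  values[idx] <- vv
  if (anyNA(values)) {
    if (!fill_missing) stop("series contains missing values", call. = FALSE)
    values <- fill_forward(values)
  }
  monitored_series(values, t0 = tt[1], dt = dt)
}

fill_forward <- function(v) {
  # forward fill, then back-fill a missing head
  ok <- !is.na(v)
  if (!any(ok)) stop("series contains no observed values", call. = FALSE)
  idx <- cummax(ifelse(ok, seq_along(v), 0L))
  v[idx > 0] <- v[idx[idx > 0]]
  if (any(idx == 0)) v[idx == 0] <- v[which(idx > 0)[1]]
  v
}

#' @rdname read_series_csv
#' @param x the object to write.
#' @export
write_series_csv <- function(x, path) {
  stopifnot(inherits(x, "monitored_series"))
  utils::write.csv(data.frame(time = series_times(x), value = x$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_series_csv
#' @param merge_duplicates passed to [event_schedule()].
#' @export
read_events_csv <- function(path, merge_duplicates = FALSE) {
  df <- utils::read.csv(path)
  for (cl in c("time", "dose"))
    if (!cl %in% names(df))
      stop("event file lacks column '", cl, "'", call. = FALSE)
  event_schedule(df$time, df$dose, merge_duplicates = merge_duplicates)
}

#' @rdname read_series_csv
#' @export
write_events_csv <- function(x, path) {
  x <- as_event_schedule(x)
  utils::write.csv(data.frame(time = x$time, dose = x$dose),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dose-mark series on a sampling grid
#'
#' Projects an administration schedule onto the grid of a monitored series:
#' zero between administrations and the dose (or a 0/1 indicator) in the grid
#' cell containing each administration.  This is the drug regressor used by
#' the Granger test.
#'
#' @param schedule an [event_schedule()].
#' @param template a [monitored_series()] supplying the grid.
#' @param encoding `"dose"` (default) or `"indicator"`.
#' @return A [monitored_series()] of marks on the template grid.
#' @export
dose_mark_series <- function(schedule, template,
                             encoding = c("dose", "indicator")) {
  encoding <- match.arg(encoding)
  schedule <- as_event_schedule(schedule)
  stopifnot(inherits(template, "monitored_series"))
  n <- length(template$values)
  marks <- numeric(n)
  if (nrow(schedule)) {
    idx <- round((schedule$time - template$t0) / template$dt) + 1
    if (any(idx < 1 | idx > n))
      stop("event times fall outside the series grid", call. = FALSE)
    val <- if (encoding == "dose") schedule$dose else rep(1, nrow(schedule))
    for (i in seq_along(idx)) marks[idx[i]] <- marks[idx[i]] + val[i]
    if (encoding == "indicator") marks <- as.numeric(marks > 0)
  }
  monitored_series(marks, t0 = template$t0, dt = template$dt, label = "drug")
}
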