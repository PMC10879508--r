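#' Event-time coding configuration
#'
#' Defines the event date, the analysis window and the per-day increment used
#' to construct the four change parameters of a discontinuous growth model:
#' `time` (linear trend through the whole window), `level` (baseline shift at
#' the event), `pre_event` (linear trend before the event) and `post_event`
#' (linear trend after the event).
#'
#' The per-day increment is `1 / denom_days`, so that with the default
#' `denom_days = 31` the main symmetric window (31 days either side of the
#' event) maps its endpoints exactly onto -1 and +1. The increment is held
#' fixed across window variants: a narrower or broader window changes the
#' *range* of the codings (e.g. about +/-1.742 for the 54-day broad window)
#' but not the meaning of a one-unit slope, so slope coefficients remain
#' comparable across windows.
#'
#' @param event_date Calendar date of the event. Default `2022-02-24`, the day
#'   of the Russian invasion of Ukraine.
#' @param window One of `"main"` (event +/- 31 days), `"narrow"` (+/- 7 days),
#'   `"broad"` (+/- 54 days) or `"custom"`.
#' @param window_start,window_end Explicit window bounds, required when
#'   `window = "custom"`; ignored otherwise.
#' @param denom_days Positive integer; days per coded unit. Default 31.
#'
#' @return An object of class `coding_config`: a list with elements
#'   `event_date`, `window`, `window_start`, `window_end`, `denom_days`.
#' @examples
#' cfg <- coding_config()
#' cfg$window_start  # 2022-01-24
#' cfg$window_end    # 2022-03-27
#' @export
coding_config <- function(event_date = as.Date("2022-02-24"),
                          window = c("main", "narrow", "broad", "custom"),
                          window_start = NULL, window_end = NULL,
                          denom_days = 31L) {
  window <- match.arg(window)
  event_date <- as.Date(event_date)
  if (is.na(event_date)) stop("'event_date' is not a valid date")
  if (window == "custom") {
    if (is.null(window_start) || is.null(window_end))
      stop("custom window requires 'window_start' and 'window_end'")
    window_start <- as.Date(window_start)
    window_end <- as.Date(window_end)
  } else {
    half <- switch(window, main = 31L, narrow = 7L, broad = 54L)
    window_start <- event_date - half
    window_end <- event_date + half
  }
  if (window_start > window_end)
    stop("'window_start' must not be after 'window_end'")
  if (!(window_start <= event_date && event_date <= window_end))
    stop("the analysis window must contain the event date")
  denom_days <- as.integer(denom_days)
  if (is.na(denom_days) || denom_days < 1L)
    stop("'denom_days' must be a positive integer")
  structure(
    list(event_date = event_date, window = window,
         window_start = window_start, window_end = window_end,
         denom_days = denom_days),
    class = "coding_config")
}

#' @export
print.coding_config <- function(x, ...) {
  cat("Event-time coding configuration\n")
  cat("  event date:  ", format(x$event_date), "\n", sep = "")
  cat("  window:      ", format(x$window_start), " .. ", format(x$window_end),
      " (", x$window, ", ",
      as.integer(x$window_end - x$window_start) + 1L, " days)\n", sep = "")
  cat("  increment:   1/", x$denom_days, " per day\n", sep = "")
  invisible(x)
}

#' Days of an analysis window
#'
#' @param config A [coding_config()].
#' @return A `Date` vector of every calendar day in the window, inclusive.
#' @export
window_days <- function(config) {
  stopifnot(inherits(config, "coding_config"))
  seq(config$window_start, config$window_end, by = "day")
}

#' Compute the change parameters for calendar dates
#'
#' For each date, with `d` the signed number of days since the event and
#' `m = denom_days`:
#' \deqn{time = d/m,\quad level = -1\,[d < 0],\quad
#'       pre = time\,[d < 0],\quad post = time\,[d > 0].}
#' The event day itself is coded `(0, 0, 0, 0)`: it belongs to the post-event
#' baseline. `time = pre_event + post_event` holds for every date.
#'
#' Dates outside the configured window are coded by the same formula
#' (magnitudes exceed 1); restricting to the window is the caller's choice.
#'
#' @param dates A `Date` vector (or anything `as.Date()` accepts).
#' @param config A [coding_config()].
#' @return A data frame with columns `date`, `time`, `level`, `pre_event`,
#'   `post_event`, one row per input date, in input order.
#' @examples
#' code_date(as.Date(c("2022-01-24", "2022-02-23", "2022-02-24", "2022-03-27")))
#' @export
code_date <- function(dates, config = coding_config()) {
  stopifnot(inherits(config, "coding_config"))
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("'dates' contains unparseable dates")
  d <- as.integer(dates - config$event_date)
  tm <- d / config$denom_days
  data.frame(
    date = dates,
    time = tm,
    level = ifelse(d < 0L, -1, 0),
    pre_event = ifelse(d < 0L, tm, 0),
    post_event = ifelse(d > 0L, tm, 0))
}

#' Join change parameters onto daily scores
#'
#' Appends the four change-parameter columns to a daily-score table. The
#' codings are a pure function of the calendar date, so identical dates
#' receive identical codings for every participant.
#'
#' @param daily A data frame with a `date` column (e.g. from
#'   [aggregate_daily()]).
#' @param config A [coding_config()].
#' @return `daily` with columns `time`, `level`, `pre_event`, `post_event`
#'   appended; row order preserved.
#' @export
build_basis <- function(daily, config = coding_config()) {
  stopifnot(is.data.frame(daily), "date" %in% names(daily))
  basis <- code_date(daily$date, config)
  daily$time <- basis$time
  daily$level <- basis$level
  daily$pre_event <- basis$pre_event
  daily$post_event <- basis$post_event
  daily
}
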