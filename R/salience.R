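# Daily event-salience series: standardization across window days, join to
# daily well-being (optionally lagged), within/between-person decomposition,
# and the salience -> well-being mixed models.

#' Standardize a daily salience series
#'
#' z-standardizes the daily tweet counts across the days of the analysis
#' window (sample SD, `n - 1`). Days outside the window are dropped.
#'
#' @param series A data frame with `date` and `tweet_count` (see
#'   [read_salience_table()]).
#' @param window Length-2 vector of window bounds, or a [coding_config()].
#' @return The window rows of `series` with a `salience_z` column appended.
#' @export
standardize_salience <- function(series, window = coding_config()) {
  if (inherits(window, "coding_config"))
    window <- c(window$window_start, window$window_end)
  window <- as.Date(window)
  stopifnot(is.data.frame(series),
            all(c("date", "tweet_count") %in% names(series)))
  series <- series[series$date >= window[1] & series$date <= window[2], ,
                   drop = FALSE]
  series$salience_z <- .zstd(series$tweet_count, "salience series")
  series
}

#' Join a salience series to daily well-being scores
#'
#' Pairs each participant-day with the (standardized) salience of that day,
#' or, with `lag = 1`, of the previous day. Rows with no matching series date
#' are dropped and their count reported in a message.
#'
#' @param daily Daily scores (see [aggregate_daily()]).
#' @param series A standardized salience series (see
#'   [standardize_salience()]).
#' @param lag Integer lag in days, 0 (same day) or 1 (previous day).
#' @return `daily` with a `salience_z` column appended.
#' @export
join_salience <- function(daily, series, lag = 0L) {
  stopifnot(is.data.frame(daily), "date" %in% names(daily),
            "salience_z" %in% names(series))
  lag <- as.integer(lag)
  if (!lag %in% c(0L, 1L)) stop("'lag' must be 0 or 1")
  key <- match(daily$date - lag, series$date)
  out <- daily
  out$salience_z <- series$salience_z[key]
  dropped <- sum(is.na(key))
  if (dropped > 0L)
    message(dropped, " daily score(s) dropped: no salience value for date - ",
            lag)
  out[!is.na(key), , drop = FALSE]
}

#' Decompose salience into between- and within-person components
#'
#' Splits each participant-day's salience into a between-subjects component
#' `bs` (the person's mean salience over all days on which they actually
#' participated) and a within-subjects component `ws = salience_z - bs` (the
#' daily deviation from that mean). By construction `ws + bs` reconstructs
#' `salience_z` exactly and each person's mean `ws` is zero.
#'
#' @param joined Daily scores joined with `salience_z` (see
#'   [join_salience()]).
#' @return `joined` with `bs` and `ws` columns appended.
#' @export
decompose_ws_bs <- function(joined) {
  stopifnot(all(c("participant_id", "salience_z") %in% names(joined)))
  pm <- tapply(joined$salience_z, joined$participant_id, mean)
  joined$bs <- as.numeric(pm[match(joined$participant_id, names(pm))])
  joined$ws <- joined$salience_z - joined$bs
  joined
}

#' Fit a salience -> well-being mixed model
#'
#' Undecomposed: daily well-being regressed on same-row salience with a
#' random intercept and a random salience slope. Decomposed: well-being
#' regressed on the within-person (`ws`) and between-person (`bs`)
#' components, with a random intercept and a random `ws` slope -- `bs` is
#' constant within person, so it can only enter as a fixed effect. An
#' optional person-level moderator adds its main effect and cross-level
#' interactions with the within-person predictor(s), as in the trajectory
#' models.
#'
#' @param rows Joined (and, if `decomposed`, decomposed) participant-day
#'   rows with `wb_z`.
#' @param decomposed Logical; fit the ws/bs split model. Default `FALSE`.
#' @param traits Optional person-level covariate table.
#' @param moderator Optional standardized covariate name.
#' @param ... Passed to [fit_ml()].
#' @return An `lmm_ml` fit.
#' @export
fit_salience_model <- function(rows, decomposed = FALSE, traits = NULL,
                               moderator = NULL, ...) {
  lvl1 <- if (decomposed) "ws" else "salience_z"
  fixed <- if (decomposed) c("ws", "bs") else "salience_z"
  need <- c("participant_id", "wb_z", fixed)
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("rows lack column(s): ", paste(miss, collapse = ", "),
         if (decomposed && any(c("ws", "bs") %in% miss))
           " (run decompose_ws_bs() first)")
  data <- rows
  if (!is.null(moderator)) {
    if (!is.null(traits) && moderator %in% names(traits))
      data <- merge(data, traits[c("participant_id", moderator)],
                    by = "participant_id", sort = FALSE)
    if (!moderator %in% names(data)) stop("unknown moderator: ", moderator)
    keep <- !is.na(data[[moderator]])
    if (!all(keep)) {
      warning(sum(!keep), " row(s) dropped: missing '", moderator, "'")
      data <- data[keep, , drop = FALSE]
    }
    if (stats::sd(data[[moderator]]) == 0)
      stop("moderator '", moderator, "' has zero variance")
    inter <- paste0(lvl1, ":", moderator)
    data[[inter]] <- data[[lvl1]] * data[[moderator]]
    fixed <- c(fixed, moderator, inter)
  }
  design <- grouped_design(data, response = "wb_z", fixed = fixed,
                           random = lvl1, group = "participant_id")
  fit_ml(design, ...)
}
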