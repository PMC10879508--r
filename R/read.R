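# CSV readers with schema mapping and validation. All readers return plain
# data frames; validation failures name the offending column or row.

.affect_items <- c("pa1", "pa2", "pa3", "na1", "na2", "na3")

.map_columns <- function(df, required, schema, what) {
  schema <- if (is.null(schema)) stats::setNames(required, required)
  else utils::modifyList(as.list(stats::setNames(required, required)),
                         as.list(schema))
  for (canonical in required) {
    src <- schema[[canonical]]
    if (is.null(src) || !src %in% names(df))
      stop(sprintf("schema error in %s: missing column '%s'", what,
                   if (is.null(src)) canonical else src), call. = FALSE)
    names(df)[names(df) == src] <- canonical
  }
  df
}

.check_range <- function(x, lo, hi, column, what) {
  bad <- which(!is.na(x) & (x < lo | x > hi | x != round(x)))
  if (length(bad))
    stop(sprintf("validation error in %s: column '%s' outside %d-%d at row(s) %s",
                 what, column, lo, hi,
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Read a state (random-beep) assessment table
#'
#' Reads per-beep affect responses: three positive-affect and three
#' negative-affect items on a 1-6 agreement scale, with participant id and an
#' ISO-8601 timestamp. Item values are range-checked; timestamps are parsed as
#' supplied (no timezone conversion) and a calendar `date` column is derived
#' from the timestamp's own wall-clock date.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Optional named list/vector mapping canonical column names
#'   (`participant_id`, `timestamp`, `pa1`..`pa3`, `na1`..`na3`) to the file's
#'   column names, for files with different headers.
#' @return A data frame with columns `participant_id`, `timestamp` (POSIXct),
#'   `date` (Date), `pa1`..`na3` and `survey_kind`; row order preserved.
#'   An empty file yields a zero-row frame with a warning.
#' @export
read_state_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .map_columns(df, c("participant_id", "timestamp", .affect_items),
                     schema, "state table")
  if (nrow(df) == 0L) {
    warning("state table is empty: ", path)
    df$date <- as.Date(character())
    df$survey_kind <- character()
    return(df)
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"),
                   optional = TRUE)
  if (anyNA(ts))
    stop(sprintf("validation error in state table: unparseable timestamp at row(s) %s",
                 paste(utils::head(which(is.na(ts)), 5L), collapse = ", ")),
         call. = FALSE)
  df$timestamp <- ts
  df$date <- as.Date(ts)
  for (item in .affect_items) .check_range(df[[item]], 1L, 6L, item, "state table")
  if (is.null(df$survey_kind)) df$survey_kind <- "random_beep"
  df
}

#' Read a participant (trait and quality) table
#'
#' @param path Path to a CSV with one row per participant: `participant_id`,
#'   `gender`, `age`, `subjective_social_status`, `political_orientation`, the
#'   five BFI-2 domain scores `bfi_e`, `bfi_a`, `bfi_c`, `bfi_n`, `bfi_o`
#'   (1-5 scale, reverse-keying assumed done upstream), `conscientious_flag`,
#'   `mean_seconds_per_item`, `country`, `is_european`.
#' @param schema Optional column-name mapping as in [read_state_table()].
#' @return A data frame, one row per participant.
#' @export
read_participant_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "gender", "age", "subjective_social_status",
           "political_orientation", "bfi_e", "bfi_a", "bfi_c", "bfi_n",
           "bfi_o", "conscientious_flag", "mean_seconds_per_item",
           "country", "is_european")
  df <- .map_columns(df, req, schema, "participant table")
  if (anyDuplicated(df$participant_id))
    stop("validation error in participant table: duplicated participant_id")
  for (dom in c("bfi_e", "bfi_a", "bfi_c", "bfi_n", "bfi_o")) {
    bad <- which(!is.na(df[[dom]]) & (df[[dom]] < 1 | df[[dom]] > 5))
    if (length(bad))
      stop(sprintf("validation error in participant table: '%s' outside 1-5 at row(s) %s",
                   dom, paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
  }
  bad <- which(!is.na(df$mean_seconds_per_item) & df$mean_seconds_per_item <= 0)
  if (length(bad))
    stop("validation error in participant table: non-positive mean_seconds_per_item at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  df$conscientious_flag <- as.logical(df$conscientious_flag)
  df$is_european <- as.logical(df$is_european)
  df
}

#' Read a daily salience series
#'
#' @param path Path to a CSV with columns `date` (ISO, UTC day) and
#'   `tweet_count` (non-negative integer).
#' @param schema Optional column-name mapping.
#' @return A data frame with `date` (Date) and `tweet_count`, one row per date.
#' @export
read_salience_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .map_columns(df, c("date", "tweet_count"), schema, "salience table")
  df$date <- as.Date(df$date)
  if (anyNA(df$date))
    stop("validation error in salience table: unparseable date", call. = FALSE)
  if (anyDuplicated(df$date))
    stop("validation error in salience table: duplicated date", call. = FALSE)
  bad <- which(!is.na(df$tweet_count) & df$tweet_count < 0)
  if (length(bad))
    stop("validation error in salience table: negative tweet_count at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  df
}
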