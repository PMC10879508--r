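# Preprocessing of experience-sampling data into analysis-ready daily scores:
# scoring, exclusion rules, window restriction, standardization, aggregation.

.zstd <- function(x, what = "values") {
  x_ok <- x[!is.na(x)]
  if (length(x_ok) < 2L)
    stop("cannot standardize ", what, ": fewer than 2 observations")
  s <- stats::sd(x_ok)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize ", what, ": zero variance")
  (x - mean(x_ok)) / s
}

#' Score state-level affective well-being
#'
#' Affective well-being at a single beep is the mean of the three
#' positive-affect items and the three reverse-scored (`7 - x`) negative-affect
#' items, all on a 1-6 scale, so the score also lies in \[1, 6\].
#'
#' @param states A data frame with columns `pa1`..`pa3`, `na1`..`na3` (e.g.
#'   from [read_state_table()]).
#' @return A numeric vector, one score per row.
#' @examples
#' score_state_wb(data.frame(pa1 = 3, pa2 = 4, pa3 = 5,
#'                           na1 = 2, na2 = 1, na3 = 3))  # 4.5
#' @export
score_state_wb <- function(states) {
  stopifnot(is.data.frame(states), all(.affect_items %in% names(states)))
  items <- as.matrix(states[.affect_items])
  miss <- which(rowSums(is.na(items)) > 0L)
  if (length(miss))
    stop("missing affect item(s) at row(s) ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  items[, c("na1", "na2", "na3")] <- 7 - items[, c("na1", "na2", "na3")]
  unname(rowMeans(items))
}

#' Score daily societal well-being
#'
#' Combines evening ratings of positivity towards, reversed perceived threat
#' from, and perceived similarity with people in one's country (each 1-10)
#' into `(positivity + (11 - threat) + similarity) / 3`.
#'
#' @param evening A data frame with columns `positivity`, `threat`,
#'   `similarity`.
#' @return A numeric vector on the 1-10 scale.
#' @export
score_societal_wb <- function(evening) {
  stopifnot(is.data.frame(evening),
            all(c("positivity", "threat", "similarity") %in% names(evening)))
  items <- as.matrix(evening[c("positivity", "threat", "similarity")])
  miss <- which(rowSums(is.na(items)) > 0L)
  if (length(miss))
    stop("missing evening item(s) at row(s) ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  unname((items[, "positivity"] + (11 - items[, "threat"]) +
            items[, "similarity"]) / 3)
}

#' Restrict state records to an analysis window
#'
#' Keeps records whose calendar date lies in `[start_date, end_date]`, both
#' inclusive.
#'
#' @param states A state data frame with a `date` column.
#' @param start_date,end_date Window bounds (`Date` or ISO strings).
#' @return The filtered data frame, original row order preserved.
#' @export
restrict_window <- function(states, start_date, end_date) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (start_date > end_date)
    stop("'start_date' must not be after 'end_date'")
  stopifnot("date" %in% names(states))
  states[states$date >= start_date & states$date <= end_date, , drop = FALSE]
}

#' Apply participant exclusion rules
#'
#' Excludes, in order: (a) participants who flagged their own survey answers
#' as not conscientious, (b) participants who averaged less than two seconds
#' per item in the pre-survey, and (c) participants with state data on fewer
#' than two distinct days inside the analysis window (two days are the minimum
#' for any within-person variance on the change parameters). Each excluded
#' participant is attributed to the first rule that removes them.
#'
#' @param states A state data frame with `participant_id` and `date`.
#' @param participants A participant data frame with `conscientious_flag` and
#'   `mean_seconds_per_item`.
#' @param window Length-2 vector of window bounds used for rule (c).
#' @return A list with elements `states` and `participants` (retained rows
#'   only) and `report`, an object of class `exclusion_report` with the
#'   per-rule counts.
#' @export
apply_exclusions <- function(states, participants, window) {
  window <- as.Date(window)
  if (length(window) != 2L || anyNA(window) || window[1] > window[2])
    stop("'window' must be two ordered dates")
  in_win <- states[states$date >= window[1] & states$date <= window[2], ]
  days <- tapply(in_win$date, in_win$participant_id,
                 function(d) length(unique(d)))
  n_days <- as.integer(days[match(participants$participant_id, names(days))])
  n_days[is.na(n_days)] <- 0L
  fail_a <- !isTRUE_vec(participants$conscientious_flag)
  fail_b <- is.na(participants$mean_seconds_per_item) |
    participants$mean_seconds_per_item < 2
  fail_c <- n_days < 2L
  rule <- rep(NA_character_, nrow(participants))
  rule[fail_c] <- "c"
  rule[fail_b] <- "b"
  rule[fail_a] <- "a"
  keep <- is.na(rule)
  report <- structure(
    list(n_input = nrow(participants),
         excluded = c(a = sum(rule == "a", na.rm = TRUE),
                      b = sum(rule == "b", na.rm = TRUE),
                      c = sum(rule == "c", na.rm = TRUE)),
         n_retained = sum(keep),
         window = window),
    class = "exclusion_report")
  kept_ids <- participants$participant_id[keep]
  list(states = states[states$participant_id %in% kept_ids, , drop = FALSE],
       participants = participants[keep, , drop = FALSE],
       report = report)
}

# vectorized isTRUE: NA counts as FALSE
isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Participant exclusions (window ", format(x$window[1]), " .. ",
      format(x$window[2]), ")\n", sep = "")
  cat("  input participants:       ", x$n_input, "\n")
  cat("  (a) not conscientious:    ", x$excluded["a"], "\n")
  cat("  (b) < 2 s per item:       ", x$excluded["b"], "\n")
  cat("  (c) < 2 days of states:   ", x$excluded["c"], "\n")
  cat("  retained:                 ", x$n_retained, "\n")
  invisible(x)
}

#' Standardize state-level well-being scores
#'
#' z-standardizes the state-level well-being score across all measurement
#' points across all days (sample standard deviation, `n - 1` denominator).
#' Daily aggregation happens after this step, so a day's score is the mean of
#' its beeps' z-scores.
#'
#' @param states A state data frame with a `wb_state` column (see
#'   [score_state_wb()]).
#' @return `states` with a `wb_z` column appended.
#' @export
standardize_states <- function(states) {
  stopifnot("wb_state" %in% names(states))
  states$wb_z <- .zstd(states$wb_state, "state well-being")
  states
}

#' Aggregate state scores to participant-days
#'
#' One row per participant and calendar date: `wb_z` is the mean of that
#' day's state-level z-scores, `wb_raw` the mean of the raw 1-6 scores and
#' `n_states` the number of beeps contributing.
#'
#' @param states A state data frame with `participant_id`, `date`, `wb_state`
#'   and `wb_z` columns.
#' @return A data frame of daily scores sorted by participant and date.
#' @export
aggregate_daily <- function(states) {
  stopifnot(all(c("participant_id", "date", "wb_state", "wb_z") %in%
                  names(states)))
  if (nrow(states) == 0L)
    return(data.frame(participant_id = character(), date = as.Date(character()),
                      wb_raw = numeric(), wb_z = numeric(),
                      n_states = integer()))
  key <- paste(states$participant_id, format(states$date, "%Y-%m-%d"),
               sep = "\r")
  sums <- rowsum(cbind(raw = states$wb_state, z = states$wb_z,
                       n = rep(1, nrow(states))), key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  out <- data.frame(
    participant_id = vapply(parts, `[`, "", 1L),
    date = as.Date(vapply(parts, `[`, "", 2L)),
    wb_raw = sums[, "raw"] / sums[, "n"],
    wb_z = sums[, "z"] / sums[, "n"],
    n_states = as.integer(sums[, "n"]))
  out <- out[order(out$participant_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score personality meta-traits
#'
#' Computes the meta-trait Stability as the mean of Agreeableness,
#' Conscientiousness and reversed Neuroticism, `(A + C + (6 - N)) / 3`, and
#' Plasticity as the mean of Extraversion and Openness, `(E + O) / 2`, from
#' BFI-2 domain scores (1-5 scale). Raw meta-traits are then z-standardized
#' across the participants with complete domain data; participants with a
#' missing domain keep `NA` z-scores and are flagged for exclusion from trait
#' analyses only.
#'
#' @param participants A participant data frame with columns `bfi_e`, `bfi_a`,
#'   `bfi_c`, `bfi_n`, `bfi_o`.
#' @return A data frame with `participant_id`, `stability_raw`,
#'   `plasticity_raw`, `stability_z` (named `stability`), `plasticity_z`
#'   (named `plasticity`) and `trait_complete`.
#' @export
score_traits <- function(participants) {
  doms <- c("bfi_e", "bfi_a", "bfi_c", "bfi_n", "bfi_o")
  stopifnot(is.data.frame(participants),
            all(c("participant_id", doms) %in% names(participants)))
  complete <- stats::complete.cases(participants[doms])
  stability_raw <- with(participants, (bfi_a + bfi_c + (6 - bfi_n)) / 3)
  plasticity_raw <- with(participants, (bfi_e + bfi_o) / 2)
  stability_raw[!complete] <- NA_real_
  plasticity_raw[!complete] <- NA_real_
  out <- data.frame(participant_id = participants$participant_id,
                    stability_raw = stability_raw,
                    plasticity_raw = plasticity_raw,
                    stability = .zstd(stability_raw, "Stability"),
                    plasticity = .zstd(plasticity_raw, "Plasticity"),
                    trait_complete = complete)
  rownames(out) <- NULL
  out
}

#' Preprocess raw tables into daily scores with change parameters
#'
#' Convenience wrapper running the full ingest chain: state scoring, window
#' restriction, exclusion rules, state-level standardization (computed across
#' all retained measurements, i.e. post-exclusion), daily aggregation and
#' change-parameter coding.
#'
#' @param states,participants Data frames as returned by the readers.
#' @param config A [coding_config()] defining the window and event coding.
#' @return A list with `daily` (daily scores joined with the change basis),
#'   `states` and `participants` (retained rows, states scored and
#'   standardized), `traits` (from [score_traits()]) and `report`.
#' @export
prepare_daily <- function(states, participants, config = coding_config()) {
  if (!"date" %in% names(states)) {
    # accept in-memory tables (e.g. from generate()) that have not been
    # round-tripped through read_state_table()
    if (is.character(states$timestamp))
      states$timestamp <- as.POSIXct(states$timestamp, tz = "UTC",
                                     format = "%Y-%m-%dT%H:%M:%S")
    states$date <- as.Date(states$timestamp)
  }
  states$wb_state <- score_state_wb(states)
  states <- restrict_window(states, config$window_start, config$window_end)
  excl <- apply_exclusions(states, participants,
                           c(config$window_start, config$window_end))
  states <- standardize_states(excl$states)
  daily <- aggregate_daily(states)
  daily <- build_basis(daily, config)
  list(daily = daily, states = states, participants = excl$participants,
       traits = score_traits(excl$participants), report = excl$report)
}
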