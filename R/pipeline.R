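# End-to-end orchestration: ingest -> coding -> model family -> moderation,
# and the salience analyses, with machine-readable reports and a manifest.

#' Run configuration for the end-to-end pipelines
#'
#' @param state_csv,participant_csv,salience_csv Input CSV paths
#'   (`salience_csv` may be `NULL` when only the trajectory analysis is run).
#' @param coding A [coding_config()].
#' @param moderators Person-level covariates to fit, one model each. Any of
#'   `"stability"`, `"plasticity"`, `"age"`, `"subjective_social_status"`,
#'   `"political_orientation"`, `"gender"`.
#' @param salience_lag Extra lag (days) for the lagged salience model.
#' @param out_dir Output directory for the report bundle.
#' @param schema Optional column mapping passed to the readers.
#' @param seed Optional integer recorded in the manifest (the analyses are
#'   deterministic; the seed is a pass-through for simulated inputs).
#' @return A `run_config` list.
#' @export
run_config <- function(state_csv, participant_csv, salience_csv = NULL,
                       coding = coding_config(), moderators = "stability",
                       salience_lag = 1L, out_dir, schema = NULL,
                       seed = NULL) {
  stopifnot(inherits(coding, "coding_config"))
  structure(list(state_csv = state_csv, participant_csv = participant_csv,
                 salience_csv = salience_csv, coding = coding,
                 moderators = moderators, salience_lag = salience_lag,
                 out_dir = out_dir, schema = schema, seed = seed),
            class = "run_config")
}

# Standardized person-level covariates for moderation analyses. Gender is
# coded female/male only (other/missing dropped), then standardized like the
# quasi-continuous covariates.
.person_covariates <- function(participants, traits) {
  z_or_na <- function(x) {
    x <- as.numeric(x)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x, na.rm = TRUE)) / s
  }
  g <- ifelse(participants$gender %in% c("female", "male"),
              as.numeric(participants$gender == "male"), NA_real_)
  data.frame(participant_id = participants$participant_id,
             stability = traits$stability,
             plasticity = traits$plasticity,
             age = z_or_na(participants$age),
             subjective_social_status =
               z_or_na(participants$subjective_social_status),
             political_orientation =
               z_or_na(participants$political_orientation),
             gender = z_or_na(g))
}

.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

.write_manifest <- function(config, path, extra = list()) {
  inputs <- Filter(Negate(is.null),
                   list(state_csv = config$state_csv,
                        participant_csv = config$participant_csv,
                        salience_csv = config$salience_csv))
  manifest <- c(list(
    package = "dgcm",
    version = as.character(utils::packageVersion("dgcm")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    coding = list(event_date = format(config$coding$event_date),
                  window_start = format(config$coding$window_start),
                  window_end = format(config$coding$window_end),
                  denom_days = config$coding$denom_days),
    moderators = as.list(config$moderators),
    seed = config$seed), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
}

#' Run the main trajectory analysis end-to-end
#'
#' Ingests and preprocesses the state and participant tables, codes event
#' time, fits and compares the eight-model family by AIC, and extends the
#' AIC winner with each configured person-level moderator in a separate
#' model. Writes `comparison.csv`, one coefficient CSV + JSON per model and
#' per moderation, `exclusions.json` and `manifest.json` into
#' `config$out_dir`. On error, partial outputs are removed and the error is
#' re-signalled with the failing stage's name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (0 = clean, 3 = at least one model
#'   did not converge), `family`, `moderated`, `daily`, `report`, `paths`.
#' @export
run_main_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  result <- tryCatch({
    states <- .with_stage("ingest",
                          read_state_table(config$state_csv, config$schema))
    participants <- .with_stage("ingest",
                                read_participant_table(config$participant_csv))
    prep <- .with_stage("preprocess",
                        prepare_daily(states, participants, config$coding))
    fam <- .with_stage("fit-family", fit_family(prep$daily))
    covars <- .with_stage("moderate",
                          .person_covariates(prep$participants, prep$traits))
    moderated <- lapply(config$moderators, function(cv)
      .with_stage(paste0("moderate:", cv),
                  moderate(prep$daily, covars, cv, model = fam$winner)))
    names(moderated) <- config$moderators

    p <- file.path(out, "comparison.csv")
    utils::write.csv(fam$table, p, row.names = FALSE)
    written <- c(written, p)
    for (nm in names(fam$fits)) {
      ps <- write_fit(fam$fits[[nm]], file.path(out, paste0("model_", nm)))
      written <- c(written, ps)
    }
    for (cv in names(moderated)) {
      ps <- write_fit(moderated[[cv]],
                      file.path(out, paste0("moderated_", cv)))
      written <- c(written, ps)
    }
    p <- file.path(out, "exclusions.json")
    jsonlite::write_json(unclass(prep$report), p, auto_unbox = TRUE,
                         digits = NA, Date = "ISO8601")
    written <- c(written, p)
    p <- file.path(out, "daily_scores.csv")
    utils::write.csv(prep$daily, p, row.names = FALSE)
    written <- c(written, p)
    all_conv <- all(fam$table$converged) &
      all(vapply(moderated, function(f) f$converged, TRUE))
    .write_manifest(config, file.path(out, "manifest.json"),
                    extra = list(analysis = "main", winner = fam$winner,
                                 converged = all_conv))
    list(status = if (all_conv) 0L else 3L, family = fam,
         moderated = moderated, daily = prep$daily,
         report = prep$report,
         paths = c(written, file.path(out, "manifest.json")))
  }, error = function(e) { unlink(written); stop(e) })
  invisible(result)
}

#' Run the salience analyses end-to-end
#'
#' Preprocesses as in [run_main_analysis()], standardizes the daily salience
#' series across window days, and fits three models of daily well-being:
#' same-day salience (random intercept and slope), the within/between
#' decomposition (`ws` + `bs`, random `ws` slope), and a lagged same-day
#' model with salience from `salience_lag` days before. Writes one
#' coefficient CSV + JSON per model and `manifest.json`.
#'
#' @param config A [run_config()] with `salience_csv` set.
#' @return Invisibly, a list with `status`, the three fits, and `paths`.
#' @export
run_salience_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$salience_csv))
    stop("[stage: ingest] 'salience_csv' is not configured", call. = FALSE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  result <- tryCatch({
    states <- .with_stage("ingest",
                          read_state_table(config$state_csv, config$schema))
    participants <- .with_stage("ingest",
                                read_participant_table(config$participant_csv))
    series <- .with_stage("ingest",
                          read_salience_table(config$salience_csv))
    prep <- .with_stage("preprocess",
                        prepare_daily(states, participants, config$coding))
    series <- .with_stage("salience-standardize",
                          standardize_salience(series, config$coding))
    joined <- .with_stage("salience-join",
                          join_salience(prep$daily, series, lag = 0L))
    decomposed <- .with_stage("salience-decompose", decompose_ws_bs(joined))
    lagged <- .with_stage("salience-join",
                          join_salience(prep$daily, series,
                                        lag = config$salience_lag))
    fits <- list(
      undecomposed = .with_stage("salience-fit",
                                 fit_salience_model(joined)),
      decomposed = .with_stage("salience-fit",
                               fit_salience_model(decomposed,
                                                  decomposed = TRUE)),
      lagged = .with_stage("salience-fit", fit_salience_model(lagged)))
    for (nm in names(fits)) {
      ps <- write_fit(fits[[nm]], file.path(out, paste0("salience_", nm)))
      written <- c(written, ps)
    }
    all_conv <- all(vapply(fits, function(f) f$converged, TRUE))
    .write_manifest(config, file.path(out, "manifest.json"),
                    extra = list(analysis = "salience",
                                 lag = config$salience_lag,
                                 converged = all_conv))
    list(status = if (all_conv) 0L else 3L, fits = fits,
         paths = c(written, file.path(out, "manifest.json")))
  }, error = function(e) { unlink(written); stop(e) })
  invisible(result)
}
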