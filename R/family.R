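# The eight-model trajectory family: each model is a combination of the four
# change parameters at Level 1, always fitted with a random intercept and
# random slopes on every included change parameter.

.family_terms <- list(
  "1a" = character(),
  "1b" = "level",
  "1c" = "post_event",
  "1d" = c("post_event", "level"),
  "2a" = "time",
  "2b" = c("time", "level"),
  "2c" = c("pre_event", "post_event"),
  "2d" = c("pre_event", "post_event", "level"))

.family_meaning <- c(
  "1a" = "no change at all",
  "1b" = "baseline level change at the event",
  "1c" = "gradual change after the event",
  "1d" = "level change at the event, then gradual change",
  "2a" = "gradual change independent of the event",
  "2b" = "gradual change plus level change at the event",
  "2c" = "independent gradual change before and after the event",
  "2d" = "pre-event trend, level change, and post-event trend")

#' The eight trajectory model specifications
#'
#' Returns the full family of discontinuous growth models: every model has a
#' random intercept and random slopes on all of its Level-1 change
#' parameters.
#'
#' @param name Optional model name (`"1a"`..`"2d"`); when given, only that
#'   specification is returned.
#' @return A list of model specs (or a single spec), each a list with `name`,
#'   `terms`, `meaning`.
#' @export
model_specs <- function(name = NULL) {
  specs <- lapply(names(.family_terms), function(nm)
    structure(list(name = nm, terms = .family_terms[[nm]],
                   meaning = .family_meaning[[nm]]), class = "model_spec"))
  names(specs) <- names(.family_terms)
  if (is.null(name)) return(specs)
  if (!name %in% names(specs)) stop("unknown model: ", name)
  specs[[name]]
}

#' Build the grouped design for a trajectory model
#'
#' Fixed effects are the intercept and the model's change parameters; a
#' person-level moderator additionally enters with its main effect and its
#' interaction with every change parameter (cross-level interactions).
#' Random effects are the intercept and all change parameters -- person-level
#' covariates get no random effects.
#'
#' @param daily Daily scores joined with the change basis (see
#'   [build_basis()]), with `participant_id` and `wb_z` columns.
#' @param spec A model spec from [model_specs()] or a model name.
#' @param traits Optional person-level covariate table (e.g. from
#'   [score_traits()]) with `participant_id`; required when `moderator` is
#'   given.
#' @param moderator Optional name of a (standardized) covariate column in
#'   `traits` or `daily`.
#' @return A [grouped_design()]. Participants with a missing moderator value
#'   are dropped with a warning.
#' @export
build_design <- function(daily, spec, traits = NULL, moderator = NULL) {
  if (is.character(spec)) spec <- model_specs(spec)
  stopifnot(inherits(spec, "model_spec"))
  need <- c("participant_id", "wb_z", spec$terms)
  miss <- setdiff(need, names(daily))
  if (length(miss))
    stop("daily data lack column(s): ", paste(miss, collapse = ", "))
  data <- daily
  fixed <- spec$terms
  if (!is.null(moderator)) {
    if (!is.null(traits) && moderator %in% names(traits)) {
      data <- merge(data, traits[c("participant_id", moderator)],
                    by = "participant_id", sort = FALSE)
    } else if (!moderator %in% names(data)) {
      stop("unknown moderator: ", moderator)
    }
    m <- data[[moderator]]
    drop <- is.na(m)
    if (any(drop)) {
      warning(sum(drop), " row(s) dropped: missing '", moderator, "'")
      data <- data[!drop, , drop = FALSE]
      m <- data[[moderator]]
    }
    if (stats::sd(m) == 0) stop("moderator '", moderator, "' has zero variance")
    for (term in spec$terms)
      data[[paste0(term, ":", moderator)]] <- data[[term]] * m
    fixed <- c(spec$terms, moderator,
               paste0(spec$terms, ":", moderator))
  }
  data <- data[order(data$participant_id, data$date), , drop = FALSE]
  grouped_design(data, response = "wb_z", fixed = fixed,
                 random = spec$terms, group = "participant_id")
}

#' Fit a discontinuous growth curve model
#'
#' The headline fitting function: fits one model of the trajectory family
#' (default `"2d"`: pre-event trend, level change at the event, post-event
#' trend) to standardized daily well-being scores by maximum likelihood,
#' optionally moderated by a person-level covariate such as the meta-trait
#' Stability.
#'
#' @inheritParams build_design
#' @param model Model name (`"1a"`..`"2d"`) or a spec from [model_specs()].
#' @param ... Passed to [fit_ml()].
#' @return An object of class `c("dgcm", "lmm_ml")`; all `lmm_ml` methods
#'   (`print`, `summary`, `coef`, `confint`, `vcov`, `logLik`, `residuals`,
#'   `simulate`, ...) apply, plus [predict.dgcm()].
#' @examples
#' \donttest{
#' sim <- generate(generator_config(n_participants = 80), seed = 1)
#' prep <- prepare_daily(sim$states, sim$participants)
#' fit <- dgcm(prep$daily)
#' coef(fit)
#' }
#' @export
dgcm <- function(daily, model = "2d", traits = NULL, moderator = NULL, ...) {
  spec <- if (is.character(model)) model_specs(model) else model
  design <- build_design(daily, spec, traits = traits, moderator = moderator)
  fit <- fit_ml(design, ...)
  fit$spec <- spec
  fit$moderator <- moderator
  class(fit) <- c("dgcm", class(fit))
  fit
}

#' @export
print.dgcm <- function(x, digits = 3, ...) {
  cat("Discontinuous growth model ", x$spec$name, " (",
      x$spec$meaning, ")\n", sep = "")
  if (!is.null(x$moderator))
    cat("  moderated by: ", x$moderator, "\n", sep = "")
  NextMethod()
}

#' Fit and compare the eight-model trajectory family
#'
#' Fits all eight models by ML on identical rows and ranks them by AIC
#' (ascending); ties closer than `1e-6` are broken towards the model with
#' fewer parameters. Non-convergence is flagged in the table and the model
#' retained.
#'
#' @param daily Daily scores joined with the change basis.
#' @param models Model names to include; default the whole family.
#' @param ... Passed to [fit_ml()].
#' @return An object of class `dgcm_family`: list with `table` (model,
#'   loglik, k, aic, delta_aic, rank, converged) sorted by AIC, and `fits`,
#'   the named list of `dgcm` fits.
#' @export
fit_family <- function(daily, models = names(.family_terms), ...) {
  fits <- lapply(models, function(nm) dgcm(daily, model = nm, ...))
  names(fits) <- models
  rows <- vapply(fits, function(f) length(f$design$y), 0L)
  if (length(unique(rows)) != 1L)
    stop("internal error: family models fitted on different row sets")
  tab <- data.frame(
    model = models,
    loglik = vapply(fits, function(f) f$loglik, 0),
    k = vapply(fits, function(f) as.integer(f$k_params), 0L),
    aic = vapply(fits, function(f) f$aic, 0),
    converged = vapply(fits, function(f) f$converged, TRUE))
  # parsimony tie-break: sort by AIC, then parameter count
  ord <- order(round(tab$aic / 1e-6) * 1e-6, tab$k)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, winner = tab$model[1]),
            class = "dgcm_family")
}

#' @export
print.dgcm_family <- function(x, digits = 2, ...) {
  cat("Trajectory model family (AIC comparison, best first)\n")
  tab <- x$table
  tab$loglik <- round(tab$loglik, digits)
  tab$aic <- round(tab$aic, digits)
  tab$delta_aic <- round(tab$delta_aic, digits)
  print(tab, row.names = FALSE)
  cat("winner:", x$winner, "-", .family_meaning[[x$winner]], "\n")
  invisible(x)
}

#' Moderate a trajectory model by a person-level covariate
#'
#' Extends a trajectory model with a standardized person-level covariate as a
#' Level-2 predictor of the random intercept and of every random slope,
#' i.e. a main effect plus a cross-level interaction with each change
#' parameter. Covariates are fitted one at a time.
#'
#' @param daily Daily scores joined with the change basis.
#' @param traits Person-level covariate table with `participant_id`.
#' @param covariate Name of the (standardized) covariate column.
#' @param model Model name; default the level-change-and-recovery model
#'   `"2d"`.
#' @param ... Passed to [fit_ml()].
#' @return A `dgcm` fit with interaction terms labelled
#'   `"<term>:<covariate>"`.
#' @export
moderate <- function(daily, traits, covariate, model = "2d", ...) {
  dgcm(daily, model = model, traits = traits, moderator = covariate, ...)
}

#' Predicted mean well-being trajectory
#'
#' Evaluates the fixed-effects equation of a (possibly moderated) trajectory
#' model over a set of dates at a given covariate value, in standardized
#' well-being units.
#'
#' @param fit A `dgcm` fit.
#' @param dates Dates to predict for; default every day of `config`'s window.
#' @param covariate_value Moderator value in z units (ignored for unmoderated
#'   fits). Default 0, the average person.
#' @param config The [coding_config()] used for the change basis.
#' @return A data frame with `date` and `wb_pred`.
#' @export
predict_trajectory <- function(fit, dates = NULL,
                               covariate_value = 0,
                               config = coding_config()) {
  stopifnot(inherits(fit, "dgcm"))
  if (is.null(dates)) dates <- window_days(config)
  basis <- code_date(dates, config)
  beta <- fit$beta
  pred <- rep(beta[["(Intercept)"]], length(dates))
  for (term in fit$spec$terms) pred <- pred + beta[[term]] * basis[[term]]
  if (!is.null(fit$moderator)) {
    pred <- pred + covariate_value * beta[[fit$moderator]]
    for (term in fit$spec$terms) {
      nm <- paste0(term, ":", fit$moderator)
      pred <- pred + covariate_value * beta[[nm]] * basis[[term]]
    }
  }
  data.frame(date = dates, wb_pred = as.numeric(pred))
}

#' @export
predict.dgcm <- function(object, dates = NULL, covariate_value = 0,
                         config = coding_config(), ...) {
  predict_trajectory(object, dates = dates,
                     covariate_value = covariate_value, config = config)
}

#' @export
plot.dgcm <- function(x, config = coding_config(), covariate_values = 0,
                      ...) {
  preds <- lapply(covariate_values, function(v)
    predict_trajectory(x, covariate_value = v, config = config))
  rng <- range(unlist(lapply(preds, `[[`, "wb_pred")))
  graphics::plot(preds[[1]]$date, preds[[1]]$wb_pred, type = "n", ylim = rng,
                 xlab = "date", ylab = "predicted well-being (z)", ...)
  for (i in seq_along(preds))
    graphics::lines(preds[[i]]$date, preds[[i]]$wb_pred, lty = i)
  graphics::abline(v = as.numeric(config$event_date), lty = 3)
  invisible(preds)
}
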