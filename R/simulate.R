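# Synthetic experience-sampling data with the statistical structure the
# analysis assumes: staggered participation windows, random beeps with
# per-beep compliance, latent daily well-being following a discontinuous
# growth trajectory with person-level random effects and trait-moderated
# slopes, discretized 1-6 item responses, and an event-spiked salience
# series. Every stage of the pipeline is testable without external data.

#' Generator configuration
#'
#' True parameters and sampling design for synthetic data. Truths are in
#' standardized well-being units (the units of the pipeline's `wb_z`), so the
#' noise components of each scenario are calibrated so that the total
#' state-level variance is approximately 1; fitted coefficients then estimate
#' the configured truths directly. Fixed-effect and moderation defaults are
#' the headline estimates of the study the design emulates.
#'
#' Scenarios: `"trajectory"` (the default; event trajectory with
#' trait-moderated slopes, no salience effects), `"salience"` (no trajectory
#' or moderation effects and no slope random effects; within/between salience
#' effects switched on), `"null"` (no change effects, no moderation, no slope
#' random effects -- data generated under the no-change model). A scenario
#' only sets defaults: any argument passed explicitly wins.
#'
#' @param n_participants Number of generated participants (default 1300).
#' @param enrollment Date range over which 28-day participation windows start
#'   (uniformly), giving individually shifted participation periods.
#' @param participation_days Length of each participation window (days).
#' @param beeps_per_day Maximum random beeps per day (default 4).
#' @param compliance_prob Per-beep i.i.d. response probability in (0, 1].
#'   The default 0.25, combined with the enrollment stagger, yields about 13
#'   observed days per participant.
#' @param true_fixed Named vector `intercept`, `level`, `pre`, `post`:
#'   fixed-effect truths in standardized units.
#' @param true_moderation Named vector `stability`, `stability_level`,
#'   `stability_pre`, `stability_post`: Stability main effect and cross-level
#'   interaction truths.
#' @param salience_effects Named vector `ws`, `bs`: effects of the
#'   within-/between-person salience components on daily well-being.
#' @param re_sd Standard deviations of the random intercept and the three
#'   random slopes (level, pre, post). The slope SDs are not reported by the
#'   emulated study; the defaults are chosen so that the generating event
#'   structure is identifiable at the design's sampling density (about 14
#'   observed days per person) while the total variance stays near 1.
#' @param re_corr 4 x 4 correlation matrix of the random effects (order:
#'   intercept, level, pre, post). The default couples a steeper event-day
#'   drop and a steeper anticipation decline with stronger recovery
#'   (correlations of -0.3 between level and post and between pre and post).
#' @param daily_noise_sd SD of the day-level residual.
#' @param state_noise_sd SD of the within-day (beep-level) deviation.
#' @param item_noise_sd SD of per-item noise, in raw 1-6 scale points.
#' @param latent_scale Raw scale points per standardized unit used to map the
#'   latent state on to the 1-6 items (items are `3.5 + latent_scale * state`
#'   plus noise, rounded and clipped; negative-affect items are generated as
#'   the `7 - x` reversal of a second noisy copy).
#' @param salience_params List `baseline`, `spike_height`, `decay_rate`,
#'   `noise_sd` shaping the event-spiked daily tweet-count series.
#' @param coding A [coding_config()]; defines the analysis window the
#'   participation windows are truncated to and the event the trajectory
#'   bends around.
#' @param scenario Preset name, see above.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 1300L,
                             enrollment = as.Date(c("2021-12-28",
                                                    "2022-03-27")),
                             participation_days = 28L,
                             beeps_per_day = 4L,
                             compliance_prob = 0.25,
                             true_fixed = c(intercept = -0.090,
                                            level = -0.200,
                                            pre = 0.005, post = 0.089),
                             true_moderation = c(stability = 0.245,
                                                 stability_level = -0.027,
                                                 stability_pre = -0.043,
                                                 stability_post = 0.161),
                             salience_effects = c(ws = 0, bs = 0),
                             re_sd = c(intercept = 0.5, level = 0.6,
                                       pre = 0.6, post = 0.6),
                             re_corr = default_re_corr(),
                             daily_noise_sd = 0.32,
                             state_noise_sd = 0.4,
                             item_noise_sd = 0.6,
                             latent_scale = 0.8,
                             salience_params = list(baseline = 150000,
                                                    spike_height = 600000,
                                                    decay_rate = 0.08,
                                                    noise_sd = 20000),
                             coding = coding_config(),
                             scenario = c("trajectory", "salience", "null")) {
  scenario <- match.arg(scenario)
  supplied <- names(match.call())[-1]
  presets <- switch(
    scenario,
    trajectory = list(),
    salience = list(
      true_fixed = c(intercept = -0.090, level = 0, pre = 0, post = 0),
      true_moderation = c(stability = 0, stability_level = 0,
                          stability_pre = 0, stability_post = 0),
      salience_effects = c(ws = -0.065, bs = -0.116),
      re_sd = c(intercept = 0.5, level = 0, pre = 0, post = 0),
      daily_noise_sd = 0.69),
    null = list(
      true_fixed = c(intercept = -0.090, level = 0, pre = 0, post = 0),
      true_moderation = c(stability = 0, stability_level = 0,
                          stability_pre = 0, stability_post = 0),
      re_sd = c(intercept = 0.5, level = 0, pre = 0, post = 0),
      daily_noise_sd = 0.69))
  for (nm in setdiff(names(presets), supplied))
    assign(nm, presets[[nm]])
  enrollment <- as.Date(enrollment)
  stopifnot(n_participants >= 2L, length(enrollment) == 2L,
            enrollment[1] <= enrollment[2], participation_days >= 1L,
            beeps_per_day >= 1L,
            compliance_prob > 0, compliance_prob <= 1,
            length(true_fixed) == 4L, length(true_moderation) == 4L,
            length(salience_effects) == 2L, length(re_sd) == 4L,
            all(re_sd >= 0), daily_noise_sd >= 0, state_noise_sd >= 0,
            item_noise_sd >= 0, latent_scale > 0,
            inherits(coding, "coding_config"))
  re_corr <- as.matrix(re_corr)
  if (!isTRUE(all.equal(re_corr, t(re_corr))) ||
      any(eigen(re_corr, symmetric = TRUE, only.values = TRUE)$values <
          -1e-10))
    stop("'re_corr' must be a symmetric positive-semidefinite matrix")
  structure(
    list(n_participants = as.integer(n_participants),
         enrollment = enrollment,
         participation_days = as.integer(participation_days),
         beeps_per_day = as.integer(beeps_per_day),
         compliance_prob = compliance_prob,
         true_fixed = true_fixed, true_moderation = true_moderation,
         salience_effects = salience_effects,
         re_sd = re_sd, re_corr = re_corr,
         daily_noise_sd = daily_noise_sd, state_noise_sd = state_noise_sd,
         item_noise_sd = item_noise_sd, latent_scale = latent_scale,
         salience_params = salience_params, coding = coding,
         scenario = scenario),
    class = "generator_config")
}

#' Default random-effect correlation structure
#'
#' Identity except for correlations of -0.3 between the level and post-event
#' random slopes and between the pre-event and post-event random slopes:
#' people with a steeper well-being drop on the event day, or a steeper
#' anticipatory decline, tend to show stronger recovery.
#'
#' @return A 4 x 4 correlation matrix (intercept, level, pre, post).
#' @export
default_re_corr <- function() {
  rc <- diag(4)
  dimnames(rc) <- rep(list(c("intercept", "level", "pre", "post")), 2)
  rc["level", "post"] <- rc["post", "level"] <- -0.3
  rc["pre", "post"] <- rc["post", "pre"] <- -0.3
  rc
}

#' Generate an event-spiked daily salience series
#'
#' Expected counts are `baseline` before the event and
#' `baseline + spike_height * exp(-decay_rate * days_since_event)` from the
#' event day on, plus non-negative half-normal noise; counts are integer and
#' non-negative. With a positive decay rate the peak falls on the event day.
#'
#' @param params List with `baseline`, `spike_height`, `decay_rate`,
#'   `noise_sd`.
#' @param config A [coding_config()]; the series covers its window.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as when called from [generate()]).
#' @return A data frame with `date` and `tweet_count`, one row per window
#'   day.
#' @export
generate_salience <- function(params, config = coding_config(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  days <- window_days(config)
  d <- as.integer(days - config$event_date)
  mu <- params$baseline +
    ifelse(d >= 0L, params$spike_height * exp(-params$decay_rate * d), 0)
  noise <- abs(stats::rnorm(length(days), 0, params$noise_sd))
  data.frame(date = days,
             tweet_count = as.integer(pmax(0, round(mu + noise))))
}

#' Generate a synthetic experience-sampling dataset
#'
#' Draws a complete dataset -- state table, participant table, salience
#' series -- under the configured truths. The latent daily well-being of
#' person j on day t is
#' \deqn{(\beta_0 + m_0 s_j + b_{0j}) + (\beta_l + m_l s_j + b_{lj})\,level_t
#'   + (\beta_p + m_p s_j + b_{pj})\,pre_t + (\beta_q + m_q s_j + b_{qj})\,post_t
#'   + \gamma_{ws} ws_{jt} + \gamma_{bs} bs_j + e_{jt}}
#' with \eqn{s_j} the person's sample-standardized Stability (computed from
#' generated BFI-2 domain scores by the same formula the pipeline uses) and
#' \eqn{b_j} multivariate-normal random effects. Which beeps are observed is
#' decided before well-being is generated (compliance is independent of
#' well-being), and the salience components `ws`/`bs` are defined over each
#' person's observed days, matching the analysis definition.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list with data frames `states`, `participants`, `salience`, and
#'   `true_params` (the configuration echoed back).
#' @export
generate <- function(config = generator_config(), seed) {
  stopifnot(inherits(config, "generator_config"))
  if (missing(seed)) stop("'seed' is required for reproducibility")
  set.seed(as.integer(seed))
  cfg <- config
  win <- cfg$coding
  if (cfg$enrollment[1] > win$window_end ||
      (cfg$enrollment[2] + cfg$participation_days - 1L) < win$window_start)
    stop("infeasible config: no participation window can touch the analysis window")
  n <- cfg$n_participants
  ids <- sprintf("p%05d", seq_len(n))

  # participant traits and demographics
  doms <- matrix(pmin(5, pmax(1, round(stats::rnorm(5L * n, 3.5, 0.6), 2))),
                 nrow = n, ncol = 5L,
                 dimnames = list(NULL, c("bfi_e", "bfi_a", "bfi_c",
                                         "bfi_n", "bfi_o")))
  stability_raw <- (doms[, "bfi_a"] + doms[, "bfi_c"] +
                      (6 - doms[, "bfi_n"])) / 3
  stab_z <- as.numeric(scale(stability_raw))
  participants <- data.frame(
    participant_id = ids,
    gender = sample(c("female", "male", "other"), n, replace = TRUE,
                    prob = c(0.80, 0.19, 0.01)),
    age = pmin(91L, 18L + as.integer(stats::rgamma(n, shape = 2,
                                                   scale = 4))),
    subjective_social_status = sample(1:10, n, replace = TRUE,
                                      prob = stats::dnorm(1:10, 6, 2)),
    political_orientation = sample(1:10, n, replace = TRUE,
                                   prob = stats::dnorm(1:10, 4.5, 2)),
    doms,
    conscientious_flag = TRUE,
    mean_seconds_per_item = round(2.2 + stats::rgamma(n, shape = 2,
                                                      scale = 1), 2),
    country = sample(c("DE", "IT", "PL", "GB", "FR", "NL", "BE"), n,
                     replace = TRUE,
                     prob = c(0.30, 0.25, 0.15, 0.10, 0.08, 0.07, 0.05)),
    is_european = TRUE)

  # staggered participation windows, truncated to the analysis window
  span <- as.integer(cfg$enrollment[2] - cfg$enrollment[1]) + 1L
  wstart <- cfg$enrollment[1] + (sample.int(span, n, replace = TRUE) - 1L)
  wend <- wstart + cfg$participation_days - 1L
  a <- pmax(wstart, win$window_start)
  b <- pmin(wend, win$window_end)
  len <- pmax(0L, as.integer(b - a) + 1L)

  # person-day grid and per-day observed beep counts (i.i.d. per beep)
  pidx <- rep.int(seq_len(n), len)
  day <- a[pidx] + (sequence(len) - 1L)
  nb <- stats::rbinom(length(day), cfg$beeps_per_day, cfg$compliance_prob)
  obs <- nb > 0L
  pidx <- pidx[obs]; day <- day[obs]; nb <- nb[obs]
  if (!length(day)) stop("configuration produced no observed days")

  # event-spiked salience, standardized over window days, split ws/bs over
  # each person's observed days
  salience <- generate_salience(cfg$salience_params, win)
  sal_z <- .zstd(salience$tweet_count, "generated salience")
  sal_day <- sal_z[match(day, salience$date)]
  bs_p <- tapply(sal_day, pidx, mean)
  bs <- as.numeric(bs_p[match(as.character(pidx), names(bs_p))])
  ws <- sal_day - bs

  # latent daily well-being
  D <- diag(cfg$re_sd) %*% cfg$re_corr %*% diag(cfg$re_sd)
  ed <- eigen(D, symmetric = TRUE)
  sqrtD <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
  B <- matrix(stats::rnorm(4L * n), n, 4L) %*% sqrtD
  basis <- code_date(day, win)
  tf <- cfg$true_fixed; tm <- cfg$true_moderation
  se <- cfg$salience_effects
  zs <- stab_z[pidx]
  wb_day <-
    (tf[["intercept"]] + tm[["stability"]] * zs + B[pidx, 1L]) +
    (tf[["level"]] + tm[["stability_level"]] * zs + B[pidx, 2L]) *
      basis$level +
    (tf[["pre"]] + tm[["stability_pre"]] * zs + B[pidx, 3L]) *
      basis$pre_event +
    (tf[["post"]] + tm[["stability_post"]] * zs + B[pidx, 4L]) *
      basis$post_event +
    se[["ws"]] * ws + se[["bs"]] * bs +
    stats::rnorm(length(day), 0, cfg$daily_noise_sd)

  # beep-level latent states and discretized 1-6 items
  sidx <- rep.int(seq_along(day), nb)
  state <- wb_day[sidx] + stats::rnorm(length(sidx), 0, cfg$state_noise_sd)
  raw <- 3.5 + cfg$latent_scale * state
  item <- function() {
    as.integer(pmin(6, pmax(1, round(raw + stats::rnorm(length(raw), 0,
                                                        cfg$item_noise_sd)))))
  }
  pa1 <- item(); pa2 <- item(); pa3 <- item()
  na1 <- 7L - item(); na2 <- 7L - item(); na3 <- 7L - item()

  mins <- sample.int(14L * 60L, length(sidx), replace = TRUE) - 1L
  states <- data.frame(
    participant_id = ids[pidx[sidx]],
    timestamp = sprintf("%sT%02d:%02d:00", format(day[sidx]),
                        8L + mins %/% 60L, mins %% 60L),
    pa1 = pa1, pa2 = pa2, pa3 = pa3, na1 = na1, na2 = na2, na3 = na3,
    survey_kind = "random_beep")
  states <- states[order(states$participant_id, states$timestamp), ,
                   drop = FALSE]
  rownames(states) <- NULL
  list(states = states, participants = participants, salience = salience,
       true_params = cfg)
}

#' Write a generated dataset to CSV + JSON
#'
#' Writes `states.csv`, `participants.csv`, `salience.csv` and
#' `true_params.json` into a directory. Identical inputs produce
#' byte-identical files.
#'
#' @param sim A dataset from [generate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(states = file.path(dir, "states.csv"),
             participants = file.path(dir, "participants.csv"),
             salience = file.path(dir, "salience.csv"),
             true_params = file.path(dir, "true_params.json"))
  utils::write.csv(sim$states, paths["states"], row.names = FALSE)
  utils::write.csv(sim$participants, paths["participants"],
                   row.names = FALSE)
  sal <- sim$salience
  sal$date <- format(sal$date)
  utils::write.csv(sal, paths["salience"], row.names = FALSE)
  cfg <- sim$true_params
  cfg$enrollment <- format(cfg$enrollment)
  cfg$coding <- list(event_date = format(cfg$coding$event_date),
                     window = cfg$coding$window,
                     window_start = format(cfg$coding$window_start),
                     window_end = format(cfg$coding$window_end),
                     denom_days = cfg$coding$denom_days)
  jsonlite::write_json(unclass(cfg), paths["true_params"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
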