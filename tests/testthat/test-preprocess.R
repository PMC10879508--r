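# Ingest, scoring, exclusion rules, standardization, aggregation.

test_that("state table reading validates schema, ranges and timestamps", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tiny_states(), f, row.names = FALSE)
  st <- read_state_table(f)
  expect_identical(nrow(st), 6L)
  expect_s3_class(st$date, "Date")
  expect_identical(st$date[1], as.Date("2022-02-20"))

  bad <- tiny_states(); bad$pa1[2] <- 7
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_state_table(f), "pa1.*row\\(s\\) 2")

  bad <- tiny_states(); bad$timestamp[3] <- "not-a-time"
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_state_table(f), "unparseable timestamp.*3")

  utils::write.csv(tiny_states()[0, ], f, row.names = FALSE)
  expect_warning(empty <- read_state_table(f), "empty")
  expect_identical(nrow(empty), 0L)

  miss <- tiny_states(); miss$na3 <- NULL
  utils::write.csv(miss, f, row.names = FALSE)
  expect_error(read_state_table(f), "missing column 'na3'")

  # schema mapping renames file columns to canonical names
  ren <- tiny_states(); names(ren)[names(ren) == "participant_id"] <- "pid"
  utils::write.csv(ren, f, row.names = FALSE)
  st2 <- read_state_table(f, schema = list(participant_id = "pid"))
  expect_identical(st2$participant_id, st$participant_id)
})

test_that("state well-being is the mean of PA and reverse-scored NA items", {
  expect_identical(score_state_wb(data.frame(pa1 = 6, pa2 = 6, pa3 = 6,
                                             na1 = 1, na2 = 1, na3 = 1)), 6)
  expect_identical(score_state_wb(data.frame(pa1 = 1, pa2 = 1, pa3 = 1,
                                             na1 = 6, na2 = 6, na3 = 6)), 1)
  expect_identical(score_state_wb(data.frame(pa1 = 3, pa2 = 4, pa3 = 5,
                                             na1 = 2, na2 = 1, na3 = 3)),
                   4.5)
  expect_error(score_state_wb(data.frame(pa1 = 3, pa2 = NA, pa3 = 5,
                                         na1 = 2, na2 = 1, na3 = 3)),
               "missing affect item")
})

test_that("societal well-being combines positivity, reversed threat, similarity", {
  expect_identical(score_societal_wb(data.frame(positivity = 10, threat = 1,
                                                similarity = 10)), 10)
  expect_identical(score_societal_wb(data.frame(positivity = 1, threat = 10,
                                                similarity = 1)), 1)
  expect_identical(score_societal_wb(data.frame(positivity = 5, threat = 6,
                                                similarity = 5)), 5)
  expect_error(score_societal_wb(data.frame(positivity = 5, threat = NA,
                                            similarity = 5)), "missing")
})

test_that("window restriction keeps both boundary days and rejects inverted windows", {
  st <- tiny_states()
  st$date <- as.Date(substr(st$timestamp, 1, 10))
  out <- restrict_window(st, "2022-02-21", "2022-02-25")
  expect_identical(sort(unique(format(out$date))),
                   c("2022-02-21", "2022-02-23", "2022-02-25"))
  expect_error(restrict_window(st, "2022-02-25", "2022-02-21"),
               "not be after")
})

test_that("exclusion rules apply in order a, b, c with first-rule attribution", {
  win <- as.Date(c("2022-01-24", "2022-03-27"))
  days <- function(id, dates)
    data.frame(participant_id = id, date = as.Date(dates))
  states <- rbind(
    days("ok", c("2022-02-01", "2022-02-02", "2022-02-03")),
    days("one_day", "2022-02-01"),
    days("fast", c("2022-02-01", "2022-02-02")),
    days("careless_and_fast", c("2022-02-01", "2022-02-02")),
    days("outside", c("2022-01-01", "2022-01-02", "2022-02-05")))
  participants <- data.frame(
    participant_id = c("ok", "one_day", "fast", "careless_and_fast",
                       "outside"),
    conscientious_flag = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    mean_seconds_per_item = c(2.5, 3, 1.9, 1.5, 3))
  res <- apply_exclusions(states, participants, win)
  # careless_and_fast violates (a) and (b) but is attributed to (a)
  expect_identical(unname(res$report$excluded), c(1L, 1L, 2L))
  expect_identical(res$participants$participant_id, "ok")
  expect_identical(unique(res$states$participant_id), "ok")
  # rule (c) counts distinct days inside the window only: "outside" has one
  expect_identical(res$report$n_retained, 1L)
  # boundary case: exactly 2 s per item is retained
  p2 <- data.frame(participant_id = "ok", conscientious_flag = TRUE,
                   mean_seconds_per_item = 2)
  res2 <- apply_exclusions(states[states$participant_id == "ok", ], p2, win)
  expect_identical(res2$report$n_retained, 1L)
})

test_that("exclusions are idempotent", {
  sim <- generate(small_config(), seed = 11)
  st <- sim$states
  st$date <- as.Date(substr(st$timestamp, 1, 10))
  win <- as.Date(c("2022-01-24", "2022-03-27"))
  r1 <- apply_exclusions(st, sim$participants, win)
  r2 <- apply_exclusions(r1$states, r1$participants, win)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$participants, r2$participants)
  expect_identical(sum(unlist(r2$report$excluded)), 0L)
})

test_that("standardization yields mean 0, sd 1 and is affine invariant", {
  st <- data.frame(wb_state = c(4, 6))
  out <- standardize_states(st)
  expect_equal(out$wb_z, c(-1, 1) / sqrt(2))
  sim <- generate(small_config(), seed = 5)
  scored <- sim$states
  scored$wb_state <- score_state_wb(scored)
  z1 <- standardize_states(scored)$wb_z
  expect_equal(mean(z1), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z1), 1, tolerance = 1e-12)
  shifted <- scored
  shifted$wb_state <- shifted$wb_state + 2.3
  expect_equal(standardize_states(shifted)$wb_z, z1, tolerance = 1e-12)
  expect_error(standardize_states(data.frame(wb_state = rep(3, 5))),
               "zero variance")
  expect_error(standardize_states(data.frame(wb_state = 3)), "fewer than 2")
})

test_that("daily aggregation: one row per participant-day, means and counts", {
  st <- data.frame(
    participant_id = c("a", "a", "a", "b"),
    date = as.Date(c("2022-02-01", "2022-02-01", "2022-02-02",
                     "2022-02-01")),
    wb_state = c(3, 5, 4, 2), wb_z = c(-1, 1, 0.5, -2))
  d <- aggregate_daily(st)
  expect_identical(nrow(d), 3L)
  a1 <- d[d$participant_id == "a" & d$date == as.Date("2022-02-01"), ]
  expect_identical(a1$wb_z, 0)         # symmetric pair averages to zero
  expect_identical(a1$wb_raw, 4)
  expect_identical(a1$n_states, 2L)
  singleton <- d[d$participant_id == "b", ]
  expect_identical(singleton$wb_z, -2) # single beep passes through
  # conservation: beep counts sum to the number of state records
  expect_identical(sum(d$n_states), nrow(st))
})

test_that("row order of the inputs does not change any output", {
  sim <- generate(small_config(), seed = 21)
  p1 <- prepare_daily(sim$states, sim$participants)
  shuf <- sim$states[sample.int(nrow(sim$states)), ]
  p2 <- prepare_daily(shuf, sim$participants[rev(seq_len(nrow(sim$participants))), ])
  expect_equal(p1$daily, p2$daily)
  expect_identical(p1$report$excluded, p2$report$excluded)
})

test_that("meta-traits: Stability and Plasticity formulas and standardization", {
  p <- tiny_participants()
  tr <- score_traits(p)
  expect_equal(tr$stability_raw,
               (p$bfi_a + p$bfi_c + (6 - p$bfi_n)) / 3)
  expect_equal(tr$plasticity_raw, (p$bfi_e + p$bfi_o) / 2)
  expect_equal(mean(tr$stability), 0, tolerance = 1e-12)
  expect_equal(stats::sd(tr$stability), 1, tolerance = 1e-12)
  # maximal profile
  pm <- p[1, ]; pm$bfi_a <- 5; pm$bfi_c <- 5; pm$bfi_n <- 1
  expect_identical(score_traits(rbind(pm, p[2, ]))$stability_raw[1], 5)
  # incomplete domains are flagged, not fatal
  p3 <- rbind(p, p[1, ]); p3$participant_id[3] <- "p3"; p3$bfi_n[3] <- NA
  tr3 <- score_traits(p3)
  expect_false(tr3$trait_complete[3])
  expect_true(is.na(tr3$stability[3]))
  # identical profiles cannot be standardized
  expect_error(score_traits(rbind(p[1, ], p[1, ])), "zero variance")
})

test_that("beep counts are conserved through the full preprocessing chain", {
  sim <- generate(small_config(), seed = 31)
  prep <- prepare_daily(sim$states, sim$participants)
  expect_identical(sum(prep$daily$n_states), nrow(prep$states))
  expect_identical(anyDuplicated(prep$daily[c("participant_id", "date")]),
                   0L)
})
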