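test_that("write/read round-trips a simulated cohort", {
  co <- simulate_cohort(sim_config(25, 90, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(length(back$recipients), length(co$recipients))
  expect_identical(back$covariate_names, co$covariate_names)
  # order recipients by id for comparison (reader sorts by id)
  by_id <- function(ch) {
    o <- order(vapply(ch$recipients, `[[`, character(1), "recipient_id"))
    ch$recipients[o]
  }
  a <- by_id(co); b <- by_id(back)
  for (i in seq_along(a)) {
    expect_equal(b[[i]]$event_times, a[[i]]$event_times)
    expect_equal(b[[i]]$obs_length, a[[i]]$obs_length)
    expect_equal(unname(b[[i]]$covariates), unname(a[[i]]$covariates))
  }
})

test_that("cohort files are deterministic and order-invariant", {
  co <- simulate_cohort(sim_config(10, 60, seed = 8))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, p1); write_cohort(co, p2)
  expect_identical(readLines(p1), readLines(p2))
  # shuffling the event rows does not change the parsed cohort
  tab <- read.csv(p1)
  set.seed(4)
  shuf <- tab[sample(nrow(tab)), ]
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(shuf, p3, row.names = FALSE, na = "")
  back1 <- read_cohort(p1); back3 <- read_cohort(p3)
  by_id <- function(ch) {
    o <- order(vapply(ch$recipients, `[[`, character(1), "recipient_id"))
    lapply(ch$recipients[o], `[[`, "event_times")
  }
  expect_identical(by_id(back1), by_id(back3))
})

test_that("reader validates schema, duplicates, and censoring violations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("recipient_id,event_time_days,obs_length_days",
               "a,5,10", "a,5,10", "b,3,20"), path)
  expect_warning(co <- read_cohort(path), "duplicate")
  expect_equal(total_events(co), 2)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("recipient_id,event_time_days,obs_length_days",
               "a,15,10"), bad)
  expect_error(read_cohort(bad), "beyond obs_length.*a")
  miss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("recipient_id,foo", "a,1"), miss)
  expect_error(read_cohort(miss), "missing required columns")
  # zero-covariate cohort round-trips
  co0 <- make_cohort(list(c(1, 2), numeric(0)), 10)
  p0 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co0, p0)
  expect_identical(length(read_cohort(p0)$covariate_names), 0L)
})

test_that("cohort construction applies the index-date rules (hand-traced)", {
  start <- as.Date("2016-01-01"); end <- as.Date("2018-12-31")
  d0 <- as.Date("2016-03-01")
  raw <- data.frame(
    recipient_id = c("keep", "keep", "keep", "drop", "drop"),
    event_date = c(d0, d0 + 100, d0 + 200, d0, d0 + 30),
    sex = "male", age = 40)
  res <- build_cohort(raw, start, end)
  # 'drop' has both events before its index date (day 90)
  expect_identical(res$exclusions$recipient_id, "drop")
  expect_match(res$exclusions$reason, "no overdose after index")
  r <- res$cohort$recipients[[1]]
  expect_equal(r$event_times, c(10, 110))
  expect_equal(r$obs_length, as.numeric(end - (d0 + 90)))
  # conservation: included + excluded = distinct raw recipients
  expect_identical(length(res$cohort$recipients) + nrow(res$exclusions), 2L)
})

test_that("age, missing demographics, and same-day duplicates are handled", {
  start <- "2016-01-01"; end <- "2017-12-31"
  d0 <- as.Date("2016-02-01")
  raw <- data.frame(
    recipient_id = rep(c("adult", "minor", "nodata", "dup"), each = 2),
    event_date = rep(c(d0, d0 + 150), 4),
    race = c("white", "white", "black", "black", NA, NA, "black", "black"),
    age = c(40, 40, 16, 16, 35, 35, 50, 50))
  raw <- rbind(raw, data.frame(recipient_id = "dup", event_date = d0 + 150,
                               race = "black", age = 50))
  res <- build_cohort(raw, start, end)
  ids <- vapply(res$cohort$recipients, `[[`, character(1), "recipient_id")
  expect_setequal(ids, c("adult", "dup"))
  expect_setequal(res$exclusions$reason,
                  c("under minimum age at index date", "missing demographics"))
  # duplicate same-day rows collapsed to one event
  dup <- res$cohort$recipients[[which(ids == "dup")]]
  expect_identical(length(dup$event_times), 1L)
  # dummy encoding against the alphabetically first level
  expect_identical(res$cohort$covariate_names, "race.white")
})

test_that("empty input and bad dates are rejected cleanly", {
  empty <- data.frame(recipient_id = character(0), event_date = character(0))
  res <- build_cohort(empty, "2016-01-01", "2016-12-31")
  expect_null(res$cohort)
  expect_identical(nrow(res$exclusions), 0L)
  expect_error(build_cohort(empty, "2016-01-01", "2015-01-01"), "after")
  bad <- data.frame(recipient_id = "a", event_date = "not-a-date")
  expect_error(suppressWarnings(build_cohort(bad, "2016-01-01", "2016-12-31")),
               "unparseable")
})

test_that("rebuilding from a built cohort's dates never adds recipients", {
  # membership can shrink (the re-found qualifying event shifts the index
  # forward) but must never grow
  start <- as.Date("2016-01-01"); end <- as.Date("2018-12-31")
  set.seed(77)
  rows <- list()
  for (i in 1:12) {
    n <- sample(2:6, 1)
    dates <- start + sort(sample(0:900, n))
    rows[[i]] <- data.frame(recipient_id = sprintf("p%02d", i),
                            event_date = dates, sex = "f", age = 30)
  }
  raw <- do.call(rbind, rows)
  first <- build_cohort(raw, start, end)
  ids1 <- vapply(first$cohort$recipients, `[[`, character(1), "recipient_id")
  # re-express kept events as calendar dates (index date = study period map)
  raw2 <- do.call(rbind, lapply(first$cohort$recipients, function(r) {
    index_date <- end - r$obs_length
    data.frame(recipient_id = r$recipient_id,
               event_date = index_date + r$event_times,
               sex = "f", age = 30)
  }))
  second <- build_cohort(raw2, start, end)
  ids2 <- if (is.null(second$cohort)) character(0) else
    vapply(second$cohort$recipients, `[[`, character(1), "recipient_id")
  expect_true(all(ids2 %in% ids1))
  # conservation again
  expect_identical(length(ids2) + nrow(second$exclusions), length(ids1))
})
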